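# shared small-scale simulation settings and independent oracles

tiny_config <- function(seed = 7, ...) {
  args <- modifyList(list(
    n_strains = 112, n_chromosomes = 4, n_markers_per_chrom = 50,
    n_genes = 300,
    edge_counts_by_type = c(PPI = 500, PDI = 200, KPI = 200, EEI = 100),
    n_planted_eqtls = 10, n_planted_ascp = 5, n_planted_asdp = 5,
    n_compounds = 10, conditions_per_compound = 2, n_planted_smp_qtls = 5,
    seed = seed), list(...))
  do.call(sim_config, args)
}

# simple geno_panel from a marker x strain matrix on one chromosome
toy_geno <- function(calls, chrom = NULL, pos = NULL) {
  m <- nrow(calls)
  if (is.null(rownames(calls))) rownames(calls) <- sprintf("m%02d", seq_len(m))
  if (is.null(colnames(calls))) colnames(calls) <- sprintf("s%02d", seq_len(ncol(calls)))
  geno_panel(calls, data.frame(marker = rownames(calls),
                               chrom = if (is.null(chrom)) "chr01" else chrom,
                               pos = if (is.null(pos)) seq_len(m) * 1000 else pos))
}

toy_net <- function(...) {
  interactome(data.frame(...))
}

# breadth-first shortest-path oracle over an undirected edge list
bfs_distance <- function(edges_a, edges_b, from, to) {
  nbr <- split(c(edges_b, edges_a), c(edges_a, edges_b))
  dist <- structure(0L, names = from)
  frontier <- from
  while (length(frontier)) {
    if (to %in% names(dist)) return(unname(dist[to]))
    nxt <- setdiff(unique(unlist(nbr[frontier], use.names = FALSE)), names(dist))
    if (!length(nxt)) break
    dist <- c(dist, structure(rep(max(dist) + 1L, length(nxt)), names = nxt))
    frontier <- nxt
  }
  if (to %in% names(dist)) unname(dist[to]) else Inf
}

# union-find connected-component oracle
uf_components <- function(nodes, edges_a, edges_b) {
  parent <- structure(nodes, names = nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_along(edges_a)) {
    ra <- find(edges_a[i]); rb <- find(edges_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  table(vapply(nodes, find, character(1)))
}

# step-up Benjamini-Hochberg by the hand recurrence
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  pmin(q, 1)
}

# allele-conditioned bivariate expression: correlation r0 in group 0,
# r1 in group 1 (independent construction from the generator's internals)
make_dys_pair <- function(alle, r0, r1) {
  n <- length(alle)
  x <- numeric(n); y <- numeric(n)
  for (grp in c(0, 1)) {
    idx <- which(alle == grp)
    r <- if (grp == 0) r0 else r1
    f <- rnorm(length(idx))
    x[idx] <- sqrt(abs(r)) * f + sqrt(1 - abs(r)) * rnorm(length(idx))
    y[idx] <- sign(r) * sqrt(abs(r)) * f + sqrt(1 - abs(r)) * rnorm(length(idx))
    if (r == 0) {
      x[idx] <- rnorm(length(idx)); y[idx] <- rnorm(length(idx))
    }
  }
  list(x = x, y = y)
}
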