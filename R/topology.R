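#' Characteristic path length of a gene set
#'
#' Mean shortest-path distance (in edges) over unordered pairs of the gene
#' set, measured in the full integrated network's undirected simple view —
#' not inside the induced subgraph — so scattered gene sets score long
#' paths even when their induced subgraph is empty. Pairs lying in
#' different components are excluded and their fraction reported.
#'
#' @param net an [interactome()] or an igraph graph (used as-is).
#' @param gene_set at least two gene ids present in the network.
#' @param induced measure within the induced subgraph instead.
#' @return list: `length` (mean distance; `NA` if every pair is
#'   disconnected), `excluded_fraction`, `n_pairs`.
#' @export
characteristic_path_length <- function(net, gene_set, induced = FALSE) {
  g <- if (inherits(net, "igraph")) net else as_undirected_graph(net)
  gene_set <- intersect(unique(gene_set), igraph::V(g)$name)
  if (length(gene_set) < 2) stop("need at least two genes present in the network")
  if (induced) g <- igraph::induced_subgraph(g, gene_set)
  d <- igraph::distances(g, v = gene_set, to = gene_set)
  vals <- d[upper.tri(d)]
  finite <- is.finite(vals)
  list(length = if (any(finite)) mean(vals[finite]) else NA_real_,
       excluded_fraction = mean(!finite),
       n_pairs = length(vals))
}

#' Density of a sub-network
#'
#' 2E / (N (N - 1)) on the undirected simple-graph view of the induced
#' edges (parallel typed edges between the same pair counted once).
#'
#' @param sub a [subnetwork()].
#' @return density in [0, 1]; `NA` with a warning when N < 2.
#' @export
subnetwork_density <- function(sub) {
  n <- length(sub$genes)
  if (n < 2) {
    warning("density undefined for fewer than 2 genes")
    return(NA_real_)
  }
  e <- nrow(unique(data.frame(a = pmin(sub$edges$gene_a, sub$edges$gene_b),
                              b = pmax(sub$edges$gene_a, sub$edges$gene_b))))
  2 * e / (n * (n - 1))
}

#' In-degree ratio of a gene set
#'
#' Ratio of edges with both endpoints inside the set ("in-degree") to
#' edges with exactly one endpoint inside ("out-degree"), on the
#' undirected simple view of the integrated network. A set with no
#' boundary edges returns `Inf` with the `boundary_free` attribute set.
#'
#' @param net an [interactome()] or igraph graph.
#' @param gene_set nonempty gene set.
#' @return the ratio (possibly 0 or `Inf`).
#' @export
in_degree_ratio <- function(net, gene_set) {
  g <- if (inherits(net, "igraph")) net else as_undirected_graph(net)
  gene_set <- intersect(unique(gene_set), igraph::V(g)$name)
  if (!length(gene_set)) stop("empty gene set")
  el <- igraph::as_edgelist(g)
  ina <- el[, 1] %in% gene_set
  inb <- el[, 2] %in% gene_set
  within <- sum(ina & inb)
  boundary <- sum(xor(ina, inb))
  if (boundary == 0) {
    r <- Inf
    attr(r, "boundary_free") <- TRUE
    return(r)
  }
  within / boundary
}

#' Degree-preserving (Maslov-Sneppen) randomization
#'
#' Rewires each interaction-type layer separately by repeated double-edge
#' swaps, preserving every gene's degree within the layer (in- and
#' out-degree for the directed PDI/KPI layers) and never introducing
#' self-loops or duplicate edges within a type. Each layer receives
#' `swaps_per_edge` x (its edge count) rewiring attempts; layers with
#' fewer than 2 edges are returned unchanged with a warning.
#'
#' @param net an [interactome()].
#' @param swaps_per_edge average rewiring attempts per edge (default 100).
#' @param seed integer seed (`NULL` leaves the RNG stream alone, for use
#'   inside callers that seed once).
#' @return a rewired [interactome()] with identical per-type degree
#'   sequences.
#' @export
maslov_sneppen_randomize <- function(net, swaps_per_edge = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pieces <- lapply(split(seq_len(nrow(net)), net$type), function(idx) {
    sub <- net[idx, , drop = FALSE]
    if (nrow(sub) < 2) {
      warning(sprintf("type %s has < 2 edges; left unchanged", sub$type[1]))
      return(sub)
    }
    directed <- sub$type[1] %in% DIRECTED_TYPES
    genes <- sort(unique(c(sub$gene_a, sub$gene_b)))
    g <- igraph::graph_from_data_frame(sub[, c("gene_a", "gene_b")],
                                       directed = directed,
                                       vertices = data.frame(name = genes))
    r <- igraph::rewire(g, igraph::keeping_degseq(
      loops = FALSE, niter = swaps_per_edge * nrow(sub)))
    el <- igraph::as_edgelist(r)
    data.frame(gene_a = el[, 1], gene_b = el[, 2], type = sub$type[1])
  })
  out <- suppressMessages(interactome(do.call(rbind, pieces)))
  stopifnot(nrow(out) == nrow(net))
  out
}

# per-type degree sequence as a canonical named structure (for contracts)
type_degree_sequences <- function(net) {
  lapply(split(net, net$type), function(sub) {
    if (sub$type[1] %in% DIRECTED_TYPES) {
      list(out = sort(table(sub$gene_a)), inn = sort(table(sub$gene_b)),
           out_by_gene = table(factor(sub$gene_a, levels = sort(unique(c(sub$gene_a, sub$gene_b))))),
           in_by_gene = table(factor(sub$gene_b, levels = sort(unique(c(sub$gene_a, sub$gene_b))))))
    } else {
      g <- c(sub$gene_a, sub$gene_b)
      list(deg = table(factor(g, levels = sort(unique(g)))))
    }
  })
}

topology_stats_for_set <- function(graph, net, gene_set) {
  cpl <- characteristic_path_length(graph, gene_set)
  sub <- suppressMessages(extract_subnetwork(net, gene_set, owner = "tmp"))
  idr <- in_degree_ratio(graph, gene_set)
  c(char_path_length = cpl$length,
    density = subnetwork_density(sub),
    in_degree_ratio = if (is.infinite(idr)) NA_real_ else idr)
}

#' Topology randomization test for sub-networks
#'
#' Scores each sub-network's characteristic path length, density, and
#' in-degree ratio against an ensemble of null networks. The default null
#' rewires the integrated interactome by degree-preserving edge swaps
#' ([maslov_sneppen_randomize()]) and recomputes the statistics on the
#' same gene sets; `null = "geneset"` instead resamples gene sets of the
#' same size from the network's nodes and keeps the network fixed. Z =
#' (observed - null mean) / null SD per statistic; the empirical p-value
#' counts null values at least as extreme in the enriched direction
#' (>= observed for density and in-degree ratio, <= observed for path
#' length, which modular sets are expected to shorten).
#'
#' @param net the integrated [interactome()].
#' @param subnetworks named list of [subnetwork()] objects (or of gene-id
#'   vectors).
#' @param n_random ensemble size (default 1000).
#' @param swaps_per_edge rewiring intensity for the edge-swap null.
#' @param seed integer seed.
#' @param null `"edgeswap"` (default) or `"geneset"`.
#' @return data.frame with one row per sub-network x statistic: observed,
#'   null mean/SD, Z, empirical p; `ensemble_means` rows averaged over
#'   sub-networks are in `attr(, "ensemble_means")`. A null SD of zero
#'   leaves Z as `NA`.
#' @export
topology_null_test <- function(net, subnetworks, n_random = 1000,
                               swaps_per_edge = 100, seed = 1L,
                               null = c("edgeswap", "geneset")) {
  null <- match.arg(null)
  set.seed(seed)
  graph <- as_undirected_graph(net)
  sets <- lapply(subnetworks, function(x) if (inherits(x, "subnetwork")) x$genes else x)
  if (is.null(names(sets))) names(sets) <- sprintf("sub%d", seq_along(sets))
  obs <- t(vapply(sets, function(gs) topology_stats_for_set(graph, net, gs),
                  numeric(3)))

  null_vals <- array(NA_real_, dim = c(n_random, length(sets), 3))
  all_genes <- igraph::V(graph)$name
  for (b in seq_len(n_random)) {
    if (null == "edgeswap") {
      rnet <- maslov_sneppen_randomize(net, swaps_per_edge = swaps_per_edge)
      rgraph <- as_undirected_graph(rnet)
      for (k in seq_along(sets))
        null_vals[b, k, ] <- topology_stats_for_set(rgraph, rnet, sets[[k]])
    } else {
      for (k in seq_along(sets)) {
        gs <- sample(all_genes, length(sets[[k]]))
        null_vals[b, k, ] <- topology_stats_for_set(graph, net, gs)
      }
    }
  }
  stat_names <- c("char_path_length", "density", "in_degree_ratio")
  smaller_is_extreme <- c(TRUE, FALSE, FALSE)
  rows <- list()
  for (k in seq_along(sets)) {
    for (j in seq_along(stat_names)) {
      nv <- null_vals[, k, j]
      mu <- mean(nv, na.rm = TRUE)
      sdv <- sd(nv, na.rm = TRUE)
      z <- if (is.na(sdv) || sdv == 0) NA_real_ else (obs[k, j] - mu) / sdv
      p <- if (smaller_is_extreme[j]) mean(nv <= obs[k, j], na.rm = TRUE)
           else mean(nv >= obs[k, j], na.rm = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        subnetwork = names(sets)[k], statistic = stat_names[j],
        observed = obs[k, j], null_mean = mu, null_sd = sdv, z = z,
        p_empirical = p)
    }
  }
  out <- do.call(rbind, rows)
  ens <- do.call(rbind, lapply(stat_names, function(st) {
    sel <- out[out$statistic == st, ]
    data.frame(statistic = st, observed_mean = mean(sel$observed, na.rm = TRUE),
               null_mean = mean(sel$null_mean, na.rm = TRUE),
               z_mean = mean(sel$z, na.rm = TRUE))
  }))
  attr(out, "ensemble_means") <- ens
  out
}

#' Component Share Ratio (CSR)
#'
#' Jaccard overlap of two blocks' perturbed gene sets: intersection size
#' divided by union size. 1 means the two blocks regulate identical
#' network components; 0 means disjoint components.
#'
#' @param genes_i,genes_j nonempty gene sets.
#' @return ratio in [0, 1]; symmetric.
#' @export
csr <- function(genes_i, genes_j) {
  genes_i <- unique(genes_i); genes_j <- unique(genes_j)
  if (!length(genes_i) || !length(genes_j)) stop("CSR undefined for empty sets")
  length(intersect(genes_i, genes_j)) / length(union(genes_i, genes_j))
}

#' Contrast CSR distributions between block-pair groups
#'
#' Two-sided Wilcoxon rank-sum test comparing CSR values of same-chromosome
#' block pairs against different-chromosome pairs. The test is applied to
#' log-transformed values when all CSRs are positive; since ranks are
#' invariant under monotone transforms, the p-value is unaffected and raw
#' values are used when zeros are present.
#'
#' @param csr_same,csr_diff nonempty numeric CSR vectors.
#' @return htest object from [stats::wilcox.test()].
#' @export
csr_group_contrast <- function(csr_same, csr_diff) {
  stopifnot(length(csr_same) > 0, length(csr_diff) > 0)
  if (all(csr_same > 0) && all(csr_diff > 0)) {
    csr_same <- log(csr_same); csr_diff <- log(csr_diff)
  }
  suppressWarnings(wilcox.test(csr_same, csr_diff, alternative = "two.sided"))
}
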