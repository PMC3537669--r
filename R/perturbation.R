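empty_perturbation_records <- function() {
  data.frame(marker = character(), gene_a = character(), gene_b = character(),
             type = character(), kind = character(), r0 = numeric(),
             r1 = numeric(), dys = numeric(), p = numeric(), q = numeric())
}

#' Detect allele-specific co-perturbation (ASCP)
#'
#' An interaction is co-perturbed by an eQTL when both interacting genes
#' are significant expression targets of the same marker. One record is
#' emitted per such (marker, edge) pair; undirected edges are already
#' canonicalized by the interactome container, so output is deterministic
#' and order-independent.
#'
#' @param eqtl_hits data.frame with `marker` and `trait` columns (already
#'   thresholded by the caller, e.g. the output of [map_qtls()]).
#' @param net an [interactome()].
#' @return perturbation-record data.frame (kind "ASCP"; correlation fields
#'   `NA`).
#' @export
detect_ascp <- function(eqtl_hits, net) {
  if (!nrow(eqtl_hits)) return(empty_perturbation_records())
  targets_by_marker <- split(eqtl_hits$trait, eqtl_hits$marker)
  recs <- lapply(names(targets_by_marker), function(mk) {
    tg <- unique(targets_by_marker[[mk]])
    hit <- net$gene_a %in% tg & net$gene_b %in% tg
    if (!any(hit)) return(NULL)
    data.frame(marker = mk, gene_a = net$gene_a[hit], gene_b = net$gene_b[hit],
               type = net$type[hit], kind = "ASCP", r0 = NA_real_,
               r1 = NA_real_, dys = NA_real_, p = NA_real_, q = NA_real_)
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) return(empty_perturbation_records())
  out <- out[order(out$marker, out$gene_a, out$gene_b, out$type), ]
  rownames(out) <- NULL
  out
}

#' Allele-specific change in expression correlation (Dys)
#'
#' Splits strains into the two allele groups of a marker and computes the
#' Pearson correlation of the two genes' expression within each group;
#' Dys = |r0 - r1|.
#'
#' @param expr_a,expr_b numeric expression vectors (same strain order as
#'   `genotype_vector`).
#' @param genotype_vector 0/1 alleles per strain.
#' @param min_group_size smallest allele group allowed (default 3; Pearson
#'   correlation is degenerate below that).
#' @return list with `r0`, `r1`, `dys`.
#' @export
dys_statistic <- function(expr_a, expr_b, genotype_vector, min_group_size = 3) {
  i0 <- which(genotype_vector == 0)
  i1 <- which(genotype_vector == 1)
  if (length(i0) < min_group_size || length(i1) < min_group_size)
    stop(sprintf("allele group too small (%d / %d strains; need >= %d)",
                 length(i0), length(i1), min_group_size))
  if (sd(expr_a[i0]) == 0 || sd(expr_b[i0]) == 0 ||
      sd(expr_a[i1]) == 0 || sd(expr_b[i1]) == 0)
    stop("zero expression variance within an allele group")
  r0 <- cor(expr_a[i0], expr_b[i0])
  r1 <- cor(expr_a[i1], expr_b[i1])
  list(r0 = r0, r1 = r1, dys = abs(r0 - r1))
}

# correlations of many gene pairs within permuted groups, vectorised over
# permutations: P is a B x s 0/1 indicator of membership in group "1"
perm_group_cor <- function(P, x, y) {
  n1 <- rowSums(P)
  n0 <- ncol(P) - n1
  Sx1 <- as.vector(P %*% x); Sy1 <- as.vector(P %*% y)
  Sxy1 <- as.vector(P %*% (x * y))
  Sxx1 <- as.vector(P %*% (x * x)); Syy1 <- as.vector(P %*% (y * y))
  tx <- sum(x); ty <- sum(y); txy <- sum(x * y)
  txx <- sum(x * x); tyy <- sum(y * y)
  r_of <- function(Sx, Sy, Sxy, Sxx, Syy, n) {
    num <- Sxy - Sx * Sy / n
    den <- sqrt(pmax(Sxx - Sx^2 / n, 0) * pmax(Syy - Sy^2 / n, 0))
    ifelse(den > 0, num / den, NA_real_)
  }
  list(r1 = r_of(Sx1, Sy1, Sxy1, Sxx1, Syy1, n1),
       r0 = r_of(tx - Sx1, ty - Sy1, txy - Sxy1, txx - Sxx1, tyy - Syy1, n0))
}

#' Detect allele-specific dys-perturbation (ASDP)
#'
#' For every candidate (eQTL marker, interaction) pair, computes Dys =
#' |r0 - r1| between the marker's allele groups and tests it against
#' `n_perm` random reassignments of strains to two groups of the original
#' sizes. The permutation p-value is the frequency of null Dys values
#' strictly greater than the observed Dys, divided by `n_perm`.
#' Benjamini-Hochberg q-values are computed across all tested pairs and,
#' by default, records with q below `fdr_level` are returned.
#'
#' The default candidate universe pairs each eQTL marker with the
#' interactions incident to at least one of its significant target genes;
#' `candidates = "all"` scans every marker x edge combination instead
#' (quadratic).
#'
#' @param expression an [expression_panel()] or genes x strains matrix.
#' @param genotypes a [geno_panel()].
#' @param eqtl_hits thresholded hits (`marker`, `trait`), used to build the
#'   candidate universe.
#' @param net an [interactome()].
#' @param n_perm permutations (default 1000).
#' @param fdr_level BH threshold.
#' @param seed integer seed.
#' @param candidates `"eqtl"` (default) or `"all"`.
#' @param keep return only significant records or all tested.
#' @param min_group_size smallest allele group tested.
#' @return perturbation-record data.frame (kind "ASDP") with r0, r1, dys,
#'   p, q. Pairs skipped as degenerate are recorded in the
#'   `attr(, "skipped")` data.frame with a reason.
#' @export
detect_asdp <- function(expression, genotypes, eqtl_hits, net,
                        n_perm = 1000, fdr_level = 0.05, seed = 1L,
                        candidates = c("eqtl", "all"),
                        keep = c("significant", "all"),
                        min_group_size = 3) {
  candidates <- match.arg(candidates)
  keep <- match.arg(keep)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (inherits(expression, "expression_panel")) expression <- expression$values
  strains <- intersect(colnames(genotypes$calls), colnames(expression))
  G <- genotypes$calls[, strains, drop = FALSE]
  E <- expression[, strains, drop = FALSE]
  s <- length(strains)

  if (candidates == "eqtl") {
    if (!nrow(eqtl_hits)) return(empty_perturbation_records())
    targets_by_marker <- split(eqtl_hits$trait, eqtl_hits$marker)
    cand <- do.call(rbind, lapply(names(targets_by_marker), function(mk) {
      tg <- unique(targets_by_marker[[mk]])
      hit <- which(net$gene_a %in% tg | net$gene_b %in% tg)
      if (!length(hit)) return(NULL)
      data.frame(marker = mk, edge = hit)
    }))
  } else {
    cand <- expand.grid(marker = rownames(G), edge = seq_len(nrow(net)),
                        stringsAsFactors = FALSE)
  }
  if (is.null(cand) || !nrow(cand)) return(empty_perturbation_records())
  cand <- cand[net$gene_a[cand$edge] %in% rownames(E) &
                 net$gene_b[cand$edge] %in% rownames(E), , drop = FALSE]
  if (!nrow(cand)) return(empty_perturbation_records())

  set.seed(seed)
  rows <- vector("list", nrow(cand))
  skipped <- list()
  for (mk in unique(cand$marker)) {
    called <- which(!is.na(G[mk, ]))
    alle <- G[mk, called]
    n1 <- sum(alle == 1)
    n0 <- sum(alle == 0)
    idx <- which(cand$marker == mk)
    if (n1 < min_group_size || n0 < min_group_size) {
      skipped[[length(skipped) + 1]] <- data.frame(
        marker = mk, edge = cand$edge[idx],
        reason = sprintf("allele group too small (%d/%d)", n0, n1))
      next
    }
    # one set of size-preserving group reassignments per marker, shared
    # across that marker's candidate edges
    n_called <- length(called)
    P <- matrix(0, n_perm, n_called)
    for (b in seq_len(n_perm)) P[b, sample.int(n_called, n1)] <- 1
    for (i in idx) {
      e <- cand$edge[i]
      x <- E[net$gene_a[e], called]
      y <- E[net$gene_b[e], called]
      obs <- tryCatch(dys_statistic(x, y, alle, min_group_size),
                      error = function(c) NULL)
      if (is.null(obs)) {
        skipped[[length(skipped) + 1]] <- data.frame(
          marker = mk, edge = e, reason = "zero within-group variance")
        next
      }
      pr <- perm_group_cor(P, x, y)
      dys_star <- abs(pr$r0 - pr$r1)
      p <- sum(dys_star > obs$dys, na.rm = TRUE) / n_perm
      rows[[i]] <- data.frame(marker = mk, gene_a = net$gene_a[e],
                              gene_b = net$gene_b[e], type = net$type[e],
                              kind = "ASDP", r0 = obs$r0, r1 = obs$r1,
                              dys = obs$dys, p = p, q = NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty_perturbation_records()
  if (nrow(out)) {
    out$q <- bh_adjust(out$p)
    out <- out[order(out$q, out$p, out$marker, out$gene_a, out$gene_b), ]
    rownames(out) <- NULL
    if (keep == "significant") out <- out[out$q < fdr_level, , drop = FALSE]
  }
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  out
}

#' Assemble the co-perturbed (CPN) or dys-perturbed (DPN) network
#'
#' Takes the union of the edges over all records of the requested kind
#' (each typed edge once, regardless of how many markers perturb it) and
#' reports basic structure.
#'
#' @param records perturbation-record data.frame.
#' @param kind "ASCP" (giving the CPN) or "ASDP" (the DPN).
#' @return list of class `perturbed_network`: `edges` (an
#'   [interactome()]), `n_nodes`, `n_edges`, `largest_component_fraction`,
#'   and the node `degree` sequence (undirected simple view).
#' @export
build_perturbed_network <- function(records, kind = c("ASCP", "ASDP")) {
  kind <- match.arg(kind)
  rec <- records[records$kind == kind, , drop = FALSE]
  if (!nrow(rec)) {
    return(structure(list(edges = interactome(data.frame(gene_a = character(),
                                                         gene_b = character(),
                                                         type = character())),
                          n_nodes = 0L, n_edges = 0L,
                          largest_component_fraction = NA_real_,
                          degree = integer(0)),
                     class = "perturbed_network"))
  }
  edges <- suppressMessages(
    interactome(unique(rec[, c("gene_a", "gene_b", "type")])))
  g <- as_undirected_graph(edges)
  comp <- igraph::components(g)
  structure(list(edges = edges,
                 n_nodes = igraph::vcount(g),
                 n_edges = nrow(edges),
                 largest_component_fraction = max(comp$csize) / igraph::vcount(g),
                 degree = igraph::degree(g)),
            class = "perturbed_network")
}

#' @export
print.perturbed_network <- function(x, ...) {
  cat(sprintf("perturbed_network: %d nodes, %d typed edges, largest component %.1f%%\n",
              x$n_nodes, x$n_edges, 100 * x$largest_component_fraction))
  invisible(x)
}
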