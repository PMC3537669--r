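LARGE_T <- 1e6

#' Pooled-variance two-sample t statistics for all marker x trait pairs
#'
#' Vectorised engine behind linkage testing: partitions strains by each
#' marker's allele (0/1) and computes the equal-variance Student t contrast
#' of each trait between the two groups, for every marker and trait at
#' once. Sign follows mean(allele 1) - mean(allele 0).
#'
#' Monomorphic markers (one empty group) give `NA`. A zero pooled variance
#' gives 0 when the group means agree and a large finite guard value
#' (+/- 1e6) with a warning when they differ.
#'
#' @param G integer matrix markers x strains with values 0/1.
#' @param Y numeric matrix traits x strains (same strain order).
#' @param welch use Welch (unequal-variance) t instead of pooled.
#' @return numeric matrix markers x traits of t statistics.
#' @export
t_stat_matrix <- function(G, Y, welch = FALSE) {
  stopifnot(ncol(G) == ncol(Y))
  s <- ncol(G)
  storage.mode(G) <- "double"
  n1 <- rowSums(G)
  n0 <- s - n1
  S1 <- G %*% t(Y)
  Sq1 <- G %*% t(Y * Y)
  ty <- rowSums(Y)
  tq <- rowSums(Y * Y)
  mean1 <- S1 / n1
  mean0 <- sweep(-S1, 2, ty, "+") / n0
  ss1 <- pmax(Sq1 - n1 * mean1^2, 0)
  ss0 <- pmax(sweep(-Sq1, 2, tq, "+") - n0 * mean0^2, 0)
  d <- mean1 - mean0
  if (welch) {
    se2 <- ss1 / pmax(n1 - 1, 1) / n1 + ss0 / pmax(n0 - 1, 1) / n0
  } else {
    se2 <- (ss1 + ss0) / (s - 2) * (1 / n1 + 1 / n0)
  }
  t <- d / sqrt(se2)
  degenerate <- is.finite(d) & se2 <= 0
  if (any(degenerate & d != 0)) {
    warning("zero pooled variance with unequal means; returning large finite t")
    t[degenerate & d != 0] <- sign(d[degenerate & d != 0]) * LARGE_T
  }
  t[degenerate & d == 0] <- 0
  mono <- n1 == 0 | n0 == 0
  t[mono, ] <- NA_real_
  dimnames(t) <- list(rownames(G), rownames(Y))
  t
}

#' Linkage t statistic for one trait at one marker
#'
#' @param trait_values numeric vector of trait values per strain.
#' @param genotype_vector 0/1 alleles per strain.
#' @param welch use Welch's t.
#' @return signed t statistic (mean allele-1 group minus allele-0 group).
#' @export
linkage_t <- function(trait_values, genotype_vector, welch = FALSE) {
  stopifnot(length(trait_values) == length(genotype_vector))
  keep <- !is.na(trait_values) & !is.na(genotype_vector)
  g <- genotype_vector[keep]
  if (!any(g == 0) || !any(g == 1))
    stop("monomorphic marker: one allele group is empty")
  t_stat_matrix(matrix(g, nrow = 1), matrix(trait_values[keep], nrow = 1),
                welch = welch)[1, 1]
}

#' Merge adjacent markers with identical genotype profiles
#'
#' Maximal runs of position-adjacent markers (within a chromosome) whose
#' genotype vectors are identical collapse to their first marker. Identical
#' but non-adjacent markers, and identical markers on different
#' chromosomes, are left alone.
#'
#' @param genotypes a [geno_panel()] with markers position-sorted.
#' @return list with `genotypes` (merged panel) and `merge_map`
#'   (data.frame `marker`, `representative` inverting the merge).
#' @export
merge_identical_markers <- function(genotypes) {
  calls <- genotypes$calls
  map <- genotypes$map
  m <- nrow(calls)
  rep_idx <- integer(m)
  rep_idx[1] <- 1L
  for (i in seq_len(m)[-1]) {
    same_chrom <- map$chrom[i] == map$chrom[i - 1L]
    if (same_chrom && identical(calls[i, ], calls[i - 1L, ])) {
      rep_idx[i] <- rep_idx[i - 1L]
    } else {
      rep_idx[i] <- i
    }
  }
  keep <- sort(unique(rep_idx))
  merged <- geno_panel(calls[keep, , drop = FALSE],
                       {
                         mm <- map[keep, , drop = FALSE]
                         rownames(mm) <- NULL
                         mm
                       })
  merge_map <- data.frame(marker = map$marker,
                          representative = map$marker[rep_idx])
  list(genotypes = merged, merge_map = merge_map)
}

#' Expand merged-marker results back to the original marker set
#'
#' @param markers character vector of representative marker ids.
#' @param merge_map the map returned by [merge_identical_markers()].
#' @return all original markers represented by `markers`.
#' @export
expand_merged_markers <- function(markers, merge_map) {
  merge_map$marker[merge_map$representative %in% markers]
}

#' Broad-sense heritability of one trait
#'
#' H2 = (sigma2_seg - sigma2_parent_pooled) / sigma2_seg, where
#' sigma2_seg is the variance of the trait among segregants and
#' sigma2_parent_pooled the df-weighted pooled within-parent variance of
#' the replicate measurements. Significance by permutation: all parent and
#' segregant values are pooled and reassigned at random to null parents and
#' null segregants (preserving group sizes), H2 recomputed each time, and
#' p = #(null H2 >= observed) / n_perm.
#'
#' @param seg_values numeric vector (>= 3 segregant values).
#' @param parent_values_by_parent list of two numeric vectors (>= 2
#'   replicate values per parent).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `h2`, `sigma2_seg`, `sigma2_parent_pooled`, `p_perm`,
#'   and `undefined` (TRUE when sigma2_seg is zero; then `h2` is `NA` and
#'   no exception is raised).
#' @export
estimate_heritability <- function(seg_values, parent_values_by_parent,
                                  n_perm = 1000, seed = 1L) {
  stopifnot(length(parent_values_by_parent) == 2,
            all(lengths(parent_values_by_parent) >= 2),
            length(seg_values) >= 3)
  h2_of <- function(seg, pa, pb) {
    s2 <- var(seg)
    if (s2 == 0) return(c(NA_real_, s2, NA_real_))
    dfa <- length(pa) - 1L
    dfb <- length(pb) - 1L
    pooled <- (dfa * var(pa) + dfb * var(pb)) / (dfa + dfb)
    c((s2 - pooled) / s2, s2, pooled)
  }
  pa <- parent_values_by_parent[[1]]
  pb <- parent_values_by_parent[[2]]
  obs <- h2_of(seg_values, pa, pb)
  if (is.na(obs[1]))
    return(list(h2 = NA_real_, sigma2_seg = obs[2],
                sigma2_parent_pooled = NA_real_, p_perm = NA_real_,
                undefined = TRUE))
  set.seed(seed)
  pool <- c(seg_values, pa, pb)
  ns <- length(seg_values); na <- length(pa); nb <- length(pb)
  null_h2 <- vapply(seq_len(n_perm), function(b) {
    x <- sample(pool)
    h2_of(x[seq_len(ns)], x[ns + seq_len(na)], x[ns + na + seq_len(nb)])[1]
  }, numeric(1))
  p <- mean(null_h2 >= obs[1], na.rm = TRUE)
  list(h2 = obs[1], sigma2_seg = obs[2], sigma2_parent_pooled = obs[3],
       p_perm = p, undefined = FALSE)
}

#' Heritability scan over an expression panel
#'
#' Applies [estimate_heritability()] to every gene, using the panel's
#' parental replicate matrices, and attaches Benjamini-Hochberg q-values
#' across genes.
#'
#' @param expr an [expression_panel()] with parental replicates.
#' @param n_perm permutations per gene.
#' @param seed integer seed.
#' @param fdr_level BH threshold used to set `passes_fdr`.
#' @return data.frame: trait, h2, sigma2_seg, sigma2_parent_pooled,
#'   p_perm, q, passes_fdr.
#' @export
heritability_scan <- function(expr, n_perm = 1000, seed = 1L, fdr_level = 0.05) {
  if (is.null(expr$parent_a) || is.null(expr$parent_b))
    stop("expression panel has no parental replicates")
  genes <- rownames(expr$values)
  recs <- lapply(seq_along(genes), function(i) {
    r <- estimate_heritability(expr$values[i, ],
                               list(expr$parent_a[i, ], expr$parent_b[i, ]),
                               n_perm = n_perm, seed = seed + i)
    data.frame(trait = genes[i], h2 = r$h2, sigma2_seg = r$sigma2_seg,
               sigma2_parent_pooled = r$sigma2_parent_pooled,
               p_perm = r$p_perm)
  })
  out <- do.call(rbind, recs)
  out$q <- NA_real_
  ok <- !is.na(out$p_perm)
  out$q[ok] <- bh_adjust(out$p_perm[ok])
  out$passes_fdr <- !is.na(out$q) & out$q <= fdr_level
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment; q-values are monotone in p and
#' clipped to 1.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Genome-wide QTL mapping with permutation significance
#'
#' For every marker x trait pair, computes the two-group linkage t
#' statistic, then assesses significance by permuting strain labels
#' `n_perm` times. With `null_pool = "trait"` (default) the null |t|
#' distribution for a trait pools the permuted statistics across all
#' markers of that trait (genome-wide null); with `"pair"` each pair uses
#' only its own marker's permuted values. The permutation p-value is the
#' plain frequency #(|t*| >= |t|) / pool size (weak inequality); set
#' `add_one = TRUE` for the conservative (+1)/(B+1) variant.
#' Benjamini-Hochberg q-values are computed across all testable pairs.
#'
#' @param genotypes a [geno_panel()].
#' @param traits numeric matrix traits x strains, or an
#'   [expression_panel()] (its `values` are used). Column names must
#'   overlap the genotype strain names; shared strains are aligned.
#' @param n_perm number of label permutations (>= 1).
#' @param fdr_level BH threshold used when `keep = "significant"`.
#' @param seed integer seed.
#' @param null_pool `"trait"` or `"pair"` (see above).
#' @param keep return only significant hits or all tests.
#' @param add_one use the (+1)/(B+1) p-value variant.
#' @param welch use Welch's t.
#' @return data.frame of hits: marker, trait, t, p, q, cis (`NA` until
#'   [classify_cis_trans()] is applied), ordered by q then p.
#' @export
map_qtls <- function(genotypes, traits, n_perm = 1000, fdr_level = 0.05,
                     seed = 1L, null_pool = c("trait", "pair"),
                     keep = c("significant", "all"), add_one = FALSE,
                     welch = FALSE) {
  null_pool <- match.arg(null_pool)
  keep <- match.arg(keep)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (inherits(traits, "expression_panel")) traits <- traits$values
  traits <- as.matrix(traits)
  strains <- intersect(colnames(genotypes$calls), colnames(traits))
  if (!length(strains)) stop("no shared strains between genotypes and traits")
  G <- genotypes$calls[, strains, drop = FALSE]
  Y <- traits[, strains, drop = FALSE]
  s <- length(strains)

  t_obs <- t_stat_matrix(G, Y, welch = welch)
  abs_obs <- abs(t_obs)
  m <- nrow(G); g <- nrow(Y)

  set.seed(seed)
  if (null_pool == "pair") {
    cnt <- matrix(0, m, g)
    for (b in seq_len(n_perm)) {
      tb <- abs(t_stat_matrix(G, Y[, sample.int(s), drop = FALSE], welch = welch))
      cnt <- cnt + (tb >= abs_obs)
    }
    denom <- n_perm
  } else {
    # per trait, pool permuted |t| across markers; count with sorted obs
    ord <- matrix(apply(abs_obs, 2, order), nrow = m)
    cnt <- matrix(0, m, g)
    for (b in seq_len(n_perm)) {
      tb <- abs(t_stat_matrix(G, Y[, sample.int(s), drop = FALSE], welch = welch))
      for (j in seq_len(g)) {
        v <- tb[, j]
        v <- sort(v[!is.na(v)])
        oj <- ord[, j]
        obs_sorted <- abs_obs[oj, j]
        ge <- length(v) - findInterval(obs_sorted, v, left.open = TRUE)
        cnt[oj, j] <- cnt[oj, j] + ge
      }
    }
    n_valid <- sum(!is.na(t_obs[, 1]))
    denom <- n_perm * n_valid
  }
  p <- if (add_one) (cnt + 1) / (denom + 1) else cnt / denom
  p[is.na(t_obs)] <- NA_real_

  out <- data.frame(marker = rep(rownames(G), times = g),
                    trait = rep(rownames(Y), each = m),
                    t = as.vector(t_obs),
                    p = as.vector(p))
  out <- out[!is.na(out$t), , drop = FALSE]
  out$q <- bh_adjust(out$p)
  out$cis <- NA_character_
  out <- out[order(out$q, out$p, out$marker, out$trait), , drop = FALSE]
  rownames(out) <- NULL
  if (keep == "significant") out <- out[out$q <= fdr_level, , drop = FALSE]
  out
}

#' Classify QTL hits as cis or trans
#'
#' A hit is cis when its marker lies on the same chromosome as the trait
#' gene and the distance between the marker position and the gene interval
#' is at most `window_bp` (a marker inside the gene span has distance 0);
#' trans otherwise; unknown when the gene has no recorded position.
#'
#' @param hits data.frame with `marker` and `trait` columns.
#' @param marker_map data.frame `marker`, `chrom`, `pos`.
#' @param gene_map data.frame `gene`, `chrom`, `start`, `end`.
#' @param window_bp cis window (default 10 kb, inclusive).
#' @return `hits` with the `cis` column set to "cis"/"trans"/"unknown".
#' @export
classify_cis_trans <- function(hits, marker_map, gene_map, window_bp = 10000) {
  mi <- match(hits$marker, marker_map$marker)
  gi <- match(hits$trait, gene_map$gene)
  res <- rep("unknown", nrow(hits))
  known <- !is.na(mi) & !is.na(gi)
  same <- known & marker_map$chrom[mi] == gene_map$chrom[gi]
  pos <- marker_map$pos[mi]
  d <- pmax(gene_map$start[gi] - pos, pos - gene_map$end[gi], 0)
  res[known] <- "trans"
  res[same & d <= window_bp] <- "cis"
  hits$cis <- res
  hits
}

#' K-nearest-neighbour imputation of missing expression values
#'
#' Each missing entry is replaced by the mean of that column's values over
#' the `k` nearest gene rows, where distance is the root mean squared
#' difference over columns observed in both rows and only rows observed in
#' the target column are candidates. Observed entries are untouched.
#'
#' @param mat numeric matrix (genes x strains) possibly containing `NA`.
#' @param k neighbour count (default 15).
#' @return the matrix with missing entries filled.
#' @export
knn_impute_expression <- function(mat, k = 15) {
  mat <- as.matrix(mat)
  all_missing <- rowSums(!is.na(mat)) == 0
  if (any(all_missing))
    stop(sprintf("row(s) with no observed values: %s",
                 paste(rownames(mat)[all_missing], collapse = ", ")))
  miss <- which(is.na(mat), arr.ind = TRUE)
  if (!nrow(miss)) return(mat)
  out <- mat
  for (i in unique(miss[, 1])) {
    cols <- miss[miss[, 1] == i, 2]
    xi <- mat[i, ]
    obs_i <- !is.na(xi)
    diff2 <- sweep(mat, 2, xi)^2
    shared <- sweep(!is.na(mat), 2, obs_i, "&")
    n_shared <- rowSums(shared)
    d <- sqrt(rowSums(diff2 * shared, na.rm = TRUE) / n_shared)
    d[i] <- Inf
    d[n_shared == 0] <- Inf
    for (j in cols) {
      cand <- which(!is.na(mat[, j]) & is.finite(d))
      if (!length(cand))
        stop(sprintf("no donor rows observed in column %d for row '%s'",
                     j, rownames(mat)[i]))
      nb <- cand[order(d[cand])[seq_len(min(k, length(cand)))]]
      out[i, j] <- mean(mat[nb, j])
    }
  }
  out
}
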