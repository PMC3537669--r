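test_that("adjacent identical markers merge into runs, non-adjacent ones do not", {
  calls <- rbind(c(0, 0, 1, 1), c(0, 0, 1, 1), c(0, 0, 1, 1),
                 c(1, 0, 1, 0), c(0, 0, 1, 1))
  g <- toy_geno(calls)
  m <- merge_identical_markers(g)
  expect_equal(rownames(m$genotypes$calls), c("m01", "m04", "m05"))
  expect_equal(m$merge_map$representative,
               c("m01", "m01", "m01", "m04", "m05"))
  # same profile on different chromosomes stays separate
  g2 <- toy_geno(rbind(c(0, 1), c(0, 1)), chrom = c("chr01", "chr02"),
                 pos = c(100, 100))
  expect_equal(nrow(merge_identical_markers(g2)$genotypes$calls), 2)
  # round trip: expanding every representative recovers the original set
  expect_setequal(expand_merged_markers(rownames(m$genotypes$calls), m$merge_map),
                  g$map$marker)
})

test_that("merged representative count matches a run-length oracle on a simulated panel", {
  ds <- simulate_cross(tiny_config(recomb_prob = 0.02, n_strains = 20, seed = 5))
  g <- ds$genotypes
  m <- merge_identical_markers(g)
  prof <- apply(g$calls, 1, paste, collapse = "")
  runs <- sum(vapply(unique(g$map$chrom), function(ch) {
    p <- prof[g$map$chrom == ch]
    1L + sum(p[-1] != p[-length(p)])
  }, integer(1)))
  expect_equal(nrow(m$genotypes$calls), runs)
})

test_that("heritability follows its variance-ratio definition", {
  # constant parents: all segregant variance is heritable
  r <- estimate_heritability(c(1, 2, 3, 4), list(c(2, 2), c(3, 3)), n_perm = 50)
  expect_equal(r$h2, 1)
  expect_equal(r$sigma2_seg, var(c(1, 2, 3, 4)))
  expect_equal(r$sigma2_parent_pooled, 0)
  # segregant variance equal to pooled parental variance: nothing heritable
  set.seed(1)
  seg <- c(-1, 0, 1)
  r0 <- estimate_heritability(seg, list(c(-1, 0, 1), c(-1, 0, 1)), n_perm = 50)
  expect_equal(r0$h2, 0)
  # df-weighted pooling, recomputed independently
  seg <- c(5, 1, 4, 2, 8)
  pa <- c(2, 4, 3); pb <- c(7, 9)
  r2 <- estimate_heritability(seg, list(pa, pb), n_perm = 50)
  pooled <- (2 * var(pa) + 1 * var(pb)) / 3
  expect_equal(r2$sigma2_parent_pooled, pooled)
  expect_equal(r2$h2, (var(seg) - pooled) / var(seg))
  # zero segregant variance flags the record instead of erroring
  rz <- estimate_heritability(c(1, 1, 1), list(c(1, 2), c(3, 4)), n_perm = 10)
  expect_true(rz$undefined)
  expect_true(is.na(rz$h2))
})

test_that("linkage t is the pooled-variance two-sample statistic", {
  expect_equal(linkage_t(c(1, 2, 3, 1, 2, 3), c(0, 0, 0, 1, 1, 1)), 0)
  tv <- linkage_t(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(abs(tv), 3.674235, tolerance = 1e-6)
  expect_equal(tv,
               unname(t.test(c(4, 5, 6), c(1, 2, 3), var.equal = TRUE)$statistic))
  expect_error(linkage_t(1:4, c(0, 0, 0, 0)), "monomorphic")
  # |t| distribution is label-exchangeable
  set.seed(2)
  y <- rnorm(20); g <- rep(c(0, 1), 10)
  t1 <- abs(linkage_t(y, g))
  perm <- replicate(500, abs(linkage_t(y, sample(g))))
  expect_gt(mean(perm >= t1), 0.01)

  # matrix engine agrees with the scalar definition across many pairs
  set.seed(3)
  G <- matrix(rbinom(5 * 30, 1, 0.5), 5, 30,
              dimnames = list(sprintf("m%d", 1:5), sprintf("s%d", 1:30)))
  Y <- matrix(rnorm(4 * 30), 4, 30,
              dimnames = list(sprintf("g%d", 1:4), sprintf("s%d", 1:30)))
  tm <- t_stat_matrix(G, Y)
  for (i in 1:5) for (j in 1:4)
    expect_equal(tm[i, j], linkage_t(Y[j, ], G[i, ]))
})

test_that("benjamini-hochberg adjustment matches the step-up recurrence", {
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(4)
  for (rep in 1:5) {
    p <- runif(37)^2
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  p <- sort(runif(20))
  expect_true(all(diff(bh_adjust(p)) >= 0))
})

test_that("permutation p-values behave at the boundary and match the analytic t test in the limit", {
  set.seed(5)
  # one huge planted effect: observed |t| beats every null draw -> p = 0
  g <- toy_geno(matrix(rep(c(0, 1), each = 10), 1, 20))
  y <- matrix(c(rnorm(10), rnorm(10) + 50), 1, 20,
              dimnames = list("g1", colnames(g$calls)))
  hits <- map_qtls(g, y, n_perm = 200, keep = "all", seed = 6)
  expect_equal(hits$p, 0)

  # per-pair null with many permutations converges to the analytic p
  set.seed(7)
  g2 <- toy_geno(matrix(rbinom(40, 1, 0.5), 1, 40))
  y2 <- matrix(rnorm(40) + 0.8 * g2$calls[1, ], 1, 40,
               dimnames = list("g1", colnames(g2$calls)))
  B <- 20000
  hits2 <- map_qtls(g2, y2, n_perm = B, keep = "all", null_pool = "pair",
                    seed = 8)
  t_obs <- hits2$t
  p_analytic <- 2 * pt(abs(t_obs), df = 38, lower.tail = FALSE)
  mc_se <- sqrt(p_analytic * (1 - p_analytic) / B)
  expect_lt(abs(hits2$p - p_analytic), 4 * mc_se + 1e-4)

  # the (+1)/(B+1) variant never returns zero
  hits3 <- map_qtls(g, y, n_perm = 50, keep = "all", add_one = TRUE, seed = 9)
  expect_equal(hits3$p, 1 / 51)
  expect_error(map_qtls(g, y, n_perm = 0), "n_perm")
})

test_that("permutation p-values are super-uniform under the global null", {
  set.seed(10)
  g <- toy_geno(matrix(rbinom(6 * 112, 1, 0.5), 6, 112))
  y <- matrix(rnorm(8 * 112), 8, 112,
              dimnames = list(sprintf("g%d", 1:8), colnames(g$calls)))
  hits <- map_qtls(g, y, n_perm = 300, keep = "all", seed = 11)
  for (a in c(0.1, 0.25, 0.5))
    expect_lt(mean(hits$p <= a), a + 3 * sqrt(a * (1 - a) / nrow(hits)))
})

test_that("cis/trans classification applies the 10 kb rule inclusively", {
  marker_map <- data.frame(marker = c("m1", "m2", "m3", "m4"),
                           chrom = c("chr1", "chr1", "chr1", "chr2"),
                           pos = c(5500, 16001, 3000, 5500))
  gene_map <- data.frame(gene = c("gA", "gB"), chrom = c("chr1", "chr1"),
                         start = c(5000, 50000), end = c(6000, 51000))
  hits <- data.frame(marker = c("m1", "m2", "m3", "m4", "m1"),
                     trait = c("gA", "gA", "gA", "gA", "gX"))
  out <- classify_cis_trans(hits, marker_map, gene_map)
  expect_equal(out$cis, c("cis",     # inside the gene span: distance 0
                          "trans",   # 10,001 bp away: strict <= 10 kb
                          "cis",     # 2,000 bp upstream
                          "trans",   # other chromosome
                          "unknown"))
  # marker exactly 10,000 bp away is still cis
  out2 <- classify_cis_trans(data.frame(marker = "m2", trait = "gA"),
                             data.frame(marker = "m2", chrom = "chr1", pos = 16000),
                             gene_map)
  expect_equal(out2$cis, "cis")
})

test_that("cis/trans labels agree with a brute-force distance scan on random placements", {
  set.seed(12)
  marker_map <- data.frame(marker = sprintf("m%d", 1:50),
                           chrom = sample(c("c1", "c2"), 50, TRUE),
                           pos = sample.int(1e5, 50))
  gene_map <- data.frame(gene = sprintf("g%d", 1:20),
                         chrom = sample(c("c1", "c2"), 20, TRUE),
                         start = sample.int(1e5, 20))
  gene_map$end <- gene_map$start + 500
  hits <- expand.grid(marker = marker_map$marker, trait = gene_map$gene,
                      stringsAsFactors = FALSE)
  out <- classify_cis_trans(hits, marker_map, gene_map)
  for (i in sample.int(nrow(out), 200)) {
    mm <- marker_map[marker_map$marker == out$marker[i], ]
    gg <- gene_map[gene_map$gene == out$trait[i], ]
    d <- if (mm$pos >= gg$start && mm$pos <= gg$end) 0 else
      min(abs(mm$pos - gg$start), abs(mm$pos - gg$end))
    expected <- if (mm$chrom == gg$chrom && d <= 10000) "cis" else "trans"
    expect_equal(out$cis[i], expected)
  }
})

test_that("knn imputation restores structure and beats the column-mean baseline", {
  m <- matrix(rnorm(20), 4, 5, dimnames = list(letters[1:4], LETTERS[1:5]))
  expect_identical(knn_impute_expression(m), m)

  # a masked entry in a duplicated row is restored from its twin
  m2 <- rbind(m, twin = m[1, ])
  m2["twin", 3] <- NA
  out <- knn_impute_expression(m2, k = 1)
  expect_equal(out["twin", 3], m[1, 3])

  set.seed(13)
  base <- matrix(rnorm(50 * 30), 50, 30)
  corr <- base[rep(1:10, each = 5), ] + matrix(rnorm(50 * 30, sd = 0.2), 50, 30)
  dimnames(corr) <- list(sprintf("g%d", 1:50), sprintf("s%d", 1:30))
  mask <- matrix(runif(length(corr)) < 0.05, nrow(corr))
  masked <- corr; masked[mask] <- NA
  knn <- knn_impute_expression(masked, k = 5)
  colmean <- masked
  for (j in seq_len(ncol(colmean)))
    colmean[is.na(colmean[, j]), j] <- mean(colmean[, j], na.rm = TRUE)
  rmse <- function(x) sqrt(mean((x[mask] - corr[mask])^2))
  expect_lt(rmse(knn), rmse(colmean))

  m3 <- m; m3[2, ] <- NA
  expect_error(knn_impute_expression(m3), "b")
})
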