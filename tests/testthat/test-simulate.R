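test_that("cross simulation is a two-state Markov chain with the configured switch rate", {
  cfg0 <- tiny_config(recomb_prob = 0, n_chromosomes = 2,
                      n_markers_per_chrom = 20, n_strains = 30)
  g0 <- simulate_cross(cfg0)$genotypes
  for (ch in unique(g0$map$chrom)) {
    sub <- g0$calls[g0$map$chrom == ch, ]
    expect_true(all(apply(sub, 2, function(col) length(unique(col)) == 1)))
  }

  cfg5 <- tiny_config(recomb_prob = 0.5, n_strains = 2000, n_chromosomes = 1,
                      n_markers_per_chrom = 30)
  g5 <- simulate_cross(cfg5)$genotypes
  r2 <- vapply(seq_len(29), function(i)
    cor(g5$calls[i, ], g5$calls[i + 1, ])^2, numeric(1))
  expect_lt(mean(r2), 0.01)

  # LD decays with distance at intermediate recombination
  cfgl <- tiny_config(recomb_prob = 0.05, n_strains = 1000, n_chromosomes = 1,
                      n_markers_per_chrom = 60)
  gl <- simulate_cross(cfgl)$genotypes
  r2_adj <- mean(vapply(seq_len(59), function(i)
    cor(gl$calls[i, ], gl$calls[i + 1, ])^2, numeric(1)))
  r2_far <- mean(vapply(seq_len(30), function(i)
    cor(gl$calls[i, ], gl$calls[i + 30, ])^2, numeric(1)))
  expect_gt(r2_adj, r2_far)

  expect_true(all(tapply(g0$map$pos, g0$map$chrom, function(p) all(diff(p) > 0))))
})

test_that("fixed seed reproduces the full dataset bit for bit", {
  d1 <- simulate_dataset(tiny_config(seed = 11))
  d2 <- simulate_dataset(tiny_config(seed = 11))
  expect_identical(d1$genotypes$calls, d2$genotypes$calls)
  expect_identical(d1$expression$values, d2$expression$values)
  expect_identical(as.data.frame(d1$net), as.data.frame(d2$net))
  expect_identical(d1$phenotypes, d2$phenotypes)
  d3 <- simulate_dataset(tiny_config(seed = 12))
  expect_false(identical(d1$genotypes$calls, d3$genotypes$calls))
})

test_that("expression carries planted effects with the configured geometry", {
  # noise-free limit: allele groups differ by exactly the planted effect
  cfg <- tiny_config(noise_sd = 0, n_planted_eqtls = 1, n_planted_ascp = 0,
                     n_planted_asdp = 0, effect_size = 1, n_strains = 40)
  ds <- simulate_dataset(cfg)
  pe <- ds$truth$planted_eqtls[1, ]
  alle <- ds$genotypes$calls[pe$marker, ]
  ev <- ds$expression$values[pe$gene, ]
  expect_equal(mean(ev[alle == 1]) - mean(ev[alle == 0]), 1)

  # planted ASDP pair reaches its target Dys at large n
  cfg2 <- tiny_config(n_strains = 500, n_planted_eqtls = 0, n_planted_ascp = 0,
                      n_planted_asdp = 1, dys_delta = 0.9, seed = 21)
  ds2 <- simulate_dataset(cfg2)
  pa <- ds2$truth$planted_asdp[1, ]
  alle <- ds2$genotypes$calls[pa$marker, ]
  d <- dys_statistic(ds2$expression$values[pa$gene_a, ],
                     ds2$expression$values[pa$gene_b, ], alle)
  expect_lt(abs(d$dys - 0.9), 0.1)

  # dangling planted references are an integrity error
  bad <- ds$truth
  bad$planted_eqtls <- rbind(bad$planted_eqtls,
                             data.frame(marker = "nope", gene = "G0001", effect = 1))
  expect_error(simulate_expression(ds$genotypes, bad, cfg), "unknown")
})

test_that("without planted effects linkage statistics follow the Student t null", {
  cfg <- tiny_config(n_planted_eqtls = 0, n_planted_ascp = 0,
                     n_planted_asdp = 0, n_strains = 112, n_chromosomes = 1,
                     n_markers_per_chrom = 40, n_genes = 5, recomb_prob = 0.5,
                     edge_counts_by_type = c(PPI = 8), seed = 31)
  ds <- simulate_dataset(cfg)
  t_obs <- t_stat_matrix(ds$genotypes$calls, ds$expression$values)
  t_obs <- t_obs[!is.na(t_obs)]
  # markers are in LD so thin to ~200 weakly dependent pairs
  t_obs <- t_obs[seq(1, length(t_obs), length.out = 200)]
  ks <- suppressWarnings(ks.test(t_obs, pt, df = 110))
  expect_gt(ks$p.value, 0.01)
})

test_that("interactome generator honours counts, types, and heavy-tailed degrees", {
  net <- simulate_interactome(50, c(PPI = 49), seed = 3)
  expect_equal(nrow(net), 49)
  expect_equal(unique(net$type), "PPI")
  expect_false(any(duplicated(paste(net$gene_a, net$gene_b))))
  expect_true(all(net$gene_a < net$gene_b))  # undirected canonical order

  net2 <- simulate_interactome(2000, c(PPI = 3000, PDI = 1500, KPI = 1000,
                                       EEI = 500), seed = 4)
  expect_equal(as.list(table(net2$type)),
               list(EEI = 500L, KPI = 1000L, PDI = 1500L, PPI = 3000L))
  deg <- table(c(net2$gene_a, net2$gene_b))
  dd <- sort(as.integer(deg), decreasing = TRUE)
  fit <- coef(lm(log(dd) ~ log(seq_along(dd))))[2]
  expect_lt(fit, 0)
  # heavier tail than a same-size Erdos-Renyi control
  er <- igraph::sample_gnm(2000, 6000)
  expect_gt(max(dd), max(igraph::degree(er)))

  expect_error(simulate_interactome(5, c(PPI = 100), seed = 1), "exceeds")

  net3 <- simulate_interactome(100, c(PPI = 150, PDI = 50), seed = 9)
  net4 <- simulate_interactome(100, c(PPI = 150, PDI = 50), seed = 9)
  expect_identical(as.data.frame(net3), as.data.frame(net4))
})

test_that("SMP phenotype generator plants mappable QTLs and matching target sets", {
  ds <- simulate_dataset(tiny_config(seed = 41))
  sq <- ds$truth$planted_smp_qtls
  expect_true(all(sq$marker %in% rownames(ds$genotypes$calls)))
  # planted target sets contain the perturbed endpoint genes of the QTL marker
  for (i in seq_len(min(3, nrow(sq)))) {
    mk <- sq$marker[i]; cp <- sq$compound[i]
    pert <- rbind(ds$truth$planted_ascp[, c("marker", "gene_a", "gene_b")],
                  ds$truth$planted_asdp[, c("marker", "gene_a", "gene_b")])
    core <- unique(c(pert$gene_a[pert$marker == mk], pert$gene_b[pert$marker == mk]))
    expect_true(all(core %in% ds$target_sets[[cp]]))
  }

  # zero-noise planted QTL: degenerate variance guard yields a large finite t
  cfg <- tiny_config(noise_sd = 0, n_planted_eqtls = 0, n_planted_ascp = 1,
                     n_planted_asdp = 0, n_planted_smp_qtls = 1,
                     n_compounds = 1, conditions_per_compound = 1, seed = 42)
  ds0 <- simulate_dataset(cfg)
  y <- as.numeric(ds0$phenotypes[1, -(1:3)])
  alle <- ds0$genotypes$calls[ds0$truth$planted_smp_qtls$marker[1], ]
  expect_warning(tv <- linkage_t(y, alle), "large finite")
  expect_true(is.finite(tv) && abs(tv) > 1e5)
})

test_that("emitted identifiers cross-reference across panel, map, and network", {
  ds <- simulate_dataset(tiny_config(seed = 51))
  expect_true(all(rownames(ds$genotypes$calls) == ds$genotypes$map$marker))
  expect_true(all(ds$truth$planted_eqtls$marker %in% ds$genotypes$map$marker))
  expect_true(all(ds$truth$planted_eqtls$gene %in% ds$truth$gene_map$gene))
  expect_true(all(rownames(ds$expression$values) %in% ds$truth$gene_map$gene))
  key_net <- paste(ds$net$gene_a, ds$net$gene_b, ds$net$type)
  key_ascp <- with(ds$truth$planted_ascp, paste(gene_a, gene_b, type))
  key_asdp <- with(ds$truth$planted_asdp, paste(gene_a, gene_b, type))
  expect_true(all(c(key_ascp, key_asdp) %in% key_net))
})
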