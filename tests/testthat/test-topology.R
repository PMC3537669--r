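test_that("characteristic path length is measured in the full network", {
  path3 <- toy_net(gene_a = c("A", "B"), gene_b = c("B", "C"), type = "PPI")
  # the two ends of a path of length 2, measured through the full graph
  expect_equal(characteristic_path_length(path3, c("A", "C"))$length, 2)
  clique <- toy_net(gene_a = c("A", "A", "B"), gene_b = c("B", "C", "C"),
                    type = "PPI")
  expect_equal(characteristic_path_length(clique, c("A", "B", "C"))$length, 1)
  # disconnected pairs are excluded and their fraction reported
  two <- toy_net(gene_a = c("A", "C"), gene_b = c("B", "D"), type = "PPI")
  r <- characteristic_path_length(two, c("A", "B", "C"))
  expect_equal(r$length, 1)
  expect_equal(r$excluded_fraction, 2 / 3)
  expect_error(characteristic_path_length(path3, "A"), "two genes")
})

test_that("path lengths agree with a hand BFS oracle on random sets", {
  set.seed(31)
  net <- simulate_interactome(200, c(PPI = 400, PDI = 100), seed = 32)
  pair <- unique(data.frame(a = pmin(net$gene_a, net$gene_b),
                            b = pmax(net$gene_a, net$gene_b)))
  for (rep in 1:5) {
    gs <- sample(interactome_genes(net), 6)
    r <- characteristic_path_length(net, gs)
    d <- c()
    for (i in 1:5) for (j in (i + 1):6)
      d <- c(d, bfs_distance(pair$a, pair$b, gs[i], gs[j]))
    expect_equal(r$length, mean(d[is.finite(d)]))
    expect_equal(r$excluded_fraction, mean(!is.finite(d)))
  }
})

test_that("density counts unordered gene pairs once across edge types", {
  tri <- subnetwork("t", c("A", "B", "C"),
                    data.frame(gene_a = c("A", "B", "A"), gene_b = c("B", "C", "C"),
                               type = "PPI"))
  expect_equal(subnetwork_density(tri), 1)
  one <- subnetwork("o", c("A", "B", "C"),
                    data.frame(gene_a = "A", gene_b = "B", type = "PPI"))
  expect_equal(subnetwork_density(one), 1 / 3)
  # a parallel typed edge between the same pair does not inflate density
  dup <- subnetwork("d", c("A", "B"),
                    data.frame(gene_a = c("A", "A"), gene_b = c("B", "B"),
                               type = c("PPI", "EEI")))
  expect_equal(subnetwork_density(dup), 1)
  expect_warning(subnetwork_density(subnetwork("s", "A",
                                               data.frame(gene_a = character(),
                                                          gene_b = character(),
                                                          type = character()))),
                 "undefined")
  set.seed(33)
  net <- simulate_interactome(30, c(PPI = 60, EEI = 30), seed = 34)
  for (rep in 1:5) {
    gs <- sample(interactome_genes(net), 8)
    sub <- suppressMessages(extract_subnetwork(net, gs))
    pairs <- unique(paste(pmin(sub$edges$gene_a, sub$edges$gene_b),
                          pmax(sub$edges$gene_a, sub$edges$gene_b)))
    n <- length(sub$genes)
    expect_equal(subnetwork_density(sub), 2 * length(pairs) / (n * (n - 1)))
  }
})

test_that("in-degree ratio classifies within and boundary edges", {
  star <- toy_net(gene_a = rep("H", 4), gene_b = c("X", "Y", "Z", "W"),
                  type = "PPI")
  expect_equal(in_degree_ratio(star, "H"), 0)  # 0 within / 4 boundary
  # isolated clique component: no boundary edges -> flagged infinite
  two_comp <- toy_net(gene_a = c("A", "B", "A", "X"), gene_b = c("B", "C", "C", "Y"),
                      type = "PPI")
  r <- in_degree_ratio(two_comp, c("A", "B", "C"))
  expect_true(is.infinite(r))
  expect_true(isTRUE(attr(r, "boundary_free")))
  set.seed(35)
  net <- simulate_interactome(50, c(PPI = 120), seed = 36)
  pair <- unique(data.frame(a = pmin(net$gene_a, net$gene_b),
                            b = pmax(net$gene_a, net$gene_b)))
  for (rep in 1:5) {
    gs <- sample(interactome_genes(net), 12)
    within <- sum(pair$a %in% gs & pair$b %in% gs)
    boundary <- sum(xor(pair$a %in% gs, pair$b %in% gs))
    got <- in_degree_ratio(net, gs)
    if (boundary == 0) expect_true(is.infinite(got))
    else expect_equal(got, within / boundary)
  }
})

test_that("degree-preserving randomization keeps per-type degrees and mixes edges", {
  net <- simulate_interactome(2000, c(PPI = 3000, PDI = 1500, KPI = 1000,
                                      EEI = 500), seed = 37)
  rnd <- maslov_sneppen_randomize(net, swaps_per_edge = 100, seed = 38)
  expect_equal(as.list(table(rnd$type)), as.list(table(net$type)))
  for (ty in unique(net$type)) {
    a <- net[net$type == ty, ]; b <- rnd[rnd$type == ty, ]
    if (ty %in% c("PDI", "KPI")) {
      expect_equal(table(b$gene_a)[sort(unique(a$gene_a))],
                   table(a$gene_a)[sort(unique(a$gene_a))])
      expect_equal(table(b$gene_b)[sort(unique(a$gene_b))],
                   table(a$gene_b)[sort(unique(a$gene_b))])
    } else {
      expect_equal(sort(table(c(b$gene_a, b$gene_b))),
                   sort(table(c(a$gene_a, a$gene_b))), ignore_attr = TRUE)
      expect_equal(table(c(b$gene_a, b$gene_b))[sort(unique(c(a$gene_a, a$gene_b)))],
                   table(c(a$gene_a, a$gene_b))[sort(unique(c(a$gene_a, a$gene_b)))])
    }
    # no duplicates within a type
    expect_false(any(duplicated(paste(b$gene_a, b$gene_b))))
  }
  expect_false(any(rnd$gene_a == rnd$gene_b))
  # mixing: most edges moved after 100 swaps per edge
  overlap <- mean(paste(rnd$gene_a, rnd$gene_b, rnd$type) %in%
                    paste(net$gene_a, net$gene_b, net$type))
  expect_lt(overlap, 0.5)
  # a 4-cycle stays a valid simple graph with the same degrees
  cyc <- toy_net(gene_a = c("A", "B", "C", "A"), gene_b = c("B", "C", "D", "D"),
                 type = "PPI")
  rc <- maslov_sneppen_randomize(cyc, swaps_per_edge = 10, seed = 39)
  expect_equal(nrow(rc), 4)
  expect_equal(sort(table(c(rc$gene_a, rc$gene_b))),
               sort(table(c(cyc$gene_a, cyc$gene_b))), ignore_attr = TRUE)
  expect_warning(maslov_sneppen_randomize(
    toy_net(gene_a = "A", gene_b = "B", type = "PPI")), "unchanged")
})

test_that("null ensemble Z-scores are standard normal over the ensemble", {
  set.seed(40)
  net <- simulate_interactome(100, c(PPI = 250), seed = 41)
  gs <- sample(interactome_genes(net), 10)
  graph_stats <- replicate(150, {
    rn <- maslov_sneppen_randomize(net, swaps_per_edge = 20)
    rg <- as_undirected_graph(rn)
    suppressMessages(characteristic_path_length(rg, gs)$length)
  })
  z <- (graph_stats - mean(graph_stats)) / sd(graph_stats)
  expect_gt(suppressWarnings(ks.test(z, pnorm))$p.value, 0.01)
})

test_that("CSR is the Jaccard overlap of component gene sets", {
  expect_equal(csr(c("A", "B"), c("A", "B")), 1)
  expect_equal(csr(c("A", "B"), c("C", "D")), 0)
  expect_equal(csr(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_equal(csr(c("A", "B", "C"), c("B", "C", "D")),
               csr(c("B", "C", "D"), c("A", "B", "C")))
  expect_error(csr(character(0), "A"), "empty")
})

test_that("CSR group contrast uses the rank-sum test (monotone-transform invariant)", {
  same <- c(0.5, 0.5, 0.6); diff <- c(0.5, 0.5, 0.6)
  p_eq <- csr_group_contrast(same, diff)$p.value
  expect_gt(p_eq, 0.9)
  # fully separated groups of 10: exact enumeration gives 2 / C(20,10)
  p_sep <- csr_group_contrast(seq(0.51, 0.6, 0.01), seq(0.01, 0.1, 0.01))$p.value
  expect_equal(p_sep, 2 / choose(20, 10), tolerance = 1e-10)
  # identical p on raw and log scale
  expect_equal(csr_group_contrast(c(.1, .2, .3), c(.15, .22, .4))$p.value,
               suppressWarnings(wilcox.test(log(c(.1, .2, .3)),
                                            log(c(.15, .22, .4))))$p.value)
})
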