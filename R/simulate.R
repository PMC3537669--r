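#' Simulation configuration
#'
#' Parameters of the synthetic segregant-panel generator. Defaults emulate
#' the scale of a classical two-parent haploid yeast cross: 112 segregants
#' genotyped at 2,956 markers over 16 chromosomes, a typed interactome of
#' 6,064 genes with layer sizes matching a hybrid yeast network (25,301
#' PPI, 12,681 PDI, 28,785 KPI, 3,486 EEI), and a 100-compound growth
#' screen with several conditions per compound.
#'
#' @param n_strains number of segregants.
#' @param n_chromosomes number of chromosomes.
#' @param n_markers_per_chrom integer vector of marker counts per
#'   chromosome (recycled to `n_chromosomes`).
#' @param marker_spacing_bp distance between adjacent markers (bp).
#' @param recomb_prob probability of a recombination event between adjacent
#'   markers (the switch probability of the genotype Markov chain).
#' @param n_genes number of genes in the interactome.
#' @param edge_counts_by_type named integer vector of edge counts per
#'   interaction type (names among PPI, PDI, KPI, EEI).
#' @param n_planted_eqtls number of planted marker -> gene effects.
#' @param n_planted_ascp number of planted co-perturbed edges (the marker
#'   gets eQTL effects on both endpoints).
#' @param n_planted_asdp number of planted dys-perturbed edges
#'   (allele-conditioned correlation difference).
#' @param effect_size standardized allele effect (units of residual SD).
#' @param noise_sd residual expression SD.
#' @param n_parent_reps parental replicate count per parent.
#' @param dys_delta target |r0 - r1| for planted ASDP pairs (correlation in
#'   the allele-0 group; the allele-1 group is left uncorrelated).
#' @param n_compounds number of small-molecule perturbagens screened.
#' @param conditions_per_compound conditions (time x concentration) per
#'   compound.
#' @param n_planted_smp_qtls number of compounds given a planted response
#'   QTL (placed on markers that also carry planted perturbations, so the
#'   QTL-to-network bridge is recoverable).
#' @param seed integer seed driving every random draw.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 112,
                       n_chromosomes = 16,
                       n_markers_per_chrom = c(rep(185L, 12), rep(184L, 4)),
                       marker_spacing_bp = 4000,
                       recomb_prob = 0.02,
                       n_genes = 6064,
                       edge_counts_by_type = c(PPI = 25301, PDI = 12681,
                                               KPI = 28785, EEI = 3486),
                       n_planted_eqtls = 50,
                       n_planted_ascp = 20,
                       n_planted_asdp = 20,
                       effect_size = 2,
                       noise_sd = 1,
                       n_parent_reps = 4,
                       dys_delta = 0.9,
                       n_compounds = 100,
                       conditions_per_compound = 3,
                       n_planted_smp_qtls = 50,
                       seed = 1L) {
  n_markers_per_chrom <- rep_len(as.integer(n_markers_per_chrom), n_chromosomes)
  edge_counts_by_type <- unlist(edge_counts_by_type)
  cfg <- list(n_strains = as.integer(n_strains),
              n_chromosomes = as.integer(n_chromosomes),
              n_markers_per_chrom = n_markers_per_chrom,
              marker_spacing_bp = marker_spacing_bp,
              recomb_prob = recomb_prob,
              n_genes = as.integer(n_genes),
              edge_counts_by_type = edge_counts_by_type,
              n_planted_eqtls = as.integer(n_planted_eqtls),
              n_planted_ascp = as.integer(n_planted_ascp),
              n_planted_asdp = as.integer(n_planted_asdp),
              effect_size = effect_size,
              noise_sd = noise_sd,
              n_parent_reps = as.integer(n_parent_reps),
              dys_delta = dys_delta,
              n_compounds = as.integer(n_compounds),
              conditions_per_compound = as.integer(conditions_per_compound),
              n_planted_smp_qtls = as.integer(n_planted_smp_qtls),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_strains > 0, n_chromosomes > 0, all(n_markers_per_chrom > 0),
              marker_spacing_bp > 0, n_genes > 0,
              recomb_prob >= 0, recomb_prob <= 1,
              effect_size >= 0, noise_sd >= 0,
              dys_delta >= 0, dys_delta <= 2,
              n_parent_reps > 0, n_compounds > 0, conditions_per_compound > 0)
    if (is.null(names(edge_counts_by_type)) ||
        !all(names(edge_counts_by_type) %in% INTERACTION_TYPES))
      stop("edge_counts_by_type must be named with types among ",
           paste(INTERACTION_TYPES, collapse = ", "))
  })
  structure(cfg, class = "sim_config")
}

new_ground_truth <- function() {
  list(planted_eqtls = data.frame(marker = character(), gene = character(),
                                  effect = numeric()),
       planted_ascp = data.frame(marker = character(), gene_a = character(),
                                 gene_b = character(), type = character()),
       planted_asdp = data.frame(marker = character(), gene_a = character(),
                                 gene_b = character(), type = character(),
                                 r0 = numeric(), r1 = numeric()),
       planted_smp_qtls = data.frame(marker = character(),
                                     compound = character(),
                                     effect = numeric()),
       gene_map = NULL)
}

#' Simulate a two-parent haploid cross
#'
#' Generates segregant genotypes chromosome by chromosome as two-state
#' Markov chains: each strain starts from a fair coin at the first marker
#' and switches parental allele between adjacent markers with probability
#' `recomb_prob`, so linkage disequilibrium decays with marker distance.
#' Genes are placed at marker positions round-robin (1 kb spans), which
#' makes cis relationships (marker within 10 kb of its gene) constructible,
#' and `n_planted_eqtls` random marker -> gene effects are recorded in the
#' returned ground truth.
#'
#' @param config a [sim_config()].
#' @return list with elements `genotypes` (a [geno_panel()]) and `truth`
#'   (ground-truth list: `planted_eqtls`, `planted_ascp`, `planted_asdp`,
#'   `planted_smp_qtls`, `gene_map`).
#' @export
simulate_cross <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  set.seed(config$seed)
  s <- config$n_strains
  chrom_calls <- vector("list", config$n_chromosomes)
  maps <- vector("list", config$n_chromosomes)
  for (ch in seq_len(config$n_chromosomes)) {
    m <- config$n_markers_per_chrom[ch]
    first <- rbinom(s, 1L, 0.5)
    if (m > 1) {
      switches <- matrix(rbinom((m - 1L) * s, 1L, config$recomb_prob),
                         nrow = m - 1L, ncol = s)
      calls <- (rep(first, each = m) +
                  rbind(0L, apply(switches, 2, cumsum))) %% 2L
      dim(calls) <- c(m, s)
    } else {
      calls <- matrix(first, nrow = 1L)
    }
    rownames(calls) <- sprintf("c%02d_m%04d", ch, seq_len(m))
    chrom_calls[[ch]] <- calls
    maps[[ch]] <- data.frame(marker = rownames(calls),
                             chrom = sprintf("chr%02d", ch),
                             pos = seq_len(m) * config$marker_spacing_bp)
  }
  calls <- do.call(rbind, chrom_calls)
  colnames(calls) <- sprintf("S%04d", seq_len(s))
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  geno <- geno_panel(calls, map)

  genes <- sprintf("G%04d", seq_len(config$n_genes))
  slot <- ((seq_len(config$n_genes) - 1L) %% nrow(map)) + 1L
  gene_map <- data.frame(gene = genes,
                         chrom = map$chrom[slot],
                         start = map$pos[slot],
                         end = map$pos[slot] + 999)

  truth <- new_ground_truth()
  truth$gene_map <- gene_map
  if (config$n_planted_eqtls > 0) {
    truth$planted_eqtls <- data.frame(
      marker = sample(map$marker, config$n_planted_eqtls, replace = TRUE),
      gene = sample(genes, config$n_planted_eqtls, replace = FALSE),
      effect = rep(config$effect_size, config$n_planted_eqtls))
  }
  list(genotypes = geno, truth = truth)
}

#' Simulate a typed scale-free interactome
#'
#' Draws a simple graph with a heavy-tailed (power-law fitness) degree
#' distribution over `n_genes` genes, then partitions its edges into the
#' requested interaction-type layers. PDI and KPI edges receive a random
#' orientation (regulator -> target, kinase -> substrate); PPI and EEI
#' stay undirected.
#'
#' @param n_genes gene count.
#' @param edge_counts_by_type named vector, edges per type.
#' @param seed integer seed.
#' @return an [interactome()].
#' @export
simulate_interactome <- function(n_genes, edge_counts_by_type, seed = 1L) {
  max_e <- n_genes * (n_genes - 1) / 2
  if (any(edge_counts_by_type > max_e))
    stop("requested edge count exceeds the number of available gene pairs")
  total <- sum(edge_counts_by_type)
  if (total > max_e) stop("total edge count exceeds available gene pairs")
  set.seed(seed)
  g <- igraph::sample_fitness_pl(n_genes, total, exponent.out = 2.5)
  el <- igraph::as_edgelist(g, names = FALSE)
  genes <- sprintf("G%04d", seq_len(n_genes))
  el <- el[sample.int(nrow(el)), , drop = FALSE]
  types <- rep(names(edge_counts_by_type), times = edge_counts_by_type)
  flip <- runif(nrow(el)) < 0.5
  a <- ifelse(flip, el[, 2], el[, 1])
  b <- ifelse(flip, el[, 1], el[, 2])
  interactome(data.frame(gene_a = genes[a], gene_b = genes[b], type = types))
}

#' Simulate expression with planted genetic effects
#'
#' Expression of gene g in strain i is the sum of planted allele effects
#' (`effect x allele`) plus Gaussian noise of SD `noise_sd`. For each
#' planted ASDP pair the two genes' noise is built from a shared latent
#' factor within one allele group only, so the within-group expression
#' correlations approach the recorded `r0`/`r1` targets in expectation.
#' Parental replicate columns are generated with the pure parental
#' genotypes (all 0 for parent A, all 1 for parent B).
#'
#' @param genotypes a [geno_panel()].
#' @param truth ground-truth list (see [simulate_cross()]); planted rows
#'   must reference markers present in `genotypes` and genes in
#'   `truth$gene_map`.
#' @param config a [sim_config()].
#' @return an [expression_panel()].
#' @export
simulate_expression <- function(genotypes, truth, config) {
  set.seed(config$seed + 1L)
  genes <- truth$gene_map$gene
  s <- ncol(genotypes$calls)
  miss_m <- setdiff(c(truth$planted_eqtls$marker, truth$planted_asdp$marker),
                    rownames(genotypes$calls))
  miss_g <- setdiff(c(truth$planted_eqtls$gene, truth$planted_asdp$gene_a,
                      truth$planted_asdp$gene_b), genes)
  if (length(miss_m) || length(miss_g))
    stop(sprintf("planted effects reference unknown %s",
                 paste(c(if (length(miss_m)) sprintf("markers: %s", paste(miss_m, collapse = ",")),
                         if (length(miss_g)) sprintf("genes: %s", paste(miss_g, collapse = ","))),
                       collapse = "; ")))

  noise <- matrix(rnorm(length(genes) * s, sd = config$noise_sd),
                  nrow = length(genes), dimnames = list(genes, colnames(genotypes$calls)))
  # allele-conditioned correlated noise for planted ASDP pairs
  correlated_noise <- function(n, r, sd) {
    f <- rnorm(n)
    ea <- rnorm(n); eb <- rnorm(n)
    a <- sqrt(abs(r)) * f + sqrt(1 - abs(r)) * ea
    b <- sign(r) * sqrt(abs(r)) * f + sqrt(1 - abs(r)) * eb
    if (r == 0) { a <- ea; b <- eb }
    cbind(a, b) * sd
  }
  if (nrow(truth$planted_asdp)) {
    for (i in seq_len(nrow(truth$planted_asdp))) {
      row <- truth$planted_asdp[i, ]
      alle <- genotypes$calls[row$marker, ]
      for (grp in c(0L, 1L)) {
        idx <- which(alle == grp)
        if (!length(idx)) next
        r <- if (grp == 0L) row$r0 else row$r1
        ab <- correlated_noise(length(idx), r, config$noise_sd)
        noise[row$gene_a, idx] <- ab[, 1]
        noise[row$gene_b, idx] <- ab[, 2]
      }
    }
  }
  expr <- noise
  if (nrow(truth$planted_eqtls)) {
    for (i in seq_len(nrow(truth$planted_eqtls))) {
      row <- truth$planted_eqtls[i, ]
      expr[row$gene, ] <- expr[row$gene, ] +
        row$effect * genotypes$calls[row$marker, ]
    }
  }

  reps <- config$n_parent_reps
  pa <- matrix(rnorm(length(genes) * reps, sd = config$noise_sd),
               nrow = length(genes),
               dimnames = list(genes, sprintf("PA_r%d", seq_len(reps))))
  pb <- matrix(rnorm(length(genes) * reps, sd = config$noise_sd),
               nrow = length(genes),
               dimnames = list(genes, sprintf("PB_r%d", seq_len(reps))))
  if (nrow(truth$planted_eqtls)) {
    tot <- tapply(truth$planted_eqtls$effect, truth$planted_eqtls$gene, sum)
    pb[names(tot), ] <- pb[names(tot), , drop = FALSE] + as.numeric(tot)
  }
  expression_panel(expr, parent_a = pa, parent_b = pb)
}

#' Simulate small-molecule response phenotypes
#'
#' One growth-yield trait per compound x condition: planted response-QTL
#' allele effects plus Gaussian noise. Alongside the phenotypes, a known
#' drug-target gene set is emitted per compound, biased to contain the
#' endpoint genes of perturbed interactions planted at the compound's QTL
#' markers (so target enrichment in QTL-linked sub-networks is recoverable
#' by construction).
#'
#' @param genotypes a [geno_panel()].
#' @param truth ground-truth list carrying `planted_smp_qtls` (and
#'   optionally planted perturbations used to bias target sets).
#' @param n_compounds number of compounds.
#' @param conditions_per_compound conditions per compound.
#' @param seed integer seed.
#' @param noise_sd residual SD of the growth trait.
#' @param target_set_size size of each emitted known-target set.
#' @return list with `phenotypes` (data.frame: compound, time,
#'   concentration, then one column per strain) and `target_sets` (named
#'   list of gene vectors).
#' @export
simulate_smp_phenotypes <- function(genotypes, truth, n_compounds,
                                    conditions_per_compound, seed = 1L,
                                    noise_sd = 1, target_set_size = 10) {
  set.seed(seed)
  miss <- setdiff(truth$planted_smp_qtls$marker, rownames(genotypes$calls))
  if (length(miss))
    stop(sprintf("planted SMP QTLs reference unknown markers: %s",
                 paste(miss, collapse = ",")))
  s <- ncol(genotypes$calls)
  compounds <- sprintf("SMP%03d", seq_len(n_compounds))
  conds <- expand.grid(compound = compounds,
                       cond = seq_len(conditions_per_compound),
                       stringsAsFactors = FALSE)
  vals <- matrix(rnorm(nrow(conds) * s, sd = noise_sd), nrow = nrow(conds))
  if (nrow(truth$planted_smp_qtls)) {
    for (i in seq_len(nrow(truth$planted_smp_qtls))) {
      row <- truth$planted_smp_qtls[i, ]
      hit <- which(conds$compound == row$compound)
      if (!length(hit)) next
      vals[hit, ] <- vals[hit, ] +
        rep(row$effect * genotypes$calls[row$marker, ], each = length(hit))
    }
  }
  colnames(vals) <- colnames(genotypes$calls)
  phen <- data.frame(compound = conds$compound,
                     time = sprintf("t%d", ((conds$cond - 1L) %/% 2L) + 1L),
                     concentration = sprintf("c%d", ((conds$cond - 1L) %% 2L) + 1L),
                     check.names = FALSE)
  phen <- cbind(phen, as.data.frame(vals, check.names = FALSE))

  all_genes <- if (!is.null(truth$gene_map)) truth$gene_map$gene else
    sort(unique(c(truth$planted_ascp$gene_a, truth$planted_ascp$gene_b)))
  perturbed_by_marker <- rbind(
    truth$planted_ascp[, c("marker", "gene_a", "gene_b")],
    truth$planted_asdp[, c("marker", "gene_a", "gene_b")])
  target_sets <- lapply(compounds, function(cp) {
    mk <- truth$planted_smp_qtls$marker[truth$planted_smp_qtls$compound == cp]
    core <- with(perturbed_by_marker,
                 unique(c(gene_a[marker %in% mk], gene_b[marker %in% mk])))
    pad <- setdiff(all_genes, core)
    n_pad <- max(0L, target_set_size - length(core))
    sort(c(core, sample(pad, min(n_pad, length(pad)))))
  })
  names(target_sets) <- compounds
  list(phenotypes = phen, target_sets = target_sets)
}

#' Simulate a complete study with ground truth
#'
#' Orchestrates the generator: cross, interactome, planted allele-specific
#' perturbations (ASCP edges get eQTL effects on both endpoints; ASDP edges
#' get an endpoint eQTL plus the allele-conditioned correlation contrast),
#' expression, and the compound screen with planted response QTLs placed on
#' perturbation-carrying markers.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes`, `expression`, `net`, `phenotypes`,
#'   `target_sets`, `truth`, and the `config` used.
#' @export
simulate_dataset <- function(config = sim_config()) {
  cross <- simulate_cross(config)
  geno <- cross$genotypes
  truth <- cross$truth
  net <- simulate_interactome(config$n_genes, config$edge_counts_by_type,
                              seed = config$seed + 2L)

  set.seed(config$seed + 3L)
  markers <- rownames(geno$calls)
  used_genes <- truth$planted_eqtls$gene
  n_extra <- config$n_planted_ascp + config$n_planted_asdp
  if (n_extra > 0) {
    # pick edges whose endpoints are untouched by other planted effects so
    # the planted correlation structure is not diluted
    free <- !(net$gene_a %in% used_genes) & !(net$gene_b %in% used_genes)
    cand <- which(free)
    pick <- integer(0)
    blocked <- character(0)
    for (i in sample(cand)) {
      if (net$gene_a[i] %in% blocked || net$gene_b[i] %in% blocked) next
      pick <- c(pick, i)
      blocked <- c(blocked, net$gene_a[i], net$gene_b[i])
      if (length(pick) == n_extra) break
    }
    if (length(pick) < n_extra)
      stop("interactome too small to plant the requested perturbations")
    ascp_idx <- pick[seq_len(config$n_planted_ascp)]
    asdp_idx <- pick[config$n_planted_ascp + seq_len(config$n_planted_asdp)]
    if (config$n_planted_ascp > 0) {
      mk <- sample(markers, config$n_planted_ascp, replace = TRUE)
      truth$planted_ascp <- data.frame(marker = mk,
                                       gene_a = net$gene_a[ascp_idx],
                                       gene_b = net$gene_b[ascp_idx],
                                       type = net$type[ascp_idx])
      truth$planted_eqtls <- rbind(
        truth$planted_eqtls,
        data.frame(marker = rep(mk, 2),
                   gene = c(net$gene_a[ascp_idx], net$gene_b[ascp_idx]),
                   effect = config$effect_size))
    }
    if (config$n_planted_asdp > 0) {
      mk <- sample(markers, config$n_planted_asdp, replace = TRUE)
      truth$planted_asdp <- data.frame(marker = mk,
                                       gene_a = net$gene_a[asdp_idx],
                                       gene_b = net$gene_b[asdp_idx],
                                       type = net$type[asdp_idx],
                                       r0 = config$dys_delta, r1 = 0)
      # make the marker an eQTL of one endpoint so the default ASDP
      # candidate universe (eQTL-target edges) contains the planted pair
      truth$planted_eqtls <- rbind(
        truth$planted_eqtls,
        data.frame(marker = mk, gene = net$gene_a[asdp_idx],
                   effect = config$effect_size))
    }
  }

  expr <- simulate_expression(geno, truth, config)

  perturbed_markers <- unique(c(truth$planted_ascp$marker,
                                truth$planted_asdp$marker))
  n_smp <- min(config$n_planted_smp_qtls, config$n_compounds)
  if (n_smp > 0 && length(perturbed_markers)) {
    truth$planted_smp_qtls <- data.frame(
      marker = sample(perturbed_markers, n_smp, replace = TRUE),
      compound = sprintf("SMP%03d", seq_len(n_smp)),
      effect = config$effect_size)
  }
  smp <- simulate_smp_phenotypes(geno, truth, config$n_compounds,
                                 config$conditions_per_compound,
                                 seed = config$seed + 4L,
                                 noise_sd = config$noise_sd)
  list(genotypes = geno, expression = expr, net = net,
       phenotypes = smp$phenotypes, target_sets = smp$target_sets,
       truth = truth, config = config)
}
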