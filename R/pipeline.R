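#' Pipeline run configuration
#'
#' Collects every threshold, permutation count, seed and mode flag of the
#' end-to-end run. Input paths may be omitted when `simulate` is a
#' [sim_config()], in which case the panel is generated in the run
#' directory first.
#'
#' @param out_dir run directory (created; outputs and manifest land here).
#' @param genotypes_file,expression_file,parent_a_file,parent_b_file,
#'   interactome_file,phenotypes_file,target_sets_file input paths
#'   (ignored when `simulate` is given).
#' @param simulate `NULL`, or a [sim_config()] to generate inputs.
#' @param fdr_level FDR level for eQTL, ASDP and heritability calls.
#' @param t_threshold absolute-t cutoff for SMP QTLs (strict >).
#' @param r2_threshold LD-block r2 rule.
#' @param min_edges minimum perturbed interactions per retained block.
#' @param min_links candidate-target link threshold.
#' @param window_bp cis window in bp.
#' @param n_perm_eqtl,n_perm_asdp,n_perm_h2 permutation counts.
#' @param n_random,swaps_per_edge topology null ensemble settings.
#' @param run_heritability estimate heritability and filter traits
#'   (needs parental replicates).
#' @param run_topology run the randomization test on block sub-networks.
#' @param null_pool,add_one,asdp_candidates,bridge,inclusive_tail mode
#'   flags passed to the respective stages.
#' @param seed master seed; every stochastic stage derives from it.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(out_dir,
                            genotypes_file = NULL, expression_file = NULL,
                            parent_a_file = NULL, parent_b_file = NULL,
                            interactome_file = NULL, phenotypes_file = NULL,
                            target_sets_file = NULL,
                            simulate = NULL,
                            fdr_level = 0.05, t_threshold = 3.28,
                            r2_threshold = 0.8, min_edges = 3, min_links = 3,
                            window_bp = 10000,
                            n_perm_eqtl = 1000, n_perm_asdp = 1000,
                            n_perm_h2 = 200,
                            n_random = 200, swaps_per_edge = 100,
                            run_heritability = TRUE, run_topology = TRUE,
                            null_pool = "trait", add_one = FALSE,
                            asdp_candidates = "eqtl", bridge = "block",
                            inclusive_tail = FALSE,
                            seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(fdr_level > 0, fdr_level <= 1, t_threshold >= 0,
            r2_threshold >= 0, r2_threshold <= 1,
            min_edges >= 1, min_links >= 1, window_bp >= 0,
            n_perm_eqtl >= 1, n_perm_asdp >= 1, n_perm_h2 >= 1,
            n_random >= 1, swaps_per_edge >= 1)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; missing keys take
#' the defaults. A `simulate:` mapping is passed to [sim_config()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(sim_config, y$simulate)
  do.call(pipeline_config, y)
}

config_md5 <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  # the hash identifies the analytic configuration, not the run location
  plain <- lapply(unclass(config)[setdiff(names(config), "out_dir")],
                  function(x) if (inherits(x, "sim_config")) unclass(x) else x)
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — simulate/load, impute,
#' heritability filter, merge identical markers, eQTL mapping with
#' cis/trans classification, ASCP and ASDP detection, LD blocks and block
#' sub-networks, topology randomization test, SMP QTL mapping with
#' per-compound sub-networks, drug-target enrichment and candidate-target
#' prediction — writing every stage's table to the run directory together
#' with a manifest (config and output checksums, seed, stage list) and a
#' stage-level log. A stage failure halts the run, naming the stage;
#' tables written so far are preserved.
#'
#' @param config a [pipeline_config()] (or path to its YAML).
#' @return the manifest list, invisibly; all outputs are under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(config$out_dir, "pipeline.log")
  cat("", file = log_file)
  stages_done <- character(0)
  log_stage <- function(name, msg = "done") {
    cat(sprintf("[%s] %s\n", name, msg), file = log_file, append = TRUE)
  }
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    stages_done <<- c(stages_done, name)
    log_stage(name)
    res
  }
  tsv <- function(df, name) {
    write.table(df, file.path(config$out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  # preflight: inputs must exist before any stage runs
  if (is.null(config$simulate)) {
    paths <- c(config$genotypes_file, config$expression_file,
               config$interactome_file, config$phenotypes_file,
               config$target_sets_file)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop(sprintf("missing input file(s): %s", paste(missing, collapse = ", ")))
  }

  inputs <- stage("load", {
    if (!is.null(config$simulate)) {
      ds <- simulate_dataset(config$simulate)
      write_dataset(ds, file.path(config$out_dir, "inputs"))
      list(geno = ds$genotypes, expr = ds$expression, net = ds$net,
           phen = ds$phenotypes, targets = ds$target_sets,
           gene_map = ds$truth$gene_map)
    } else {
      geno <- read_genotypes(config$genotypes_file)
      ev <- read_expression(config$expression_file)
      pa <- if (!is.null(config$parent_a_file)) read_expression(config$parent_a_file)
      pb <- if (!is.null(config$parent_b_file)) read_expression(config$parent_b_file)
      list(geno = geno,
           expr = expression_panel(ev, parent_a = pa, parent_b = pb),
           net = read_interactome(config$interactome_file),
           phen = read_phenotypes(config$phenotypes_file, geno),
           targets = read_gmt(config$target_sets_file),
           gene_map = NULL)
    }
  })

  expr_vals <- stage("impute", {
    v <- inputs$expr$values
    if (anyNA(v)) v <- knn_impute_expression(v) else v
  })

  traits <- expr_vals
  if (config$run_heritability && !is.null(inputs$expr$parent_a)) {
    h2 <- stage("heritability", {
      panel <- expression_panel(expr_vals, inputs$expr$parent_a,
                                inputs$expr$parent_b)
      heritability_scan(panel, n_perm = config$n_perm_h2,
                        seed = config$seed + 10L,
                        fdr_level = config$fdr_level)
    })
    tsv(h2, "heritability.tsv")
    keep <- h2$trait[h2$passes_fdr]
    log_stage("heritability", sprintf("%d/%d traits pass FDR %.2f",
                                      length(keep), nrow(h2), config$fdr_level))
    if (length(keep) >= 2) traits <- expr_vals[keep, , drop = FALSE]
  }

  merged <- stage("merge_markers", merge_identical_markers(inputs$geno))
  tsv(merged$merge_map, "marker_merge_map.tsv")
  geno <- merged$genotypes

  hits <- stage("eqtl_map", {
    h <- map_qtls(geno, traits, n_perm = config$n_perm_eqtl,
                  fdr_level = config$fdr_level, seed = config$seed + 20L,
                  null_pool = config$null_pool, add_one = config$add_one)
    if (!is.null(inputs$gene_map))
      h <- classify_cis_trans(h, geno$map, inputs$gene_map,
                              window_bp = config$window_bp)
    h
  })
  tsv(hits, "eqtl_hits.tsv")

  records <- stage("perturbation", {
    ascp <- detect_ascp(hits, inputs$net)
    asdp <- detect_asdp(expr_vals, geno, hits, inputs$net,
                        n_perm = config$n_perm_asdp,
                        fdr_level = config$fdr_level,
                        seed = config$seed + 30L,
                        candidates = config$asdp_candidates)
    rbind(ascp, asdp)
  })
  tsv(records, "perturbation_records.tsv")

  blocks <- stage("blocks", find_ld_blocks(geno, r2_threshold = config$r2_threshold))
  tsv(blocks, "blocks.tsv")
  assoc <- stage("block_association",
                 block_association_matrix(blocks, records,
                                          min_edges = config$min_edges))
  tsv(data.frame(block = rownames(assoc), assoc, check.names = FALSE),
      "block_association_matrix.tsv")
  subnets <- stage("block_subnetworks",
                   assemble_block_subnetworks(blocks, records, inputs$net,
                                              min_edges = config$min_edges))

  if (config$run_topology && length(subnets)) {
    topo <- stage("topology",
                  topology_null_test(inputs$net, subnets,
                                     n_random = config$n_random,
                                     swaps_per_edge = config$swaps_per_edge,
                                     seed = config$seed + 40L))
    tsv(topo, "topology_stats.tsv")
  }

  smp_qtls <- stage("smp_map",
                    map_smp_qtls(geno, inputs$phen,
                                 t_threshold = config$t_threshold,
                                 n_perm = config$n_perm_eqtl,
                                 seed = config$seed + 50L,
                                 fdr_level = config$fdr_level))
  tsv(data.frame(compound = rep(names(smp_qtls),
                                vapply(smp_qtls, function(x) length(x$qtl_markers), 0L)),
                 marker = unlist(lapply(smp_qtls, `[[`, "qtl_markers"),
                                 use.names = FALSE)),
      "smp_qtls.tsv")

  smp_nets <- stage("smp_subnetworks",
                    suppressMessages(smp_subnetwork(smp_qtls, blocks, records,
                                                    inputs$net,
                                                    bridge = config$bridge)))
  background <- interactome_genes(inputs$net)
  enr <- stage("enrichment", {
    lapply(smp_nets, function(sn) {
      if (!length(sn$genes)) return(NULL)
      enrich_sets(sn$genes, inputs$targets, background,
                  inclusive = config$inclusive_tail)
    })
  })
  enr_tab <- do.call(rbind, lapply(names(enr), function(cp) {
    if (is.null(enr[[cp]])) return(NULL)
    cbind(compound = cp, enr[[cp]])
  }))
  if (!is.null(enr_tab)) tsv(enr_tab, "enrichment.tsv")

  cand <- stage("candidate_targets",
                predict_candidate_targets(smp_nets, inputs$targets,
                                          min_links = config$min_links))
  tsv(cand, "candidate_targets.tsv")

  mats <- stage("association_matrices",
                association_matrices(smp_qtls, blocks, enr))
  tsv(data.frame(block = rownames(mats$block_by_smp), mats$block_by_smp,
                 check.names = FALSE), "block_by_smp.tsv")
  if (!is.null(mats$function_by_smp))
    tsv(data.frame(class = rownames(mats$function_by_smp),
                   mats$function_by_smp, check.names = FALSE),
        "function_by_smp.tsv")

  outputs <- setdiff(list.files(config$out_dir, recursive = TRUE),
                     c("manifest.json", "pipeline.log"))
  manifest <- list(
    package = "aspnet",
    version = as.character(utils::packageVersion("aspnet")),
    seed = config$seed,
    config_md5 = config_md5(config),
    stages = stages_done,
    outputs = as.list(tools::md5sum(file.path(config$out_dir, outputs))))
  names(manifest$outputs) <- outputs
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
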