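phenotype_trait_matrix <- function(phenotypes) {
  meta_cols <- c("compound", "time", "concentration")
  stopifnot(all(meta_cols %in% names(phenotypes)))
  strains <- setdiff(names(phenotypes), meta_cols)
  Y <- as.matrix(phenotypes[, strains, drop = FALSE])
  rownames(Y) <- paste(phenotypes$compound, phenotypes$time,
                       phenotypes$concentration, sep = "|")
  list(Y = Y, compound = phenotypes$compound)
}

#' Map small-molecule response QTLs
#'
#' Treats every compound x condition growth trait as an independent
#' phenotype, maps it with the same permutation machinery as eQTLs
#' ([map_qtls()]), retains hits with |t| strictly greater than
#' `t_threshold`, and unions the hit markers across conditions of each
#' compound.
#'
#' @param genotypes a [geno_panel()].
#' @param phenotypes data.frame: compound, time, concentration, then one
#'   column per strain.
#' @param t_threshold absolute-t cutoff (default 3.28; strict >).
#' @param n_perm label permutations for the p-values carried on the hits.
#' @param seed integer seed.
#' @param fdr_level BH level recorded on the hits (hits are selected by
#'   the t threshold, not by q).
#' @return named list (by compound): `qtl_markers` (character vector,
#'   union over conditions) and `per_condition_hits` (list of hit
#'   data.frames keyed by condition label).
#' @export
map_smp_qtls <- function(genotypes, phenotypes, t_threshold = 3.28,
                         n_perm = 1000, seed = 1L, fdr_level = 0.05) {
  tm <- phenotype_trait_matrix(phenotypes)
  all_na <- rowSums(!is.na(tm$Y)) == 0
  if (any(all_na)) {
    warning(sprintf("skipping %d all-missing phenotype trait(s)", sum(all_na)))
    tm$Y <- tm$Y[!all_na, , drop = FALSE]
    tm$compound <- tm$compound[!all_na]
  }
  hits <- map_qtls(genotypes, tm$Y, n_perm = n_perm, fdr_level = fdr_level,
                   seed = seed, keep = "all")
  hits <- hits[abs(hits$t) > t_threshold, , drop = FALSE]
  compound_of <- sub("\\|.*$", "", hits$trait)
  out <- lapply(unique(tm$compound), function(cp) {
    h <- hits[compound_of == cp, , drop = FALSE]
    list(qtl_markers = sort(unique(h$marker)),
         per_condition_hits = split(h, h$trait))
  })
  names(out) <- unique(tm$compound)
  out
}

#' Assemble per-compound perturbed sub-networks
#'
#' Bridges response QTLs to network perturbations at LD-block resolution:
#' a compound recruits every perturbation record whose eQTL marker lies in
#' an LD block that also contains one of the compound's QTL markers; the
#' sub-network is the interactome subgraph induced on those records' edge
#' endpoints. `bridge = "marker"` requires the exact marker to match
#' instead.
#'
#' @param smp_qtls output of [map_smp_qtls()].
#' @param blocks block table from [find_ld_blocks()].
#' @param records perturbation-record data.frame (ASCP and ASDP).
#' @param net the integrated [interactome()].
#' @param bridge `"block"` (default) or `"marker"`.
#' @return named list (by compound) of [subnetwork()] objects; compounds
#'   with no recruitable perturbation get an empty sub-network.
#' @export
smp_subnetwork <- function(smp_qtls, blocks, records, net,
                           bridge = c("block", "marker")) {
  bridge <- match.arg(bridge)
  m2b <- marker_block_lookup(blocks)
  rec_block <- m2b$block[match(records$marker, m2b$marker)]
  out <- lapply(names(smp_qtls), function(cp) {
    qtl <- smp_qtls[[cp]]$qtl_markers
    if (bridge == "block") {
      qtl_blocks <- unique(m2b$block[m2b$marker %in% qtl])
      sel <- !is.na(rec_block) & rec_block %in% qtl_blocks
    } else {
      sel <- records$marker %in% qtl
    }
    rec <- records[sel, , drop = FALSE]
    if (!nrow(rec)) {
      message(sprintf("compound %s: no perturbed interactions recruited", cp))
      return(subnetwork(cp, character(0),
                        net[integer(0), , drop = FALSE], records = rec))
    }
    suppressMessages(extract_subnetwork(net, unique(c(rec$gene_a, rec$gene_b)),
                                        owner = cp, records = rec))
  })
  names(out) <- names(smp_qtls)
  out
}

jaccard_dist <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    u <- sum(mat[i, ] | mat[j, ])
    d[i, j] <- if (u == 0) 0 else 1 - sum(mat[i, ] & mat[j, ]) / u
  }
  as.dist(d)
}

order_by_clustering <- function(mat) {
  ord_r <- if (nrow(mat) > 2) hclust(jaccard_dist(mat), method = "average")$order
           else seq_len(nrow(mat))
  ord_c <- if (ncol(mat) > 2) hclust(jaccard_dist(t(mat)), method = "average")$order
           else seq_len(ncol(mat))
  mat[ord_r, ord_c, drop = FALSE]
}

#' Block x SMP and function x SMP association matrices
#'
#' Binary summaries of the compound screen: the genetic matrix marks which
#' LD blocks carry QTLs of which compounds, and the functional matrix
#' marks which functional classes each compound's sub-network is enriched
#' in (q < `q_level`). Optionally, rows and columns are reordered by
#' average-linkage hierarchical clustering on Jaccard distance —
#' presentation only; cell contents are unchanged and independent of input
#' order.
#'
#' @param smp_qtls output of [map_smp_qtls()].
#' @param blocks block table.
#' @param enrichments named list (by compound) of [enrich_sets()] results
#'   over functional classes, or `NULL` to skip the functional matrix.
#' @param q_level enrichment q threshold (default 0.05).
#' @param cluster reorder rows/columns by clustering.
#' @return list with `block_by_smp` and `function_by_smp` binary matrices
#'   (the latter `NULL` when no enrichments are given).
#' @export
association_matrices <- function(smp_qtls, blocks, enrichments = NULL,
                                 q_level = 0.05, cluster = FALSE) {
  m2b <- marker_block_lookup(blocks)
  compounds <- sort(names(smp_qtls))
  bm <- matrix(0L, length(blocks$block), length(compounds),
               dimnames = list(blocks$block, compounds))
  for (cp in compounds) {
    bl <- unique(m2b$block[m2b$marker %in% smp_qtls[[cp]]$qtl_markers])
    bm[bl[bl %in% rownames(bm)], cp] <- 1L
  }
  fm <- NULL
  if (!is.null(enrichments)) {
    classes <- sort(unique(unlist(lapply(enrichments, function(e) e$set_name))))
    fm <- matrix(0L, length(classes), length(compounds),
                 dimnames = list(classes, compounds))
    for (cp in intersect(compounds, names(enrichments))) {
      e <- enrichments[[cp]]
      sig <- e$set_name[!is.na(e$q) & e$q < q_level]
      fm[sig, cp] <- 1L
    }
  }
  if (cluster) {
    bm <- order_by_clustering(bm)
    if (!is.null(fm)) fm <- order_by_clustering(fm)
  }
  list(block_by_smp = bm, function_by_smp = fm)
}
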