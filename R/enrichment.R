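#' Strict upper-tail hypergeometric probability
#'
#' P(X > x) for a hypergeometric count X of successes in `k` draws without
#' replacement from a background of `m` successes and `n` failures, i.e.
#' `1 - phyper(x, m, n, k)`. Note the strict inequality: the observed
#' count itself is excluded from the tail, so x = min(m, k) always gives
#' exactly 0. The conventional inclusive tail P(X >= x) is available with
#' `inclusive = TRUE`.
#'
#' @param x observed success count (0 <= x <= min(m, k)).
#' @param m successes in the background.
#' @param n failures in the background.
#' @param k draws (sub-network size).
#' @param inclusive use P(X >= x) instead of the default strict P(X > x).
#' @return probability in [0, 1]. Vectorised over its arguments.
#' @export
hypergeom_upper_tail <- function(x, m, n, k, inclusive = FALSE) {
  if (any(x < 0 | m < 0 | n < 0 | k < 0) || any(k > m + n) ||
      any(x > pmin(m, k)) || any(x < pmax(0, k - n)))
    stop("infeasible hypergeometric counts")
  if (inclusive) x <- x - 1
  phyper(x, m, n, k, lower.tail = FALSE)
}

#' Gene-set enrichment of a sub-network
#'
#' Tests each gene set for over-representation in the sub-network against
#' a fixed background (all interactome genes by default in the pipeline):
#' m = set genes in the background, n = remaining background genes, k =
#' sub-network size, x = set genes inside the sub-network; p =
#' [hypergeom_upper_tail()] and q = Benjamini-Hochberg across the tested
#' sets.
#'
#' @param subnetwork_genes genes of the sub-network (must lie in the
#'   background).
#' @param gene_sets named list of gene-id vectors (e.g. from
#'   [read_gmt()]).
#' @param background_genes the background universe.
#' @param inclusive tail convention flag passed through.
#' @return data.frame sorted by p: set_name, x, m, n, k, p, q.
#' @export
enrich_sets <- function(subnetwork_genes, gene_sets, background_genes,
                        inclusive = FALSE) {
  background_genes <- unique(background_genes)
  if (!length(background_genes)) stop("empty background")
  subnetwork_genes <- unique(subnetwork_genes)
  outside <- setdiff(subnetwork_genes, background_genes)
  if (length(outside))
    stop(sprintf("%d sub-network gene(s) outside the background", length(outside)))
  k <- length(subnetwork_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), background_genes)
    m <- length(set)
    n <- length(background_genes) - m
    x <- length(intersect(set, subnetwork_genes))
    data.frame(set_name = nm, x = x, m = m, n = n, k = k,
               p = hypergeom_upper_tail(x, m, n, k, inclusive = inclusive))
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$set_name), ]
  rownames(out) <- NULL
  out
}

#' Predict candidate drug targets by connectivity to known targets
#'
#' Pools the perturbed (ASCP/ASDP) edges of all compound sub-networks and,
#' for every gene that is not itself a known target, counts the distinct
#' known target genes it touches through those edges (a target reached via
#' several edge types counts once). Genes reaching at least `min_links`
#' targets are reported with their per-compound link breakdown.
#'
#' @param smp_subnetworks named list (by compound) of [subnetwork()]
#'   objects whose `records` carry the perturbed edges.
#' @param known_target_sets named list (by compound) of known target gene
#'   vectors.
#' @param min_links minimum distinct linked targets (default 3).
#' @return data.frame: gene, n_targets, targets (comma-separated),
#'   compounds (comma-separated), sorted by decreasing n_targets.
#' @export
predict_candidate_targets <- function(smp_subnetworks, known_target_sets,
                                      min_links = 3) {
  all_targets <- unique(unlist(known_target_sets))
  links <- list()  # gene -> set of targets
  via <- list()    # gene -> set of compounds
  for (cp in names(smp_subnetworks)) {
    rec <- smp_subnetworks[[cp]]$records
    if (is.null(rec) || !nrow(rec)) next
    targets <- unique(known_target_sets[[cp]])
    if (is.null(targets)) targets <- character(0)
    for (i in seq_len(nrow(rec))) {
      for (ord in list(c(rec$gene_a[i], rec$gene_b[i]),
                       c(rec$gene_b[i], rec$gene_a[i]))) {
        gene <- ord[1]; partner <- ord[2]
        if (gene %in% all_targets || !(partner %in% targets)) next
        links[[gene]] <- union(links[[gene]], partner)
        via[[gene]] <- union(via[[gene]], cp)
      }
    }
  }
  if (!length(links))
    return(data.frame(gene = character(), n_targets = integer(),
                      targets = character(), compounds = character()))
  out <- data.frame(gene = names(links),
                    n_targets = vapply(links, length, integer(1)),
                    targets = vapply(links, function(x) paste(sort(x), collapse = ","),
                                     character(1)),
                    compounds = vapply(via[names(links)],
                                       function(x) paste(sort(x), collapse = ","),
                                       character(1)))
  out <- out[out$n_targets >= min_links, , drop = FALSE]
  out <- out[order(-out$n_targets, out$gene), ]
  rownames(out) <- NULL
  out
}
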