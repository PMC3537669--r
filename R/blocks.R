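#' Find linkage-disequilibrium blocks
#'
#' Greedy contiguous extension along each chromosome: a block keeps growing
#' while the next marker's minimum pairwise r-squared with every marker
#' already in the block stays at or above `r2_threshold`. Blocks partition
#' the marker list; blocks with fewer than `min_markers` markers are still
#' emitted (each marker always belongs to exactly one block) but can be
#' filtered by the caller.
#'
#' @param genotypes a [geno_panel()], markers position-sorted.
#' @param r2_threshold minimum pairwise allele-correlation r2 (default
#'   0.8).
#' @param min_markers blocks smaller than this are dropped from the
#'   returned table (default 1 keeps everything).
#' @return data.frame of blocks: `block` (B1, B2, ...), `chrom`,
#'   `first_marker`, `last_marker`, `n_markers`, `span_start`, `span_end`,
#'   with the marker-to-block assignment in `attr(, "marker2block")`.
#' @export
find_ld_blocks <- function(genotypes, r2_threshold = 0.8, min_markers = 1) {
  calls <- genotypes$calls
  map <- genotypes$map
  assignment <- integer(nrow(map))
  block_id <- 0L
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    members <- integer(0)
    for (i in idx) {
      ok <- FALSE
      if (length(members)) {
        r2 <- suppressWarnings(
          cor(calls[i, ], t(calls[members, , drop = FALSE]),
              use = "pairwise.complete.obs"))^2
        r2[is.na(r2)] <- 0
        ok <- min(r2) >= r2_threshold
      }
      if (!ok) {
        block_id <- block_id + 1L
        members <- i
      } else {
        members <- c(members, i)
      }
      assignment[i] <- block_id
    }
  }
  blocks <- do.call(rbind, lapply(seq_len(block_id), function(b) {
    i <- which(assignment == b)
    data.frame(block = sprintf("B%d", b), chrom = map$chrom[i[1]],
               first_marker = map$marker[i[1]],
               last_marker = map$marker[i[length(i)]],
               n_markers = length(i),
               span_start = map$pos[i[1]], span_end = map$pos[i[length(i)]])
  }))
  marker2block <- data.frame(marker = map$marker,
                             block = sprintf("B%d", assignment))
  blocks <- blocks[blocks$n_markers >= min_markers, , drop = FALSE]
  rownames(blocks) <- NULL
  attr(blocks, "marker2block") <- marker2block
  blocks
}

#' Read an external marker-to-block assignment
#'
#' Allows block definitions computed elsewhere to override the built-in
#' r-squared rule: a two-column TSV (`marker`, `block`).
#'
#' @param path TSV path.
#' @param genotypes a [geno_panel()] used to derive the block table.
#' @return block table as from [find_ld_blocks()].
#' @export
read_block_assignment <- function(path, genotypes) {
  m2b <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("marker", "block") %in% names(m2b)))
  map <- genotypes$map
  m2b <- m2b[match(map$marker, m2b$marker), ]
  if (any(is.na(m2b$block))) stop("block assignment missing for some markers")
  blocks <- do.call(rbind, lapply(unique(m2b$block), function(b) {
    i <- which(m2b$block == b)
    data.frame(block = b, chrom = map$chrom[i[1]],
               first_marker = map$marker[i[1]],
               last_marker = map$marker[i[length(i)]],
               n_markers = length(i),
               span_start = map$pos[i[1]], span_end = map$pos[i[length(i)]])
  }))
  rownames(blocks) <- NULL
  attr(blocks, "marker2block") <- m2b[, c("marker", "block")]
  blocks
}

marker_block_lookup <- function(blocks) {
  m2b <- attr(blocks, "marker2block")
  if (is.null(m2b)) stop("block table lacks the marker2block attribute")
  m2b[m2b$block %in% blocks$block, , drop = FALSE]
}

#' Block x interaction association matrix
#'
#' Binary matrix with one row per LD block and one column per perturbed
#' interaction: a cell is 1 when at least one perturbation record's marker
#' lies in the block and its edge is that interaction. Blocks perturbing
#' fewer than `min_edges` distinct interactions are dropped. Rows follow
#' the block table order; columns are sorted by edge key
#' (`gene_a|gene_b|type`).
#'
#' @param blocks block table from [find_ld_blocks()].
#' @param records perturbation-record data.frame (ASCP and/or ASDP).
#' @param min_edges minimum distinct perturbed interactions per retained
#'   block (default 3).
#' @return binary integer matrix, rownames = block ids, colnames = edge
#'   keys.
#' @export
block_association_matrix <- function(blocks, records, min_edges = 3) {
  m2b <- marker_block_lookup(blocks)
  bl <- m2b$block[match(records$marker, m2b$marker)]
  unassigned <- is.na(bl)
  if (any(unassigned)) {
    message(sprintf("%d record(s) on markers outside any block skipped",
                    sum(unassigned)))
    records <- records[!unassigned, , drop = FALSE]
    bl <- bl[!unassigned]
  }
  keys <- edge_key(records$gene_a, records$gene_b, records$type)
  all_keys <- sort(unique(keys))
  all_blocks <- blocks$block
  mat <- matrix(0L, length(all_blocks), length(all_keys),
                dimnames = list(all_blocks, all_keys))
  if (length(keys)) mat[cbind(match(bl, all_blocks), match(keys, all_keys))] <- 1L
  mat <- mat[rowSums(mat) >= min_edges, , drop = FALSE]
  mat
}

#' Induced sub-network on a gene set
#'
#' All integrated-interactome edges (any type) with both endpoints in the
#' gene set. Genes absent from the interactome are dropped with a message.
#'
#' @param net an [interactome()].
#' @param gene_set character vector of gene ids.
#' @param owner label for the resulting sub-network.
#' @param records optional perturbation records backing the set
#'   (provenance).
#' @return a [subnetwork()].
#' @export
extract_subnetwork <- function(net, gene_set, owner = "subnetwork",
                               records = NULL) {
  gene_set <- unique(gene_set)
  known <- gene_set %in% c(net$gene_a, net$gene_b)
  if (any(!known))
    message(sprintf("%d gene(s) not in the interactome dropped", sum(!known)))
  gene_set <- gene_set[known]
  keep <- net$gene_a %in% gene_set & net$gene_b %in% gene_set
  subnetwork(owner, gene_set, net[keep, , drop = FALSE], records = records)
}

#' Assemble per-block allele-specific sub-networks
#'
#' For each LD block, collects the perturbation records whose marker lies
#' in the block, takes the union of their edges' endpoint genes, and
#' extracts the induced sub-network from the integrated interactome. The
#' perturbed edges are guaranteed to be contained because both their
#' endpoints are included. Blocks with fewer than `min_edges` distinct
#' perturbed interactions are omitted.
#'
#' @param blocks block table from [find_ld_blocks()].
#' @param records perturbation-record data.frame.
#' @param net an [interactome()].
#' @param min_edges threshold as in [block_association_matrix()].
#' @return named list of [subnetwork()] objects, one per retained block.
#' @export
assemble_block_subnetworks <- function(blocks, records, net, min_edges = 3) {
  m2b <- marker_block_lookup(blocks)
  bl <- m2b$block[match(records$marker, m2b$marker)]
  keep <- !is.na(bl)
  records <- records[keep, , drop = FALSE]
  bl <- bl[keep]
  out <- list()
  for (b in unique(bl)) {
    rec <- records[bl == b, , drop = FALSE]
    n_edges <- length(unique(edge_key(rec$gene_a, rec$gene_b, rec$type)))
    if (n_edges < min_edges) next
    genes <- unique(c(rec$gene_a, rec$gene_b))
    out[[b]] <- extract_subnetwork(net, genes, owner = b, records = rec)
  }
  if (!length(out)) return(out)
  out[order(names(out))]
}
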