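#' Genotype panel
#'
#' Container for biallelic haploid marker calls with a genomic marker map.
#' Calls are coded 0 (parent A allele) / 1 (parent B allele); `NA` marks
#' missing data. No heterozygote code exists: the panel models haploid
#' segregants.
#'
#' @param calls integer matrix, markers in rows, strains in columns, values
#'   in \{0, 1, NA\}; rownames are marker ids, colnames strain ids.
#' @param map data.frame with columns `marker`, `chrom`, `pos` (1-based bp),
#'   one row per marker, in the same order as `calls` rows. Positions must be
#'   strictly increasing within each chromosome.
#' @return An object of class `geno_panel`: a list with elements `calls`
#'   and `map`.
#' @export
geno_panel <- function(calls, map) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls))) stop("calls must have marker rownames")
  if (is.null(colnames(calls))) stop("calls must have strain colnames")
  bad <- !(calls %in% c(0L, 1L, NA))
  if (any(bad)) {
    idx <- which(bad)[1]
    rc <- arrayInd(idx, dim(calls))
    stop(sprintf("non-biallelic genotype code at marker '%s', strain '%s': %s",
                 rownames(calls)[rc[1]], colnames(calls)[rc[2]],
                 calls[idx]))
  }
  storage.mode(calls) <- "integer"
  stopifnot(is.data.frame(map), all(c("marker", "chrom", "pos") %in% names(map)))
  if (nrow(map) != nrow(calls) || !identical(as.character(map$marker), rownames(calls)))
    stop("map rows must match calls rownames in order")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0)) stop(sprintf("marker positions not strictly increasing on chromosome %s", ch))
  }
  structure(list(calls = calls, map = map), class = "geno_panel")
}

#' @export
print.geno_panel <- function(x, ...) {
  cat(sprintf("geno_panel: %d markers x %d strains on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chrom))))
  invisible(x)
}

#' Expression panel
#'
#' Expression values for segregants plus optional parental replicate
#' measurements (needed only by the heritability stage).
#'
#' @param values numeric matrix, genes in rows, strains in columns.
#' @param parent_a,parent_b optional numeric matrices of parental replicate
#'   expression (same genes, replicates in columns), or `NULL`.
#' @return An object of class `expression_panel`.
#' @export
expression_panel <- function(values, parent_a = NULL, parent_b = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have gene rownames")
  if (is.null(colnames(values))) stop("values must have strain colnames")
  for (p in list(parent_a, parent_b)) {
    if (!is.null(p) && !identical(rownames(as.matrix(p)), rownames(values)))
      stop("parent matrices must cover the same genes, in order")
  }
  structure(list(values = values, parent_a = parent_a, parent_b = parent_b),
            class = "expression_panel")
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("expression_panel: %d genes x %d strains%s\n",
              nrow(x$values), ncol(x$values),
              if (!is.null(x$parent_a)) sprintf(", parental reps %d + %d",
                                                ncol(x$parent_a), ncol(x$parent_b)) else ""))
  invisible(x)
}

#' Interaction types treated as directed
#' @keywords internal
DIRECTED_TYPES <- c("PDI", "KPI")

#' Known interaction types
#' @keywords internal
INTERACTION_TYPES <- c("PPI", "PDI", "KPI", "EEI")

#' Typed interactome
#'
#' A multi-layer molecular interaction network held as a typed edge list.
#' Protein-DNA (PDI, regulator -> target) and kinase-substrate (KPI,
#' kinase -> substrate) edges are directed; protein-protein (PPI) and
#' enzyme-enzyme (EEI) edges are undirected and stored with endpoints in
#' lexicographic order. Duplicate edges within a type are collapsed; the
#' same gene pair may carry edges of several types.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `type`.
#' @return An object of class `interactome` (a canonicalized edge
#'   data.frame).
#' @export
interactome <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("gene_a", "gene_b", "type") %in% names(edges)))
  edges$gene_a <- as.character(edges$gene_a)
  edges$gene_b <- as.character(edges$gene_b)
  edges$type <- as.character(edges$type)
  unknown <- setdiff(unique(edges$type), INTERACTION_TYPES)
  if (length(unknown))
    stop(sprintf("unknown interaction type(s): %s", paste(unknown, collapse = ", ")))
  if (any(edges$gene_a == edges$gene_b)) stop("self-loops are not allowed")
  undir <- !(edges$type %in% DIRECTED_TYPES)
  flip <- undir & edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[flip]
  edges$gene_a[flip] <- edges$gene_b[flip]
  edges$gene_b[flip] <- tmp
  key <- paste(edges$gene_a, edges$gene_b, edges$type, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) message(sprintf("collapsed %d duplicate edge(s)", sum(dup)))
  edges <- edges[!dup, c("gene_a", "gene_b", "type"), drop = FALSE]
  rownames(edges) <- NULL
  class(edges) <- c("interactome", "data.frame")
  edges
}

#' Genes covered by an interactome
#' @param net an [interactome()].
#' @return character vector of gene ids.
#' @export
interactome_genes <- function(net) sort(unique(c(net$gene_a, net$gene_b)))

#' Stable identifier of a typed edge
#' @keywords internal
edge_key <- function(gene_a, gene_b, type) paste(gene_a, gene_b, type, sep = "|")

#' Undirected simple-graph view of an interactome
#'
#' Collapses edge direction and parallel typed edges between the same gene
#' pair into single undirected edges; the view used by all topology
#' statistics.
#'
#' @param net an [interactome()].
#' @return an igraph undirected simple graph over all interactome genes.
#' @export
as_undirected_graph <- function(net) {
  genes <- interactome_genes(net)
  pair <- unique(data.frame(
    a = pmin(net$gene_a, net$gene_b),
    b = pmax(net$gene_a, net$gene_b)))
  igraph::graph_from_data_frame(pair, directed = FALSE,
                                vertices = data.frame(name = genes))
}

#' Perturbed sub-network
#'
#' A gene set together with the edges of the integrated interactome induced
#' on it, owned by an LD block or a compound.
#'
#' @param owner block or compound id.
#' @param genes character vector of gene ids.
#' @param edges typed edge data.frame (subset of the interactome rows).
#' @param records optional perturbation-record data.frame backing the
#'   sub-network (provenance).
#' @return An object of class `subnetwork`.
#' @export
subnetwork <- function(owner, genes, edges, records = NULL) {
  structure(list(owner = owner, genes = sort(unique(genes)),
                 edges = edges, records = records),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("subnetwork '%s': %d genes, %d induced edges\n",
              x$owner, length(x$genes), nrow(x$edges)))
  invisible(x)
}
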