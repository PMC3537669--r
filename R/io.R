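#' Read a genotype TSV
#'
#' Expected layout: header row, columns `marker`, `chrom`, `pos`, then one
#' column per strain with calls in \{0, 1, NA\}. Any other code is
#' rejected with the offending row and column named. CRLF and LF line
#' endings parse identically.
#'
#' @param path file path.
#' @return a [geno_panel()].
#' @export
read_genotypes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(df)))
    stop("genotype file must have marker, chrom, pos columns")
  if (anyDuplicated(df$marker))
    stop(sprintf("duplicate marker id: %s", df$marker[duplicated(df$marker)][1]))
  strains <- setdiff(names(df), need)
  calls <- as.matrix(df[, strains, drop = FALSE])
  rownames(calls) <- df$marker
  geno_panel(calls, df[, need])
}

#' Write a genotype TSV
#' @param genotypes a [geno_panel()].
#' @param path file path.
#' @export
write_genotypes <- function(genotypes, path) {
  out <- cbind(genotypes$map, as.data.frame(genotypes$calls, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read an expression TSV (genes x strains)
#'
#' First column `gene`, then one numeric column per strain (or parental
#' replicate).
#'
#' @param path file path.
#' @return numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene") stop("expression file must start with a 'gene' column")
  if (anyDuplicated(df$gene))
    stop(sprintf("duplicate gene id: %s", df$gene[duplicated(df$gene)][1]))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix TSV
#' @param mat numeric matrix with gene rownames.
#' @param path file path.
#' @export
write_expression <- function(mat, path) {
  out <- data.frame(gene = rownames(mat), as.data.frame(mat, check.names = FALSE),
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a phenotype TSV
#'
#' Columns `compound`, `time`, `concentration`, then one column per
#' strain.
#'
#' @param path file path.
#' @param genotypes optional [geno_panel()]; when given, strain columns
#'   must all be known genotyped strains.
#' @return phenotype data.frame.
#' @export
read_phenotypes <- function(path, genotypes = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("compound", "time", "concentration")
  if (!all(need %in% names(df)))
    stop("phenotype file must have compound, time, concentration columns")
  if (!is.null(genotypes)) {
    strains <- setdiff(names(df), need)
    bad <- setdiff(strains, colnames(genotypes$calls))
    if (length(bad))
      stop(sprintf("phenotype strain column(s) not in genotypes: %s",
                   paste(head(bad, 5), collapse = ", ")))
  }
  df
}

#' Write a phenotype TSV
#' @param phenotypes phenotype data.frame.
#' @param path file path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a typed edge-list TSV into an interactome
#'
#' Columns `gene_a`, `gene_b`, `type` with type among PPI, PDI, KPI, EEI.
#' Undirected types are canonicalized and duplicates within a type
#' collapsed (with a message reporting the count).
#'
#' @param path file path.
#' @return an [interactome()].
#' @export
read_interactome <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("gene_a", "gene_b", "type") %in% names(df)))
    stop("interactome file must have gene_a, gene_b, type columns")
  interactome(df)
}

#' Write an interactome edge-list TSV
#' @param net an [interactome()].
#' @param path file path.
#' @export
write_interactome <- function(net, path) {
  write.table(as.data.frame(net), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path file path.
#' @return named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3) stop("malformed GMT line: fewer than 3 fields")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1)
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of gene-id vectors.
#' @param path file path.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Write ground truth as JSON
#' @param truth ground-truth list (see [simulate_cross()]).
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

#' Write a simulated dataset to a directory
#'
#' Emits the same file formats the readers consume: genotype, expression
#' (segregants and parental replicates), interactome and phenotype TSVs, a
#' GMT of known target sets, and the ground truth as JSON.
#'
#' @param dataset output of [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotypes(dataset$genotypes, file.path(dir, "genotypes.tsv"))
  write_expression(dataset$expression$values, file.path(dir, "expression.tsv"))
  if (!is.null(dataset$expression$parent_a)) {
    write_expression(dataset$expression$parent_a, file.path(dir, "parent_a.tsv"))
    write_expression(dataset$expression$parent_b, file.path(dir, "parent_b.tsv"))
  }
  write_interactome(dataset$net, file.path(dir, "interactome.tsv"))
  write_phenotypes(dataset$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_gmt(dataset$target_sets, file.path(dir, "target_sets.gmt"))
  write_ground_truth(dataset$truth, file.path(dir, "ground_truth.json"))
  invisible(dir)
}
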