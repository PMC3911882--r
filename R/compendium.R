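#' Expression compendium container
#'
#' An expression compendium is a genes x samples matrix of normalized,
#' log-scale expression values, the basic currency of both the training and
#' the testing phase. Gene and sample identifiers must be unique and every
#' value finite.
#'
#' @param values numeric matrix, genes in rows and samples in columns. Row and
#'   column names are used as identifiers when `genes`/`samples` are missing.
#' @param genes character vector of gene identifiers (length `nrow(values)`).
#' @param samples character vector of sample identifiers (length
#'   `ncol(values)`).
#' @param metadata optional data.frame of per-sample annotations (condition
#'   label, replicate id, exposure time, concentration ...), one row per
#'   sample.
#'
#' @return An object of class `expr_compendium`: a list with elements
#'   `values` (named matrix) and `metadata`.
#' @export
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' comp <- expression_compendium(m)
#' n_genes(comp); n_samples(comp)
expression_compendium <- function(values, genes = rownames(values),
                                  samples = colnames(values),
                                  metadata = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stopf("expression values must be numeric")
  if (is.null(genes) || is.null(samples))
    stopf("gene and sample identifiers are required (dimnames or arguments)")
  genes <- as.character(genes)
  samples <- as.character(samples)
  if (length(genes) != nrow(values) || length(samples) != ncol(values))
    stopf("identifier lengths (%d genes, %d samples) do not match the %d x %d value matrix",
          length(genes), length(samples), nrow(values), ncol(values))
  dup <- genes[duplicated(genes)]
  if (length(dup)) stopf("duplicate gene identifier(s): %s",
                         paste(unique(dup), collapse = ", "))
  dup <- samples[duplicated(samples)]
  if (length(dup)) stopf("duplicate sample identifier(s): %s",
                         paste(unique(dup), collapse = ", "))
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stopf("non-finite expression value at gene '%s', sample '%s'",
          genes[bad[1L]], samples[bad[2L]])
  }
  dimnames(values) <- list(genes, samples)
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (nrow(metadata) != length(samples))
      stopf("metadata must have one row per sample")
    rownames(metadata) <- samples
  }
  structure(list(values = values, metadata = metadata),
            class = "expr_compendium")
}

#' @rdname expression_compendium
#' @param x an `expr_compendium`.
#' @export
n_genes <- function(x) nrow(x$values)

#' @rdname expression_compendium
#' @export
n_samples <- function(x) ncol(x$values)

#' @rdname expression_compendium
#' @export
compendium_genes <- function(x) rownames(x$values)

#' @rdname expression_compendium
#' @export
compendium_samples <- function(x) colnames(x$values)

#' @export
print.expr_compendium <- function(x, ...) {
  cat(sprintf("Expression compendium: %d genes x %d samples\n",
              n_genes(x), n_samples(x)))
  if (!is.null(x$metadata))
    cat("  metadata columns:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' Read a tab-delimited expression table
#'
#' Expects a header row of sample identifiers, a first column of gene
#' identifiers and a numeric body. Row and column order of the file is
#' preserved.
#'
#' @param path path to a tab-delimited file.
#' @return An [expression_compendium()].
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", row.names = NULL)
  if (ncol(raw) < 2L) stopf("expression table needs a gene column and at least one sample column: %s", path)
  genes <- raw[[1L]]
  body <- raw[-1L]
  mat <- matrix(NA_real_, nrow(raw), ncol(body))
  for (j in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !is.na(body[[j]]))
    if (length(bad))
      stopf("non-numeric cell at row %d (gene '%s'), column '%s'",
            bad[1L], genes[bad[1L]], names(body)[j])
    mat[, j] <- v
  }
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stopf("missing value at row %d, column '%s'", bad[1L], names(body)[bad[2L]])
  }
  expression_compendium(mat, genes = genes, samples = names(body))
}

#' Write an expression compendium as a tab-delimited table
#'
#' Inverse of [read_expression_table()]: full float precision (values survive
#' a write/read round trip), deterministic byte output.
#'
#' @param compendium an `expr_compendium`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(compendium, path) {
  stopifnot(inherits(compendium, "expr_compendium"))
  if (n_samples(compendium) == 0L)
    stopf("refusing to write a compendium with no samples")
  df <- data.frame(gene = compendium_genes(compendium),
                   format(compendium$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("gene", compendium_samples(compendium))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene set from a newline-delimited identifier list
#'
#' Blank lines and lines starting with `#` are ignored; duplicated
#' identifiers are collapsed.
#'
#' @param path path to the gene list file.
#' @param name name for the set (defaults to the file name without extension).
#' @return An object of class `gene_set`: list with `name` and `members`.
#' @export
read_gene_set <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  members <- unique(lines)
  if (!length(members)) stopf("gene set file '%s' contains no identifiers", path)
  gene_set(name, members)
}

#' @rdname read_gene_set
#' @param members character vector of member gene identifiers.
#' @export
gene_set <- function(name, members) {
  members <- unique(as.character(members))
  if (!length(members)) stopf("a gene set must have at least one member")
  structure(list(name = as.character(name), members = members),
            class = "gene_set")
}

#' Append experiments to a training compendium
#'
#' The training-compendium modification: new experiment columns are added to
#' the base compendium so that a new, distinct interaction network can be
#' inferred from the merged table. Genes are aligned by identifier and the
#' base compendium's order wins; both inputs are assumed normalized to a
#' common scale.
#'
#' @param base,extra `expr_compendium` objects over the same gene universe
#'   with disjoint sample identifiers.
#' @return An `expr_compendium` with `n_samples(base) + n_samples(extra)`
#'   samples; base values are unchanged.
#' @export
append_experiments <- function(base, extra) {
  stopifnot(inherits(base, "expr_compendium"), inherits(extra, "expr_compendium"))
  bg <- compendium_genes(base); eg <- compendium_genes(extra)
  missing <- setdiff(bg, eg)
  surplus <- setdiff(eg, bg)
  if (length(missing) || length(surplus))
    stopf("gene universes differ: %s",
          paste(c(if (length(missing)) sprintf("missing from extra: %s",
                                               paste(missing, collapse = ", ")),
                  if (length(surplus)) sprintf("absent from base: %s",
                                               paste(surplus, collapse = ", "))),
                collapse = "; "))
  clash <- intersect(compendium_samples(base), compendium_samples(extra))
  if (length(clash))
    stopf("sample identifier collision: %s", paste(clash, collapse = ", "))
  values <- cbind(base$values, extra$values[bg, , drop = FALSE])
  md <- NULL
  if (!is.null(base$metadata) || !is.null(extra$metadata)) {
    bm <- base$metadata
    em <- extra$metadata
    if (is.null(bm)) bm <- data.frame(row.names = compendium_samples(base))
    if (is.null(em)) em <- data.frame(row.names = compendium_samples(extra))
    cols <- union(names(bm), names(em))
    for (cc in cols) {
      if (is.null(bm[[cc]])) bm[[cc]] <- NA
      if (is.null(em[[cc]])) em[[cc]] <- NA
    }
    md <- rbind(bm[cols], em[cols])
  }
  expression_compendium(values, metadata = md)
}

#' Write a gene ranking as a tab-delimited table
#'
#' Columns `gene`, `residual`, `abs_residual`, `rank`, `percentile`, sorted by
#' rank ascending (rank 1 = strongest candidate target first).
#'
#' @param ranking a `gene_ranking` (see [rank_genes()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranking_table <- function(ranking, path) {
  stopifnot(inherits(ranking, "gene_ranking"))
  p <- length(ranking$genes)
  df <- data.frame(gene = ranking$genes,
                   residual = ranking$residual,
                   abs_residual = ranking$abs_residual,
                   rank = ranking$rank,
                   percentile = rank_percentile(ranking$rank, p),
                   stringsAsFactors = FALSE)
  df <- df[order(df$rank), ]
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ranking table written by [write_ranking_table()]
#'
#' @param path path to the TSV.
#' @return A `gene_ranking`.
#' @export
read_ranking_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  new_gene_ranking(genes = df$gene, residual = df$residual,
                   abs_residual = df$abs_residual, rank = df$rank)
}
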