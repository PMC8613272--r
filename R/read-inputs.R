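#' Read a protein-protein interaction edge list
#'
#' Reads gene-gene interaction pairs from a tab-separated file. Two dialects
#' are supported: a plain two-column edge list (`"two_column"`), and a
#' nine-column flat-file layout with the interactor gene symbols in columns
#' 1 and 4 (`"hprd_flat"`). The result is an undirected simple edge set:
#' duplicate pairs (in either orientation) are collapsed and
#' self-interactions dropped. Gene symbols are matched exactly, case
#' preserved; no alias normalisation is attempted.
#'
#' @param path Path to a tab-separated file without header.
#' @param dialect `"two_column"` (default) or `"hprd_flat"`.
#' @return A tibble with columns `gene_a`, `gene_b`, one row per undirected
#'   interaction, with `gene_a < gene_b` lexicographically.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("TP53\tMDM2", "MDM2\tTP53", "TP53\tEP300"), tf)
#' read_ppi_edges(tf)
#' @export
read_ppi_edges <- function(path, dialect = c("two_column", "hprd_flat")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("PPI file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(paste0("empty PPI file: ", path))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- if (dialect == "two_column") 2L else 4L
  cols <- if (dialect == "two_column") c(1L, 2L) else c(1L, 4L)
  bad <- which(vapply(fields, length, 1L) < need)
  if (length(bad) > 0L)
    abort(sprintf("malformed PPI row at line %d: expected at least %d tab-separated columns",
                  bad[1L], need))
  a <- vapply(fields, `[[`, "", cols[1L])
  b <- vapply(fields, `[[`, "", cols[2L])
  empty <- which(!nzchar(a) | !nzchar(b))
  if (length(empty) > 0L)
    abort(sprintf("malformed PPI row at line %d: empty gene symbol", empty[1L]))

  edges <- tibble(gene_a = pmin(a, b), gene_b = pmax(a, b))
  edges <- distinct(filter(edges, .data$gene_a != .data$gene_b))
  arrange(edges, .data$gene_a, .data$gene_b)
}

#' Read a gene-level copy-number matrix
#'
#' Reads a genes-by-samples integer copy-number table in the common portal
#' export layout: first column gene symbol (`Hugo_Symbol` or any name), an
#' optional Entrez id column (dropped), remaining columns one per sample.
#'
#' @param path Path to a TSV file with a header row.
#' @return A wide tibble with first column `gene` and one numeric column per
#'   sample.
#' @export
read_cn_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(x) < 2L) abort("copy-number matrix needs a gene column and at least one sample column")
  names(x)[1L] <- "gene"
  drop <- grepl("^entrez", names(x), ignore.case = TRUE)
  x <- x[!drop]
  if (anyDuplicated(x$gene))
    abort("duplicate gene symbols in copy-number matrix")
  x$gene <- as.character(x$gene)
  as_tibble(x)
}

#' Read copy-number segments (SEG layout)
#'
#' Reads a tab-separated segment file with a header row; the first five
#' columns are interpreted as sample identifier, chromosome, start, end and
#' segment value (total copy number, or a log2/linear ratio for
#' fraction-genome-altered use). Extra columns are ignored. Coordinates are
#' 1-based inclusive.
#'
#' @param path Path to a SEG file.
#' @return A tibble with columns `sample`, `chrom`, `start`, `end`, `value`.
#' @export
read_seg <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(x) < 5L) abort("SEG file needs at least 5 columns (sample, chrom, start, end, value)")
  x <- x[, 1:5]
  names(x) <- c("sample", "chrom", "start", "end", "value")
  x$sample <- as.character(x$sample)
  x$chrom <- as.character(x$chrom)
  if (any(!is.finite(x$start)) || any(!is.finite(x$end)))
    abort("non-numeric segment coordinates")
  if (any(x$end < x$start)) abort("segment with end < start")
  as_tibble(x)
}

#' Read gene models (GRCh37 coordinates)
#'
#' Reads gene coordinates from a 4-column BED file (0-based half-open,
#' converted internally to 1-based inclusive) or a minimal GTF (1-based
#' inclusive, `gene_name` or `gene_id` attribute used as the symbol; only
#' `gene` feature rows are used when present).
#'
#' @param path Path to a BED or GTF file.
#' @param format `"bed"` or `"gtf"`; guessed from the file extension when
#'   missing.
#' @return A tibble with columns `symbol`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_gene_models <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "bed"
  }
  format <- match.arg(format, c("bed", "gtf"))
  if (format == "bed") {
    x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE, comment = "#")
    if (ncol(x) < 4L) abort("BED gene models need 4 columns (chrom, start, end, name)")
    out <- tibble(
      symbol = as.character(x[[4L]]),
      chrom = as.character(x[[1L]]),
      start = as.integer(x[[2L]]) + 1L, # 0-based half-open -> 1-based inclusive
      end = as.integer(x[[3L]])
    )
  } else {
    x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE, comment = "#")
    if (ncol(x) < 9L) abort("GTF gene models need 9 columns")
    if (any(x[[3L]] == "gene")) x <- x[x[[3L]] == "gene", ]
    attr_col <- x[[9L]]
    sym <- sub('.*gene_name[ =]"?([^";]+)"?.*', "\\1", attr_col)
    no_name <- !grepl("gene_name", attr_col)
    sym[no_name] <- sub('.*gene_id[ =]"?([^";]+)"?.*', "\\1", attr_col[no_name])
    out <- tibble(
      symbol = sym,
      chrom = as.character(x[[1L]]),
      start = as.integer(x[[4L]]),
      end = as.integer(x[[5L]])
    )
  }
  if (any(out$end < out$start)) abort("gene model with end < start")
  if (any(!nzchar(out$symbol))) abort("gene model with empty symbol")
  if (anyDuplicated(out$symbol)) abort("duplicate gene symbols in gene models")
  out
}

#' Read a clinical table
#'
#' Reads a tab-separated clinical table. Columns `sample`, `os_months` and
#' `event` are required; `event` may be 0/1 or logical. Any further columns
#' (e.g. `tmb`, `fga`, `lst`, `sample_type`, `vital_status`) are carried
#' through unchanged.
#'
#' @param path Path to a TSV file with a header row.
#' @return A tibble with at least `sample`, `os_months`, `event` (logical).
#' @export
read_clinical <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample", "os_months", "event")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0L)
    abort(paste0("clinical table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  x$sample <- as.character(x$sample)
  if (any(x$os_months < 0, na.rm = TRUE)) abort("negative survival times")
  x$event <- as.logical(x$event)
  as_tibble(x)
}
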