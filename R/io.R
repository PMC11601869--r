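#' Write / read a time-course expression matrix as CSV
#'
#' Wide layout: genes as rows (`gene` column), one column per sample named
#' `<genotype>_<age>m_r<rep>`. Values round-trip exactly through their
#' decimal representation.
#'
#' @param data A `timecourse_sim` or long tibble with columns `gene`,
#'   `sample_id`, `log2_expr`.
#' @param path File path.
#' @return `path` invisibly (writer); a long tibble with `gene`, `genotype`,
#'   `timepoint`, `replicate`, `sample_id`, `log2_expr` (reader).
#' @export
write_expression_csv <- function(data, path) {
  if (inherits(data, "timecourse_sim")) data <- data$expression
  wide <- data |>
    dplyr::select(dplyr::all_of(c("gene", "sample_id", "log2_expr"))) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "log2_expr")
  readr::write_csv(wide, path)
  invisible(path)
}

#' @rdname write_expression_csv
#' @export
read_expression_csv <- function(path) {
  hdr <- strsplit(readr::read_lines(path, n_max = 1), ",", fixed = TRUE)[[1]]
  if (length(hdr) < 2 || hdr[1] != "gene") {
    stop("malformed header: first column must be `gene`.", call. = FALSE)
  }
  wide <- readr::read_csv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_double()
  ))
  if (nrow(readr::problems(wide))) {
    pr <- readr::problems(wide)[1, ]
    stop(sprintf("parse error at row %d, column %d of %s.",
                 pr$row, pr$col, path), call. = FALSE)
  }
  dup <- wide$gene[duplicated(wide$gene)]
  if (length(dup)) {
    stop(sprintf("duplicate gene id(s): %s.",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  samples <- names(wide)[-1]
  m <- stringr::str_match(samples, "^(.*)_([0-9.]+)m_r([0-9]+)$")
  if (anyNA(m[, 1])) {
    stop(sprintf("malformed sample column(s): %s (expected <genotype>_<age>m_r<rep>).",
                 paste(samples[is.na(m[, 1])], collapse = ", ")),
         call. = FALSE)
  }
  meta <- tibble::tibble(sample_id = samples, genotype = m[, 2],
                         timepoint = as.numeric(m[, 3]),
                         replicate = as.integer(m[, 4]))
  wide |>
    tidyr::pivot_longer(-"gene", names_to = "sample_id",
                        values_to = "log2_expr") |>
    dplyr::left_join(meta, by = "sample_id") |>
    dplyr::arrange(.data$timepoint, .data$replicate) |>
    dplyr::select(dplyr::all_of(c("gene", "genotype", "timepoint",
                                  "replicate", "sample_id", "log2_expr")))
}

#' Write / read a proteomics intensity table as CSV
#'
#' Wide layout: proteins as rows, one column per sample named
#' `<genotype>_<age>m_r<rep>`; empty cells are missing values.
#'
#' @param data A `proteome_sim` or long tibble with columns `protein`,
#'   `genotype`, `timepoint`, `replicate`, `intensity`.
#' @param path File path.
#' @return `path` invisibly (writer); the long tibble (reader).
#' @export
write_proteome_csv <- function(data, path) {
  if (inherits(data, "proteome_sim")) data <- data$intensities
  wide <- data |>
    dplyr::mutate(sample_id = sprintf("%s_%gm_r%d", .data$genotype,
                                      .data$timepoint, .data$replicate)) |>
    dplyr::select(dplyr::all_of(c("protein", "sample_id", "intensity"))) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "intensity")
  readr::write_csv(wide, path, na = "")
  invisible(path)
}

#' @rdname write_proteome_csv
#' @export
read_proteome_csv <- function(path) {
  wide <- readr::read_csv(path, col_types = readr::cols(
    protein = readr::col_character(), .default = readr::col_double()
  ), na = "")
  samples <- names(wide)[-1]
  m <- stringr::str_match(samples, "^(.*)_([0-9.]+)m_r([0-9]+)$")
  if (anyNA(m[, 1])) {
    stop("malformed proteome sample column(s).", call. = FALSE)
  }
  meta <- tibble::tibble(sample_id = samples, genotype = m[, 2],
                         timepoint = as.numeric(m[, 3]),
                         replicate = as.integer(m[, 4]))
  wide |>
    tidyr::pivot_longer(-"protein", names_to = "sample_id",
                        values_to = "intensity") |>
    dplyr::left_join(meta, by = "sample_id") |>
    dplyr::select(dplyr::all_of(c("protein", "genotype", "timepoint",
                                  "replicate", "intensity")))
}

#' Write / read a cohort table as TSV
#'
#' Columns: `sample_id`, `age_years`, `os_time`, `os_event`, and optionally
#' `group`.
#'
#' @param data A `cohort_sim` or cohort data frame.
#' @param path File path.
#' @return `path` invisibly (writer); a tibble (reader).
#' @export
write_cohort_tsv <- function(data, path) {
  if (inherits(data, "cohort_sim")) data <- data$cohort
  readr::write_tsv(data, path)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols())
  need <- c("sample_id", "age_years", "os_time", "os_event")
  if (!all(need %in% names(d))) {
    stop(sprintf("cohort table must have columns %s.",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (any(d$os_time < 0)) stop("`os_time` must be >= 0.", call. = FALSE)
  if (any(d$age_years <= 0)) stop("`age_years` must be > 0.", call. = FALSE)
  d
}

#' Read / write gene sets in GMT format
#'
#' Tab-separated, one set per line: name, description, then gene ids. Blank
#' gene fields are dropped; duplicated genes within a set are removed with a
#' warning.
#'
#' @param path File path.
#' @return Named list of character vectors, with set descriptions in the
#'   `descriptions` attribute (reader).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file.", call. = FALSE)
    return(structure(list(), descriptions = character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) {
    stop(sprintf("GMT line %d has fewer than 3 fields.", which(bad)[1]),
         call. = FALSE)
  }
  sets <- lapply(parts, function(p) {
    genes <- p[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicate gene(s) in set `%s` deduplicated.", p[1]),
              call. = FALSE)
      genes <- unique(genes)
    }
    genes
  })
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "descriptions") <- vapply(parts, `[`, character(1), 2)
  sets
}

#' @rdname read_gmt
#' @param gene_sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(gene_sets))
  lines <- purrr::imap_chr(gene_sets, function(gs, nm) {
    paste(c(nm, descriptions[[match(nm, names(gene_sets))]], gs),
          collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write / read single-cell counts as MatrixMarket triplets
#'
#' 10x-style layout in `dir`: `matrix.mtx` (genes x cells, 1-based integer
#' triplets), `features.tsv` (one gene id per line), `barcodes.tsv` (one
#' barcode per line).
#'
#' @param counts Cell x gene matrix (sparse or dense); a `cells_sim` is also
#'   accepted.
#' @param dir Output directory (created if missing).
#' @return `dir` invisibly (writer); a sparse cell x gene dgCMatrix (reader).
#' @export
write_mtx_counts <- function(counts, dir) {
  if (inherits(counts, "cells_sim")) counts <- counts$counts
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::t(Matrix::Matrix(counts, sparse = TRUE)),
                   "generalMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  readr::write_lines(colnames(counts), file.path(dir, "features.tsv"))
  readr::write_lines(rownames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_mtx_counts
#' @export
read_mtx_counts <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  features <- readr::read_lines(file.path(dir, "features.tsv"))
  barcodes <- readr::read_lines(file.path(dir, "barcodes.tsv"))
  if (nrow(m) != length(features) || ncol(m) != length(barcodes)) {
    stop("matrix dimensions do not match features/barcodes.", call. = FALSE)
  }
  out <- methods::as(Matrix::t(m), "CsparseMatrix")
  dimnames(out) <- list(barcodes, features)
  out
}
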