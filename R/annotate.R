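#' Log2 feature-sum score per cell
#'
#' For each cell, `log2(1 + sum of counts over the listed genes)`. Genes
#' absent from the matrix are skipped with a warning.
#'
#' @param counts Cell x gene matrix (dense or sparse), non-negative.
#' @param features Character vector of gene ids.
#' @return Numeric vector, one score per cell.
#' @export
feature_score <- function(counts, features) {
  if (!length(features)) stop("`features` must be non-empty.", call. = FALSE)
  present <- intersect(features, colnames(counts))
  if (!length(present)) {
    stop("none of the listed genes are present in the matrix.", call. = FALSE)
  }
  if (length(present) < length(features)) {
    warning(sprintf("skipping %d absent gene(s): %s",
                    length(features) - length(present),
                    paste(setdiff(features, present), collapse = ", ")),
            call. = FALSE)
  }
  s <- Matrix::rowSums(counts[, present, drop = FALSE])
  log2(1 + as.numeric(s))
}

#' Half-max feature-sum gate
#'
#' Gates cells on a combined feature list: a cell passes when its log2
#' feature-sum score reaches half of the maximum score across cells (the
#' half-max convention used to call proliferating and regulon-positive
#' cells).
#'
#' @inheritParams feature_score
#' @return Logical vector, one gate per cell.
#' @examples
#' m <- matrix(c(1023, 31, 30), ncol = 1,
#'             dimnames = list(NULL, "Cenpe"))
#' feature_sum_gate(m, "Cenpe") # scores 10, 5, ~4.95 -> TRUE TRUE FALSE
#' @export
feature_sum_gate <- function(counts, features) {
  s <- feature_score(counts, features)
  if (all(s == 0)) {
    warning("all feature sums are zero; every gate is FALSE.", call. = FALSE)
    return(rep(FALSE, length(s)))
  }
  s >= max(s) / 2
}

#' Annotate mammary epithelial cell types from marker panels
#'
#' Deterministic score-based replacement for interactive cluster gating.
#' Each cell gets a log2 feature-sum score per panel (HS, AV, ME). The label
#' is the arg-max panel provided its score reaches that panel's `min_score`
#' (default: half of the panel's maximum score across cells, the half-max
#' convention). Cells whose HS and AV scores are both above threshold and
#' within a relative margin of each other are labelled the mixed lineage
#' `HS-AV`. Cells passing no gate are `unassigned`. Proliferating and
#' regulon gates use [feature_sum_gate()]; their conjunction is the
#' PPBC-like flag.
#'
#' @param counts Cell x gene matrix (cells in rows), non-negative.
#' @param panel Marker panels as [marker_panels()].
#' @param min_score Named numeric vector of per-panel score thresholds
#'   (`HS`, `AV`, `ME`); `NULL` for the half-max default.
#' @param hs_av_margin Relative margin within which HS and AV scores count as
#'   co-expressed (default 0.25).
#' @return Tibble of class `cell_annotation`: `barcode`, `label` (one of
#'   `HS`, `AV`, `HS-AV`, `ME`, `unassigned`), `score_HS`, `score_AV`,
#'   `score_ME`, `proliferating`, `regulon`, `ppbc_like`.
#' @examples
#' sim <- simulate_cells(cells_per_sample = 200, background_rate = 0, seed = 1)
#' ann <- annotate_cells(sim$counts, sim$panel)
#' table(ann$label)
#' @export
annotate_cells <- function(counts, panel = marker_panels(), min_score = NULL,
                           hs_av_margin = 0.25) {
  if (any(counts < 0)) stop("`counts` must be non-negative.", call. = FALSE)
  sc <- sapply(c("HS", "AV", "ME"), function(p) feature_score(counts, panel[[p]]))
  if (is.null(dim(sc))) sc <- matrix(sc, nrow = 1, dimnames = list(NULL, c("HS", "AV", "ME")))
  if (is.null(min_score)) {
    min_score <- apply(sc, 2, max) / 2
  } else {
    min_score <- min_score[c("HS", "AV", "ME")]
  }
  pass <- sweep(sc, 2, min_score, `>=`)

  both_la <- pass[, "HS"] & pass[, "AV"] &
    abs(sc[, "HS"] - sc[, "AV"]) <= hs_av_margin * pmax(sc[, "HS"], sc[, "AV"])
  best <- colnames(sc)[max.col(sc, ties.method = "first")]
  best_pass <- pass[cbind(seq_len(nrow(sc)), max.col(sc, ties.method = "first"))]
  label <- ifelse(both_la, "HS-AV", ifelse(best_pass, best, "unassigned"))

  gate_or_false <- function(features, name) {
    tryCatch(suppressWarnings(feature_sum_gate(counts, features)),
             error = function(e) {
               warning(sprintf("no %s panel gene in the matrix; gate FALSE.",
                               name), call. = FALSE)
               rep(FALSE, nrow(counts))
             })
  }
  proliferating <- gate_or_false(panel$proliferating, "proliferating")
  regulon <- gate_or_false(panel$regulon, "regulon")

  out <- tibble::tibble(
    barcode = rownames(counts) %||% sprintf("cell_%06d", seq_len(nrow(counts))),
    label = label,
    score_HS = sc[, "HS"], score_AV = sc[, "AV"], score_ME = sc[, "ME"],
    proliferating = proliferating,
    regulon = regulon,
    ppbc_like = proliferating & regulon
  )
  class(out) <- c("cell_annotation", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cell-type composition ratios over the luminal denominator
#'
#' The total luminal epithelial count LE = #HS + #AV + #HS-AV is the common
#' denominator; each sub-type count is reported as a ratio over LE, so the
#' three luminal ratios sum to 1 and ME/LE can exceed its luminal
#' counterparts' range.
#'
#' @param annotation A `cell_annotation` tibble (or any data frame with a
#'   `label` column), optionally carrying a `sample_id` column for per-sample
#'   ratios.
#' @param sample_info Optional data frame with `barcode` and grouping columns
#'   (e.g. `sample_id`, `timepoint`) to join before grouping.
#' @return Tibble with one row per sample (or a single row): `n_HS`, `n_AV`,
#'   `n_HS_AV`, `n_ME`, `LE`, `HS_LE`, `AV_LE`, `HS_AV_LE`, `ME_LE`.
#' @examples
#' ann <- tibble::tibble(label = rep(c("HS", "AV", "HS-AV", "ME"),
#'                                   c(10, 5, 5, 4)))
#' composition_ratios(ann)
#' @export
composition_ratios <- function(annotation, sample_info = NULL) {
  d <- tibble::as_tibble(annotation)
  if (!is.null(sample_info)) {
    d <- dplyr::left_join(d, tibble::as_tibble(sample_info), by = "barcode")
  }
  grp <- intersect(c("sample_id", "timepoint"), names(d))
  out <- d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_HS = sum(.data$label == "HS"),
      n_AV = sum(.data$label == "AV"),
      n_HS_AV = sum(.data$label == "HS-AV"),
      n_ME = sum(.data$label == "ME"),
      .groups = "drop"
    ) |>
    dplyr::mutate(LE = .data$n_HS + .data$n_AV + .data$n_HS_AV)
  if (any(out$LE == 0)) {
    stop("a sample has no luminal (HS/AV/HS-AV) cells; ratios undefined.",
         call. = FALSE)
  }
  dplyr::mutate(
    out,
    HS_LE = .data$n_HS / .data$LE,
    AV_LE = .data$n_AV / .data$LE,
    HS_AV_LE = .data$n_HS_AV / .data$LE,
    ME_LE = .data$n_ME / .data$LE
  )
}
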