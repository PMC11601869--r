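#' Presence/absence detection matrix for a proteomics table
#'
#' A protein is DETECTED in a genotype x timepoint block when at least
#' `min_detect` replicates have a non-missing intensity at or above the
#' detection floor.
#'
#' @param data A `proteome_sim` or data frame with columns `protein`,
#'   `genotype`, `timepoint`, `replicate`, `intensity` (`NA` = missing).
#' @param detection_floor Intensity threshold for a detected measurement.
#' @param min_detect Minimum detected replicates per block; default the
#'   majority rule `ceiling(n_replicates / 2)`.
#' @return Tibble with `protein`, `genotype`, `timepoint`, `n_detected`,
#'   `detected`.
#' @export
detection_table <- function(data, detection_floor = 15, min_detect = NULL) {
  if (inherits(data, "proteome_sim")) {
    if (is.null(min_detect)) {
      min_detect <- ceiling(data$config$n_replicates / 2)
    }
    detection_floor <- data$config$detection_floor
    data <- data$intensities
  }
  need <- c("protein", "genotype", "timepoint", "intensity")
  if (!all(need %in% names(data))) {
    stop("`data` needs columns protein, genotype, timepoint, intensity.",
         call. = FALSE)
  }
  if (detection_floor < 0) stop("`detection_floor` must be >= 0.", call. = FALSE)
  n_rep <- data |>
    dplyr::count(.data$protein, .data$genotype, .data$timepoint) |>
    dplyr::pull(.data$n) |>
    max()
  if (is.null(min_detect)) min_detect <- ceiling(n_rep / 2)
  if (min_detect > n_rep) {
    stop("`min_detect` exceeds the replicate count.", call. = FALSE)
  }
  data |>
    dplyr::group_by(.data$protein, .data$genotype, .data$timepoint) |>
    dplyr::summarise(
      n_detected = sum(!is.na(.data$intensity) &
                         .data$intensity >= detection_floor),
      .groups = "drop"
    ) |>
    dplyr::mutate(detected = .data$n_detected >= min_detect)
}

#' Call cyclic (phase-restricted, genotype-unique) proteins
#'
#' A protein is called cyclic when it is detected at the 2nd and 4th ages
#' (the 11/19-month phase) in the designated genotype, NOT detected at the
#' 1st and 3rd ages in that genotype, and NOT detected at any age in the
#' other genotype. Detection uses the majority rule of [detection_table()]
#' by default. The call is deterministic, invariant to replicate order and to
#' rescaling intensities above the floor.
#'
#' @inheritParams detection_table
#' @param cyclic_genotype Genotype in which the cyclic pattern is sought;
#'   defaults to the generator's designated genotype for `proteome_sim`
#'   input, otherwise must be supplied.
#' @return Tibble of class `cyclic_protein_calls`: one row per called
#'   protein.
#' @examples
#' sim <- simulate_proteome(n_background = 30, n_cyclic = 5, seed = 1)
#' call_cyclic_proteins(sim)
#' @export
call_cyclic_proteins <- function(data, cyclic_genotype = NULL,
                                 detection_floor = 15, min_detect = NULL) {
  if (inherits(data, "proteome_sim")) {
    if (is.null(cyclic_genotype)) cyclic_genotype <- data$config$cyclic_genotype
  }
  det <- detection_table(data, detection_floor = detection_floor,
                         min_detect = min_detect)
  genotypes <- unique(det$genotype)
  if (is.null(cyclic_genotype)) {
    stop("`cyclic_genotype` must be supplied for data-frame input.",
         call. = FALSE)
  }
  if (!cyclic_genotype %in% genotypes) {
    stop(sprintf("genotype `%s` not present in the data.", cyclic_genotype),
         call. = FALSE)
  }
  if (length(genotypes) < 2) {
    stop("cyclic-protein calling needs both genotypes.", call. = FALSE)
  }
  tps <- sort(unique(det$timepoint))
  if (length(tps) != 4) {
    stop("cyclic-protein calling needs exactly 4 timepoints.", call. = FALSE)
  }
  on_tp <- tps[c(2, 4)]

  calls <- det |>
    dplyr::mutate(
      want = .data$genotype == cyclic_genotype & .data$timepoint %in% on_tp
    ) |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(
      cyclic = all(.data$detected == .data$want),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$cyclic) |>
    dplyr::select(dplyr::all_of("protein"))
  class(calls) <- c("cyclic_protein_calls", class(calls))
  attr(calls, "cyclic_genotype") <- cyclic_genotype
  attr(calls, "on_timepoints") <- on_tp
  calls
}

#' Differential protein abundance between two groups
#'
#' Unpaired t-test (Welch by default) on log2 intensities between the two
#' levels of `group`, with BH adjustment across tested proteins. Proteins
#' with fewer than 2 non-missing replicates in either group are reported as
#' untested (`tested = FALSE`, `NA` statistics).
#'
#' @param data Data frame with columns `protein`, `intensity` and the
#'   grouping column; `NA` intensities are dropped per protein.
#' @param group Name of the grouping column (must have exactly 2 levels);
#'   `log2fc` is level2 minus level1 in sorted order.
#' @param q_max Significance threshold reported in the `significant` column.
#' @param var_equal Pooled-variance Student t instead of Welch.
#' @return Tibble with `protein`, `log2fc`, `statistic`, `df`, `p`, `q`,
#'   `tested`, `significant`.
#' @export
differential_proteins <- function(data, group = "group", q_max = 0.05,
                                  var_equal = FALSE) {
  if (!group %in% names(data)) {
    stop(sprintf("grouping column `%s` not found.", group), call. = FALSE)
  }
  lv <- sort(unique(data[[group]]))
  if (length(lv) != 2) stop("`group` must have exactly 2 levels.", call. = FALSE)
  counts <- table(data[[group]])
  if (any(counts == 0)) stop("both groups must be non-empty.", call. = FALSE)

  res <- data |>
    dplyr::filter(!is.na(.data$intensity)) |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(
      t_out = list(two_group_t(.data$intensity, .data[[group]] == lv[2],
                               var_equal)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("t_out")

  tested <- res$tested
  res$q <- NA_real_
  if (any(tested)) res$q[tested] <- bh_adjust(res$p[tested])
  res$significant <- !is.na(res$q) & res$q < q_max
  res
}

two_group_t <- function(x, is_b, var_equal) {
  a <- x[!is_b]; b <- x[is_b]
  if (length(a) < 2 || length(b) < 2) {
    return(list(log2fc = NA_real_, statistic = NA_real_, df = NA_real_,
                p = NA_real_, tested = FALSE))
  }
  out <- welch_rows(matrix(a, 1), matrix(b, 1), "x", var_equal)
  list(log2fc = out$log2fc, statistic = out$statistic, df = out$df,
       p = out$p, tested = TRUE)
}
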