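#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Kaplan-Meier curve
#'
#' Step-function survival curve with censoring marks.
#'
#' @param object A `km_curve` from [km_estimate()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.km_curve <- function(object, ...) {
  d <- dplyr::bind_rows(
    tibble::tibble(time = 0, surv = 1),
    tibble::tibble(time = object$time, surv = object$surv)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(
      data = dplyr::filter(tibble::as_tibble(object), .data$n_censor > 0),
      shape = 3
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Overlayed Kaplan-Meier curves per group
#'
#' @param data Data frame with time, event and group columns.
#' @param time,event,group Column names (strings).
#' @return A ggplot.
#' @export
plot_km_groups <- function(data, time = "os_time", event = "os_event",
                           group = "group") {
  d <- purrr::imap_dfr(split(data, data[[group]]), function(dd, g) {
    km <- km_estimate(dd[[time]], dd[[event]])
    dplyr::bind_rows(tibble::tibble(time = 0, surv = 1, n_censor = 0),
                     tibble::as_tibble(km)[c("time", "surv", "n_censor")]) |>
      dplyr::mutate(group = g)
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$surv,
                                  colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot age-at-diagnosis histograms with KDE overlay
#'
#' @param object An `age_density` from [age_density()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.age_density <- function(object, ...) {
  ggplot2::ggplot() +
    ggplot2::geom_col(
      data = object$histogram,
      ggplot2::aes(x = .data$mid, y = .data$density, fill = .data$group),
      position = "identity", alpha = 0.4, width = object$binwidth
    ) +
    ggplot2::geom_line(
      data = object$density,
      ggplot2::aes(x = .data$age, y = .data$density, colour = .data$group)
    ) +
    ggplot2::labs(x = "Age at diagnosis (years)", y = "Density",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cell-type composition ratios across timepoints
#'
#' @param ratios Output of [composition_ratios()] with a `timepoint` column.
#' @return A ggplot.
#' @export
plot_composition <- function(ratios) {
  if (!"timepoint" %in% names(ratios)) {
    stop("`ratios` needs a `timepoint` column.", call. = FALSE)
  }
  d <- ratios |>
    tidyr::pivot_longer(dplyr::all_of(c("HS_LE", "AV_LE", "HS_AV_LE",
                                        "ME_LE")),
                        names_to = "ratio", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$timepoint), y = .data$value,
                                  group = .data$ratio)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~ratio, scales = "free_y") +
    ggplot2::labs(x = "Age (months)", y = "Ratio over luminal cells") +
    ggplot2::theme_minimal()
}

#' Plot mean log2 profiles of called cyclic genes
#'
#' @param calls A `cyclic_calls` tibble.
#' @param data The `timecourse_sim` or long expression tibble the calls came
#'   from.
#' @param max_genes Cap on plotted genes.
#' @return A ggplot.
#' @export
plot_cyclic_profiles <- function(calls, data, max_genes = 50) {
  if (inherits(data, "timecourse_sim")) data <- data$expression
  keep <- head(calls$gene, max_genes)
  d <- data |>
    dplyr::filter(.data$gene %in% keep) |>
    dplyr::group_by(.data$gene, .data$timepoint) |>
    dplyr::summarise(mean_expr = mean(.data$log2_expr), .groups = "drop") |>
    dplyr::left_join(calls[c("gene", "orientation")], by = "gene")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$timepoint, y = .data$mean_expr,
                                  group = .data$gene)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~orientation) +
    ggplot2::labs(x = "Age (months)", y = "Mean log2 expression") +
    ggplot2::theme_minimal()
}
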