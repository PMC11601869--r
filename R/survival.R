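#' Kaplan-Meier product-limit survival curve
#'
#' Product-limit estimate of the survival function, with censored subjects
#' leaving the risk set after their time and ties handled events-before-
#' censorings at equal times (the [survival::survfit()] conventions, which
#' this wraps).
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicators (1/TRUE = death observed, 0/FALSE =
#'   censored).
#' @return Tibble of class `km_curve` with `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` at each observed time.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))$surv # 2/3, 1/3, 0
#' @export
km_estimate <- function(time, event) {
  if (length(time) != length(event)) {
    stop("`time` and `event` must have equal length.", call. = FALSE)
  }
  if (any(time < 0)) stop("`time` must be >= 0.", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1,
                           conf.type = "none")
  out <- tibble::tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    surv = fit$surv
  )
  class(out) <- c("km_curve", class(out))
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank test: observed minus expected events summed over event
#' times with the hypergeometric variance, compared to chi-square with 1
#' degree of freedom (wraps [survival::survdiff()]).
#'
#' @param data Data frame with the three columns below.
#' @param time,event,group Column names (strings) for follow-up time, event
#'   indicator and the two-level group.
#' @return Object of class `logrank_test`: list with `chi_square`, `p_value`,
#'   `df`, and the per-group observed/expected table. Has `tidy()`/`glance()`
#'   methods.
#' @examples
#' d <- data.frame(t = c(1, 2, 3, 4, 5, 6), e = 1,
#'                 g = rep(c("a", "b"), each = 3))
#' logrank_test(d, "t", "e", "g")
#' @export
logrank_test <- function(data, time = "os_time", event = "os_event",
                         group = "group") {
  stopifnot(all(c(time, event, group) %in% names(data)))
  g <- data[[group]]
  if (length(unique(g)) != 2) {
    stop("`group` must have exactly 2 levels.", call. = FALSE)
  }
  if (sum(data[[event]]) < 1) {
    stop("log-rank statistic undefined without any event.", call. = FALSE)
  }
  fml <- stats::as.formula(
    sprintf("survival::Surv(%s, %s) ~ %s", time, event, group))
  fit <- survival::survdiff(fml, data = data)
  chi <- unname(fit$chisq)
  structure(
    list(chi_square = chi, df = 1,
         p_value = pchisq(chi, df = 1, lower.tail = FALSE),
         observed = fit$obs, expected = fit$exp,
         groups = sort(unique(as.character(g)))),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f (1 df), p = %.4g\n",
              x$chi_square, x$p_value))
  invisible(x)
}

#' @export
tidy.logrank_test <- function(x, ...) {
  tibble::tibble(statistic = x$chi_square, df = x$df, p.value = x$p_value,
                 method = "two-group log-rank")
}

#' @export
glance.logrank_test <- function(x, ...) tidy(x)

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Point-probability rule: the two-sided p-value sums the probabilities of
#' all tables (with the observed margins) no more probable than the observed
#' one — the [stats::fisher.test()] convention, which this wraps. A zero
#' margin gives `p = 1` with a warning.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Object of class `fisher_exact`: list with `p_value`, `odds_ratio`,
#'   and the table.
#' @examples
#' fisher_exact(matrix(c(3, 1, 1, 3), 2))$p_value # 34/70
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) ||
      any(table != round(table))) {
    stop("`table` must be a 2x2 matrix of non-negative integers.",
         call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("zero margin: p = 1 by convention.", call. = FALSE)
    return(structure(list(p_value = 1, odds_ratio = NA_real_, table = table),
                     class = "fisher_exact"))
  }
  ft <- stats::fisher.test(table)
  structure(
    list(p_value = ft$p.value, odds_ratio = unname(ft$estimate),
         table = table),
    class = "fisher_exact"
  )
}

#' @export
print.fisher_exact <- function(x, ...) {
  cat(sprintf("Fisher exact (two-sided): p = %.4g, OR = %.3f\n",
              x$p_value, x$odds_ratio))
  invisible(x)
}

#' @export
tidy.fisher_exact <- function(x, ...) {
  tibble::tibble(p.value = x$p_value, odds.ratio = x$odds_ratio,
                 method = "Fisher exact, two-sided (point-probability rule)")
}

#' Histogram and kernel-density table of age at diagnosis per group
#'
#' Shared histogram bin edges across groups plus a Gaussian KDE (Silverman's
#' rule-of-thumb bandwidth) evaluated on a common grid — a plot-ready table
#' for the bimodal-vs-unimodal age-distribution comparison.
#'
#' @param data Data frame with an age column and a group column.
#' @param age,group Column names (strings).
#' @param binwidth Histogram bin width in years.
#' @return Object of class `age_density`: list with `histogram` (tibble:
#'   `group`, `mid`, `count`, `density`), `density` (tibble: `group`, `age`,
#'   `density`), and `bandwidths`.
#' @export
age_density <- function(data, age = "age_years", group = "group",
                        binwidth = 2.5) {
  stopifnot(all(c(age, group) %in% names(data)))
  x <- data[[age]]
  g <- as.character(data[[group]])
  cnt <- table(g)
  if (any(cnt < 2)) stop("each group needs >= 2 ages.", call. = FALSE)
  edges <- seq(floor(min(x) / binwidth) * binwidth,
               ceiling(max(x) / binwidth) * binwidth, by = binwidth)
  if (length(edges) < 2) edges <- c(edges, edges + binwidth)

  hist_tbl <- purrr::map_dfr(sort(unique(g)), function(gr) {
    h <- graphics::hist(x[g == gr], breaks = edges, plot = FALSE)
    tibble::tibble(group = gr, mid = h$mids, count = h$counts,
                   density = h$density)
  })
  bw <- vapply(sort(unique(g)), function(gr) {
    b <- stats::bw.nrd0(x[g == gr])
    if (!is.finite(b) || b <= 0) b <- binwidth / 4 # degenerate (constant ages)
    b
  }, numeric(1))
  grid <- seq(min(x) - 3 * max(bw), max(x) + 3 * max(bw), length.out = 512)
  dens_tbl <- purrr::map_dfr(sort(unique(g)), function(gr) {
    d <- density(x[g == gr], bw = bw[[gr]], from = min(grid), to = max(grid),
                 n = length(grid))
    tibble::tibble(group = gr, age = d$x, density = d$y)
  })
  structure(
    list(histogram = hist_tbl, density = dens_tbl, bandwidths = bw,
         binwidth = binwidth),
    class = "age_density"
  )
}
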