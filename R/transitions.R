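#' Per-transition differential statistics for a four-timepoint time course
#'
#' For every gene and every adjacent pair of timepoints, computes the log2
#' fold change (difference of replicate means on the log2 scale), a two-sided
#' unpaired t-test p-value (Welch by default), and a Benjamini-Hochberg
#' q-value adjusted across genes within each transition.
#'
#' Conventions for degenerate inputs: when both groups have zero variance and
#' equal means, `p = 1`; zero variance with unequal means gives `p = 0`
#' (the noise-free planted case).
#'
#' @param data A `timecourse_sim` or a data frame with columns `gene`,
#'   `timepoint`, `log2_expr` (replicate structure implied by multiple rows
#'   per gene x timepoint).
#' @param var_equal Use the pooled-variance Student t instead of Welch.
#' @return A tibble of class `transition_stats` with columns `gene`,
#'   `transition` (1-based index), `from`, `to` (age labels), `log2fc`,
#'   `statistic`, `df`, `p`, `q`.
#' @examples
#' sim <- simulate_timecourse(n_genes = 20, n_cyclic_udu = 5,
#'                            n_cyclic_dud = 0, seed = 1)
#' transition_stats(sim)
#' @export
transition_stats <- function(data, var_equal = FALSE) {
  if (inherits(data, "timecourse_sim")) data <- data$expression
  need <- c("gene", "timepoint", "log2_expr")
  if (!all(need %in% names(data))) {
    stop("`data` needs columns gene, timepoint, log2_expr.", call. = FALSE)
  }
  if (!all(is.finite(data$log2_expr))) {
    stop("`log2_expr` must be finite.", call. = FALSE)
  }
  tps <- sort(unique(data$timepoint))
  genes <- unique(data$gene)

  # gene x replicate matrices per timepoint
  mats <- lapply(tps, function(tp) {
    d <- data[data$timepoint == tp, ]
    n_rep <- nrow(d) / length(genes)
    if (n_rep < 2) {
      stop(sprintf("timepoint %s has < 2 replicates.", format(tp)),
           call. = FALSE)
    }
    matrix(d$log2_expr[order(match(d$gene, genes))],
           nrow = length(genes), byrow = TRUE)
  })

  res <- purrr::map_dfr(seq_len(length(tps) - 1), function(i) {
    a <- mats[[i]]; b <- mats[[i + 1]]
    welch_rows(a, b, genes, var_equal) |>
      dplyr::mutate(transition = i, from = tps[i], to = tps[i + 1],
                    .after = "gene")
  }) |>
    dplyr::group_by(.data$transition) |>
    dplyr::mutate(q = bh_adjust(.data$p)) |>
    dplyr::ungroup()

  class(res) <- c("transition_stats", class(res))
  attr(res, "timepoints") <- tps
  res
}

# Vectorised two-sample t-test over matrix rows (a, b: genes x replicates).
welch_rows <- function(a, b, genes, var_equal = FALSE) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  lfc <- m2 - m1
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  stat <- lfc / se
  p <- 2 * pt(-abs(stat), df)
  # zero variance in both groups: p = 1 when the means agree, else 0
  degen <- se == 0
  p[degen] <- ifelse(lfc[degen] == 0, 1, 0)
  stat[degen & lfc == 0] <- 0
  tibble::tibble(gene = genes, log2fc = lfc, statistic = stat, df = df, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity, capped
#' at 1, input order preserved (a thin validated wrapper around
#' [stats::p.adjust()]).
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals) || anyNA(pvals) ||
      any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must be numeric, non-missing and in [0, 1].", call. = FALSE)
  }
  p.adjust(pvals, method = "BH")
}

#' Call cyclic genes from per-transition statistics
#'
#' A gene is called cyclic when its three transition log2 fold changes
#' alternate in sign in one of the requested orientations (`UDU`:
#' up-down-up, i.e. high at the 2nd and 4th ages; `DUD`: the mirror image),
#' every `|log2fc|` reaches the amplitude threshold `tau`, and every
#' transition q-value is at or below `q_max`. Both orientations are called by
#' default and recorded per gene.
#'
#' @param stats A `transition_stats` tibble with exactly 3 transitions.
#' @param tau Minimum per-transition `|log2fc|` (log2 units, >= 0).
#' @param q_max Per-transition significance threshold on the BH q-value, in
#'   (0, 1].
#' @param orientations Subset of `c("UDU", "DUD")`.
#' @return A tibble of class `cyclic_calls` with columns `gene`,
#'   `orientation`, `lfc1`, `lfc2`, `lfc3`, `q1`, `q2`, `q3`; thresholds kept
#'   as attributes `tau` and `q_max`.
#' @examples
#' sim <- simulate_timecourse(n_genes = 100, n_cyclic_udu = 10, noise_sd = 0,
#'                            seed = 1)
#' call_cyclic_genes(transition_stats(sim), tau = 1)
#' @export
call_cyclic_genes <- function(stats, tau = 1, q_max = 0.05,
                              orientations = c("UDU", "DUD")) {
  if (tau < 0) stop("`tau` must be >= 0.", call. = FALSE)
  if (q_max <= 0 || q_max > 1) stop("`q_max` must be in (0, 1].", call. = FALSE)
  orientations <- match.arg(orientations, c("UDU", "DUD"), several.ok = TRUE)
  if (length(unique(stats$transition)) != 3) {
    stop("cyclic calling needs exactly 3 transitions (4 timepoints).",
         call. = FALSE)
  }

  wide <- stats |>
    dplyr::select(dplyr::all_of(c("gene", "transition", "log2fc", "q"))) |>
    tidyr::pivot_wider(names_from = "transition",
                       values_from = c("log2fc", "q"), names_sep = "") |>
    dplyr::rename(lfc1 = "log2fc1", lfc2 = "log2fc2", lfc3 = "log2fc3")

  sgn <- sign(cbind(wide$lfc1, wide$lfc2, wide$lfc3))
  orient <- dplyr::case_when(
    sgn[, 1] > 0 & sgn[, 2] < 0 & sgn[, 3] > 0 ~ "UDU",
    sgn[, 1] < 0 & sgn[, 2] > 0 & sgn[, 3] < 0 ~ "DUD",
    TRUE ~ NA_character_
  )
  amp_ok <- abs(wide$lfc1) >= tau & abs(wide$lfc2) >= tau &
    abs(wide$lfc3) >= tau
  q_ok <- wide$q1 <= q_max & wide$q2 <= q_max & wide$q3 <= q_max
  calls <- wide |>
    dplyr::mutate(orientation = orient) |>
    dplyr::filter(!is.na(orient) & orient %in% orientations & amp_ok & q_ok) |>
    dplyr::select(dplyr::all_of(c("gene", "orientation", "lfc1", "lfc2",
                                  "lfc3", "q1", "q2", "q3")))
  class(calls) <- c("cyclic_calls", class(calls))
  attr(calls, "tau") <- tau
  attr(calls, "q_max") <- q_max
  attr(calls, "orientations") <- orientations
  calls
}
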