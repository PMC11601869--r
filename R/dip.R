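#' Hartigan's dip statistic
#'
#' Computes the Hartigan & Hartigan dip statistic: the smallest sup-norm
#' distance between the empirical CDF of `x` and any unimodal CDF. Large
#' values indicate departure from unimodality (e.g. a bimodal age-at-diagnosis
#' distribution). The statistic is computed exactly (to numerical bisection
#' tolerance ~1e-13) by a greatest-convex-minorant / least-concave-majorant
#' feasibility search over candidate mode locations.
#'
#' For a sample of `n` distinct values the dip always lies in
#' `[1/(2n), 1/4]`; the lower bound is attained by equally spaced points and
#' the upper bound is approached by two well-separated clusters.
#'
#' @param x Numeric vector, `length(x) >= 2`, finite values.
#' @return A single number, the dip statistic.
#' @examples
#' dip_statistic(c(0, 1))          # 0.25, the maximal value
#' dip_statistic(c(0, 1, 2, 3))    # 0.125 = 1/(2n), equally spaced
#' @seealso [dip_test()] for a Monte-Carlo calibrated p-value.
#' @export
dip_statistic <- function(x) {
  if (!is.numeric(x) || length(x) < 2) {
    stop("`x` must be a numeric vector with at least 2 values.", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("`x` must contain only finite values.", call. = FALSE)
  .dip_cpp(as.numeric(x))
}

#' Draw a null sample of dip statistics under the uniform distribution
#'
#' The classical calibration of the dip test compares the observed dip with
#' dips of uniform samples of the same size (the uniform is the asymptotically
#' least-favourable unimodal null). Precomputing a null table lets many tests
#' of the same sample size share one reference distribution.
#'
#' @param n Sample size of each null draw.
#' @param n_boot Number of null replicates.
#' @param seed Optional integer seed (local to this call).
#' @return Numeric vector of `n_boot` dip statistics.
#' @export
dip_null <- function(n, n_boot = 2000, seed = NULL) {
  stopifnot(n >= 2, n_boot >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  .dip_uniform_null_cpp(as.integer(n), as.integer(n_boot))
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Dip test of unimodality with Monte-Carlo p-value
#'
#' Tests the null hypothesis that `x` was drawn from a unimodal distribution.
#' The p-value is calibrated against uniform null samples of the same size:
#' `p = (1 + #(dip_null >= dip_obs)) / (n_boot + 1)`. The uniform null is the
#' classical (slightly conservative for peaked unimodal alternatives)
#' calibration.
#'
#' @param x Numeric sample (`n >= 4` recommended; a warning is issued below).
#' @param n_boot Number of uniform null replicates (warning below 100).
#' @param seed Optional integer seed making the p-value reproducible.
#' @param null_dips Optional precomputed null sample from [dip_null()] with
#'   matching `n`; when supplied, no new null draws are made.
#' @return An object of class `dip_htest`: a list with `statistic` (the dip),
#'   `p_value`, `n`, `n_boot`, and `seed`. Has [generics::tidy()] and
#'   [generics::glance()] methods.
#' @examples
#' set.seed(1)
#' dip_test(c(rnorm(50, 45, 3), rnorm(50, 65, 3)), n_boot = 199, seed = 7)
#' @export
dip_test <- function(x, n_boot = 2000, seed = NULL, null_dips = NULL) {
  if (length(x) < 4) warning("dip test is unreliable for n < 4.", call. = FALSE)
  if (is.null(null_dips) && n_boot < 100) {
    warning("n_boot < 100 gives a coarse Monte-Carlo p-value.", call. = FALSE)
  }
  stat <- dip_statistic(x)
  if (is.null(null_dips)) {
    null_dips <- dip_null(length(x), n_boot = n_boot, seed = seed)
  }
  nb <- length(null_dips)
  p <- (1 + sum(null_dips >= stat)) / (nb + 1)
  structure(
    list(statistic = stat, p_value = p, n = length(x), n_boot = nb, seed = seed),
    class = "dip_htest"
  )
}

#' @export
print.dip_htest <- function(x, ...) {
  cat("Hartigan dip test of unimodality\n")
  cat(sprintf("  dip = %.5f,  n = %d,  Monte-Carlo p = %.4g (%d uniform null draws)\n",
              x$statistic, x$n, x$p_value, x$n_boot))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.dip_htest <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 n = x$n, n_boot = x$n_boot,
                 method = "Hartigan dip (Monte-Carlo uniform null)")
}

#' @importFrom generics glance
#' @export
glance.dip_htest <- function(x, ...) tidy(x)
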