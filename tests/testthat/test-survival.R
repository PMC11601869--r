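# Kaplan-Meier, log-rank, Fisher exact, age-density tables.

test_that("product-limit estimates match hand computations", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))

  # censored case: event at 1 (S = 2/3), censored at 2, event at 3 with risk
  # set {3} alone (S = 0)
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)

  km3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km3$surv == 1))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), ">= 0")
})

test_that("KM with no censoring equals 1 - empirical CDF at event times", {
  set.seed(41)
  t <- rexp(50)
  km <- km_estimate(t, rep(1, 50))
  expect_equal(km$surv, 1 - ecdf(t)(km$time), tolerance = 1e-12)
})

test_that("log-rank: identical groups give chi-square 0; hand oracle matches", {
  d <- data.frame(os_time = rep(c(1, 2, 3), 2), os_event = 1,
                  group = rep(c("a", "b"), each = 3))
  lr <- logrank_test(d)
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)

  # group A all events at t=1, group B all at t=2 (n = 3 each):
  # t=1: O_A=3, E_A=1.5, V=3*(1/2)*(1/2)*(3/5)=0.45; t=2 contributes nothing
  # -> chi-square = 1.5^2 / 0.45 = 5
  d2 <- data.frame(os_time = rep(c(1, 2), each = 3), os_event = 1,
                   group = rep(c("a", "b"), each = 3))
  lr2 <- logrank_test(d2)
  expect_equal(lr2$chi_square, 5, tolerance = 1e-10)

  # label symmetry
  d3 <- dplyr::mutate(d2, group = ifelse(group == "a", "b", "a"))
  expect_equal(logrank_test(d3)$chi_square, lr2$chi_square, tolerance = 1e-12)
  expect_gte(lr2$chi_square, 0)

  expect_error(logrank_test(dplyr::mutate(d2, os_event = 0)), "event")
})

test_that("log-rank type-I error is close to the nominal 5% level", {
  set.seed(42)
  rej <- vapply(1:400, function(i) {
    t_ev <- rexp(120, 0.1)
    t_c <- rexp(120, 0.03)
    d <- data.frame(os_time = pmin(t_ev, t_c),
                    os_event = as.integer(t_ev <= t_c),
                    group = rep(c("a", "b"), each = 60))
    logrank_test(d)$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("Fisher exact matches enumerations and is transpose-symmetric", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2))$p_value, 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(10, 0, 0, 10), 2))$p_value,
               2 / choose(20, 10), tolerance = 1e-12)
  set.seed(43)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 5), 2)
    expect_equal(fisher_exact(tab)$p_value, fisher_exact(t(tab))$p_value,
                 tolerance = 1e-12)
  }
  expect_warning(p0 <- fisher_exact(matrix(c(0, 0, 3, 4), 2))$p_value, "margin")
  expect_equal(p0, 1)
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("age-density tables share bins, integrate to 1, and resolve bimodality", {
  set.seed(44)
  d <- data.frame(
    age_years = c(rnorm(150, 45, 3), rnorm(150, 65, 3), rnorm(200, 65, 8)),
    group = rep(c("high", "low"), c(300, 200))
  )
  ad <- age_density(d)
  # KDE integrates to 1 (trapezoid)
  for (g in c("high", "low")) {
    dd <- ad$density[ad$density$group == g, ]
    integral <- sum(diff(dd$age) * (head(dd$density, -1) + dd$density[-1]) / 2)
    expect_equal(integral, 1, tolerance = 1e-3)
  }
  # shared bin mids across groups
  expect_equal(unique(ad$histogram$mid[ad$histogram$group == "high"]),
               unique(ad$histogram$mid[ad$histogram$group == "low"]))
  # the bimodal group's KDE has two local maxima at this separation/bandwidth
  y <- ad$density$density[ad$density$group == "high"]
  peaks <- sum(diff(sign(diff(y))) == -2)
  expect_equal(peaks, 2)

  # equal ages still produce a one-bin histogram
  d1 <- data.frame(age_years = rep(50, 5), group = "g")
  ad1 <- age_density(d1)
  expect_equal(sum(ad1$histogram$count > 0), 1)
  expect_error(age_density(data.frame(age_years = 1, group = "g")), ">= 2")
})
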