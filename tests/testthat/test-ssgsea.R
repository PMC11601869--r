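# ssGSEA scoring, tertile stratification, ORA.

test_that("the 4-gene worked example scores exactly 2 at alpha = 0", {
  expr <- c(g1 = 4, g2 = 3, g3 = 2, g4 = 1)
  expect_equal(ssgsea_score(expr, "g1", alpha = 0), 2)
})

test_that("identical rankings give identical scores; monotone transforms are neutral", {
  set.seed(11)
  expr <- setNames(rnorm(30), sprintf("g%02d", 1:30))
  gs <- sprintf("g%02d", c(2, 5, 9, 20))
  s0 <- ssgsea_score(expr, gs)
  expect_equal(ssgsea_score(expr * 3 + 100, gs), s0)
  expect_equal(ssgsea_score(exp(expr), gs), s0)
  expect_equal(ssgsea_score(rank(expr), gs), s0)
})

test_that("the score equals a brute-force recomputation on random instances", {
  set.seed(12)
  for (i in 1:300) {
    n <- sample(3:12, 1)
    expr <- setNames(round(rnorm(n), 2), sprintf("g%02d", sample(n)))
    k <- sample(n - 1, 1)
    gs <- sample(names(expr), k)
    alpha <- sample(c(0, 0.25, 1), 1)
    expect_equal(ssgsea_score(expr, gs, alpha),
                 ssgsea_brute(expr, gs, alpha), tolerance = 1e-12)
  }
})

test_that("adding the strictly last-ranked gene to the set never raises an alpha=0 score", {
  set.seed(13)
  for (i in 1:40) {
    n <- sample(5:12, 1)
    expr <- setNames(sort(rnorm(n), decreasing = TRUE),
                     sprintf("g%02d", 1:n))
    gs <- sample(names(expr)[-n], sample(n - 2, 1))
    s1 <- ssgsea_score(expr, gs, alpha = 0)
    s2 <- ssgsea_score(expr, c(gs, names(expr)[n]), alpha = 0)
    expect_lte(s2, s1 + 1e-12)
  }
})

test_that("degenerate sets are rejected", {
  expr <- c(a = 1, b = 2)
  expect_error(ssgsea_score(expr, c("a", "b")), "degenerate")
  expect_error(ssgsea_score(expr, "zz"), "degenerate")
})

test_that("tertile stratification sizes, ordering and tie handling", {
  s <- tertile_stratify(tibble::tibble(sample_id = letters[1:9], score = 1:9))
  expect_equal(sort(s$sample_id[s$group == "high"]), c("g", "h", "i"))
  expect_equal(sum(s$group == "high"), 3)

  for (n in c(3, 4, 7, 10, 100)) {
    s <- tertile_stratify(tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                                         score = rnorm(n)))
    expect_equal(sum(s$group == "high"), ceiling(n / 3))
    expect_equal(nrow(s), n)
  }

  expect_warning(
    s <- tertile_stratify(tibble::tibble(sample_id = sprintf("s%d", 1:6),
                                         score = rep(1, 6))),
    "ties"
  )
  expect_equal(s$sample_id[s$group == "high"], c("s1", "s2"))
  expect_error(tertile_stratify(tibble::tibble(sample_id = "a", score = 1)),
               ">= 3")
})

test_that("scored cohort recovers the planted signature-high group", {
  sim <- simulate_cohort(n_samples = 120, seed = 21)
  sc <- tertile_stratify(score_samples(sim$expression, sim$signature_genes))
  agree <- mean((sc$group == "high") ==
                  (sim$cohort$group_true[match(sc$sample_id,
                                               sim$cohort$sample_id)] == "high"))
  expect_gte(agree, 0.95)
})

test_that("hypergeometric ORA matches enumerations", {
  # universe 20, one set of 4, query of 4, full overlap: p = 1/C(20,4)
  u <- sprintf("g%02d", 1:20)
  r <- ora_enrichment(u[1:4], list(s = u[1:4]), u)
  expect_equal(r$p, 1 / choose(20, 4), tolerance = 1e-12)
  # zero overlap: p = P(X >= 0) = 1
  r0 <- ora_enrichment(u[5:8], list(s = u[1:4]), u)
  expect_equal(r0$p, 1)
  # degenerate: query = universe forces the overlap
  expect_warning(rd <- ora_enrichment(u, list(s = u[1:3]), u), "universe")
  expect_equal(rd$p, 1)
  expect_error(ora_enrichment("x", list(s = "x"), character(0)), "universe")
  expect_error(ora_enrichment("zz", list(s = u[1:2]), u), "subset")
})
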