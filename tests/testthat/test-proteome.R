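# Cyclic-protein presence calling and differential abundance.

proteome_row <- function(protein, genotype, timepoint, intensity, n_rep = 3) {
  tidyr::expand_grid(protein = protein, genotype = genotype,
                     timepoint = timepoint, replicate = seq_len(n_rep)) |>
    dplyr::mutate(intensity = intensity)
}

build_pt <- function(pattern) {
  # pattern: tibble(protein, genotype, timepoint) rows where detected
  base <- tidyr::expand_grid(protein = unique(pattern$protein),
                             genotype = c("A", "B"),
                             timepoint = c(3, 11, 14, 19),
                             replicate = 1:3)
  base |>
    dplyr::left_join(dplyr::mutate(pattern, on = TRUE),
                     by = c("protein", "genotype", "timepoint")) |>
    dplyr::mutate(intensity = ifelse(!is.na(on), 20, NA_real_)) |>
    dplyr::select(-on)
}

test_that("the presence pattern rule matches the construction", {
  pattern <- dplyr::bind_rows(
    tidyr::expand_grid(protein = "hit", genotype = "B", timepoint = c(11, 19)),
    tidyr::expand_grid(protein = "everywhere", genotype = c("A", "B"),
                       timepoint = c(3, 11, 14, 19)),
    tidyr::expand_grid(protein = "both_genos", genotype = c("A", "B"),
                       timepoint = c(11, 19)),
    tidyr::expand_grid(protein = "wrong_phase", genotype = "B",
                       timepoint = c(3, 14))
  )
  calls <- call_cyclic_proteins(build_pt(pattern), cyclic_genotype = "B",
                                detection_floor = 15)
  expect_equal(calls$protein, "hit")
})

test_that("calls are invariant to replicate order and to rescaling above the floor", {
  sim <- simulate_proteome(n_background = 25, n_cyclic = 6, missingness = 0.15,
                           seed = 8)
  c0 <- call_cyclic_proteins(sim)
  shuf <- sim$intensities[sample(nrow(sim$intensities)), ]
  c1 <- call_cyclic_proteins(shuf, cyclic_genotype = sim$config$cyclic_genotype,
                             detection_floor = sim$config$detection_floor,
                             min_detect = 3)
  expect_setequal(c0$protein, c1$protein)
  # rescale intensities above the floor (order-preserving, floor-respecting)
  resc <- dplyr::mutate(sim$intensities,
                        intensity = ifelse(intensity >= 15,
                                           15 + (intensity - 15) * 7,
                                           intensity))
  c2 <- call_cyclic_proteins(resc, cyclic_genotype = sim$config$cyclic_genotype,
                             detection_floor = 15, min_detect = 3)
  expect_setequal(c0$protein, c2$protein)
})

test_that("noise-free generation recovers exactly the planted cyclic set", {
  sim <- simulate_proteome(n_background = 40, n_cyclic = 16, missingness = 0,
                           seed = 9)
  calls <- call_cyclic_proteins(sim)
  expect_setequal(calls$protein,
                  sim$truth$protein[sim$truth$class == "cyclic"])
})

test_that("differential testing: identical groups give p = 1 and no hits", {
  d <- tidyr::expand_grid(protein = sprintf("p%d", 1:5), group = c("a", "b"),
                          replicate = 1:4) |>
    dplyr::mutate(intensity = rep(c(1, 2, 3, 4), 10))
  res <- differential_proteins(d)
  expect_true(all(res$p == 1))
  expect_false(any(res$significant))
})

test_that("differential testing controls false positives and finds a 4-fold shift", {
  set.seed(10)
  fp <- replicate(12, {
    d <- tidyr::expand_grid(protein = sprintf("p%03d", 1:100),
                            group = c("a", "b"), replicate = 1:5) |>
      dplyr::mutate(intensity = rnorm(dplyr::n(), 20, 1))
    sum(differential_proteins(d)$significant)
  })
  # BH controls FDR at 5% under the global null: false-positive sets are rare
  expect_lte(mean(fp) / 100, 0.05 + 0.03)

  hits <- replicate(25, {
    d <- tidyr::expand_grid(protein = sprintf("p%02d", 1:50),
                            group = c("a", "b"), replicate = 1:5) |>
      dplyr::mutate(intensity = rnorm(dplyr::n(), 20, 0.25) +
                      ifelse(protein == "p01" & group == "b", 2, 0))
    differential_proteins(d)$significant[1]
  })
  expect_gte(mean(hits), 0.95)
})

test_that("proteins with too few observations are reported untested", {
  d <- tibble::tibble(protein = c(rep("ok", 8), rep("sparse", 8)),
                      group = rep(c("a", "b"), each = 4, times = 2),
                      intensity = c(rnorm(8, 20),
                                    c(20, NA, NA, NA, 21, 22, 23, 24)))
  res <- differential_proteins(d)
  expect_true(res$tested[res$protein == "ok"])
  expect_false(res$tested[res$protein == "sparse"])
  expect_true(is.na(res$p[res$protein == "sparse"]))
})
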