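# Marker-panel annotation, half-max gating, composition ratios.

panel <- marker_panels()

mk_counts <- function(rows) {
  genes <- unique(c(panel$HS, panel$AV, panel$ME))
  m <- matrix(0, length(rows), length(genes),
              dimnames = list(sprintf("c%d", seq_along(rows)), genes))
  for (i in seq_along(rows)) {
    for (g in names(rows[[i]])) m[i, g] <- rows[[i]][[g]]
  }
  m
}

test_that("pure-panel cells are labelled by their panel; empty cells are unassigned", {
  counts <- mk_counts(list(
    c(Prlr = 50, Pgr = 40, Esr1 = 30),            # HS
    c(Mfge8 = 60, Trf = 40),                      # AV
    c(Krt17 = 50, Krt14 = 50),                    # ME
    c()                                            # all-zero
  ))
  ann <- suppressWarnings(annotate_cells(counts, panel))
  expect_equal(ann$label, c("HS", "AV", "ME", "unassigned"))
})

test_that("cells with comparable HS and AV scores above threshold are HS-AV", {
  counts <- mk_counts(list(
    c(Prlr = 40, Pgr = 40, Mfge8 = 40, Trf = 40), # balanced co-expression
    c(Prlr = 80, Pgr = 80),                       # pure HS
    c(Mfge8 = 80, Trf = 80)                       # pure AV
  ))
  ann <- suppressWarnings(annotate_cells(counts, panel))
  expect_equal(ann$label, c("HS-AV", "HS", "AV"))
})

test_that("half-max gate follows the rule on scores [10, 5, ~4.95] and degenerate cases", {
  m <- matrix(c(1023, 31, 30), ncol = 1, dimnames = list(NULL, "Cenpe"))
  expect_equal(feature_sum_gate(m, "Cenpe"), c(TRUE, TRUE, FALSE))
  # a single cell is always at its own max
  m1 <- matrix(5, 1, 1, dimnames = list(NULL, "Cenpe"))
  expect_true(feature_sum_gate(m1, "Cenpe"))
  mz <- matrix(0, 3, 1, dimnames = list(NULL, "Cenpe"))
  expect_warning(g <- feature_sum_gate(mz, "Cenpe"), "zero")
  expect_false(any(g))
})

test_that("absent panel genes are skipped with a warning (e.g. Bud1)", {
  sim <- simulate_cells(cells_per_sample = 30, seed = 3)
  counts <- sim$counts[, setdiff(colnames(sim$counts), "Bud1")]
  expect_warning(feature_score(counts, panel$proliferating), "Bud1")
  expect_error(feature_score(counts[, 1:3], c("NotAGene")), "present")
})

test_that("composition ratios match hand arithmetic and luminal ratios sum to 1", {
  ann <- tibble::tibble(label = rep(c("HS", "AV", "HS-AV", "ME"),
                                    c(10, 5, 5, 4)))
  r <- composition_ratios(ann)
  expect_equal(r$HS_LE, 0.5)
  expect_equal(r$AV_LE, 0.25)
  expect_equal(r$HS_AV_LE, 0.25)
  expect_equal(r$ME_LE, 0.2)
  expect_error(composition_ratios(tibble::tibble(label = rep("ME", 5))),
               "luminal")
})

test_that("background-free simulation is recovered perfectly; ratios equal planted values", {
  sim <- simulate_cells(cells_per_sample = 400, background_rate = 0, seed = 4)
  ann <- annotate_cells(sim$counts, sim$panel)
  truth <- gsub("HS_AV", "HS-AV", sim$cells$true_label)
  expect_equal(mean(ann$label == truth), 1)
  r <- composition_ratios(ann, sim$cells)
  expect_equal(r$HS_LE + r$AV_LE + r$HS_AV_LE, rep(1, nrow(r)))
  # ratios equal the realised planted composition exactly
  realised <- sim$cells |>
    dplyr::count(timepoint, true_label) |>
    tidyr::pivot_wider(names_from = "true_label", values_from = "n")
  le <- realised$HS + realised$AV + realised$HS_AV
  expect_equal(r$HS_LE[match(realised$timepoint, r$timepoint)],
               realised$HS / le)
})

test_that("annotation is invariant under cell reordering; ppbc implies both gates", {
  sim <- simulate_cells(cells_per_sample = 150, seed = 5)
  ann <- annotate_cells(sim$counts, sim$panel)
  perm <- sample(nrow(sim$counts))
  ann_p <- annotate_cells(sim$counts[perm, ], sim$panel)
  expect_equal(ann_p$label, ann$label[perm])
  expect_true(all(!ann$ppbc_like | (ann$proliferating & ann$regulon)))
  expect_lte(sum(ann$ppbc_like),
             min(sum(ann$proliferating), sum(ann$regulon)))
})
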