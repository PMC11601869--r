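#' Simulate a replicated four-timepoint expression time course
#'
#' Generates log2-scale expression for a two-phase ("zigzag") aging design:
#' four ages with replicated samples per age, a planted set of cyclic genes
#' whose mean profile alternates between the 3/14-month phase and the
#' 11/19-month phase, optional monotone-drift genes, and flat null genes.
#' Planted cyclic genes come in two orientations:
#' `udu` (transitions +amplitude, -amplitude, +amplitude: high at the 2nd and
#' 4th ages) and `dud` (the mirror image). Monotone genes drift by
#' `amplitude` per transition in a per-gene random direction. Every gene gets
#' a gene-specific baseline (so that timepoint profiles are correlated, as in
#' real transcriptomes) and i.i.d. Gaussian replicate noise.
#'
#' @param n_genes Total number of genes.
#' @param timepoints Ordered ages in months (exactly 4 for cyclic designs).
#' @param n_replicates Replicates per timepoint (>= 2; the source design is 5
#'   animals per timepoint per genotype).
#' @param n_cyclic_udu,n_cyclic_dud,n_monotonic Planted gene counts.
#' @param amplitude Log2 fold change per transition for planted genes (>= 0).
#' @param noise_sd Replicate-level Gaussian SD on the log2 scale (>= 0).
#' @param baseline_mean,baseline_sd Per-gene baseline log2 expression
#'   distribution.
#' @param genotype Free-text genotype label used in sample ids.
#' @param seed Integer seed; identical seeds give identical output.
#' @return An object of class `timecourse_sim`: a list with
#'   * `expression`: tibble with columns `gene`, `timepoint`, `replicate`,
#'     `sample_id`, `log2_expr`;
#'   * `truth`: tibble with `gene`, `class` (`udu`/`dud`/`monotonic`/`null`);
#'   * `config`: the arguments.
#' @examples
#' sim <- simulate_timecourse(n_genes = 50, n_cyclic_udu = 5,
#'                            n_cyclic_dud = 5, seed = 1)
#' dplyr::count(sim$truth, class)
#' @export
simulate_timecourse <- function(n_genes = 2000,
                                timepoints = c(3, 11, 14, 19),
                                n_replicates = 5,
                                n_cyclic_udu = 50,
                                n_cyclic_dud = 50,
                                n_monotonic = 0,
                                amplitude = 2,
                                noise_sd = 0.5,
                                baseline_mean = 6,
                                baseline_sd = 2,
                                genotype = "BL6_NZB",
                                seed = NULL) {
  if (length(timepoints) != 4) {
    stop_config("timepoints", "cyclic designs need exactly 4 timepoints")
  }
  if (is.unsorted(timepoints, strictly = TRUE)) {
    stop_config("timepoints", "ages must be strictly increasing")
  }
  if (n_replicates < 2) stop_config("n_replicates", "must be >= 2")
  if (amplitude < 0) stop_config("amplitude", "must be >= 0")
  if (noise_sd < 0) stop_config("noise_sd", "must be >= 0")
  n_planted <- n_cyclic_udu + n_cyclic_dud + n_monotonic
  if (n_planted > n_genes) {
    stop_config("n_genes", "planted gene counts exceed n_genes")
  }

  with_seed(seed, {
    classes <- c(rep("udu", n_cyclic_udu), rep("dud", n_cyclic_dud),
                 rep("monotonic", n_monotonic),
                 rep("null", n_genes - n_planted))
    gene <- sprintf("gene_%05d", seq_len(n_genes))
    truth <- tibble::tibble(gene = gene, class = classes)

    baseline <- rnorm(n_genes, baseline_mean, baseline_sd)
    mono_sign <- ifelse(runif(n_genes) < 0.5, 1, -1)
    # mean profile offsets per class, one row per gene, 4 columns
    offsets <- matrix(0, n_genes, 4)
    offsets[classes == "udu", ] <- matrix(rep(c(0, amplitude, 0, amplitude),
                                              each = sum(classes == "udu")),
                                          ncol = 4)
    offsets[classes == "dud", ] <- matrix(rep(c(0, -amplitude, 0, -amplitude),
                                              each = sum(classes == "dud")),
                                          ncol = 4)
    mono <- classes == "monotonic"
    offsets[mono, ] <- outer(mono_sign[mono] * amplitude, 0:3)

    expr <- tidyr::expand_grid(
      gene = gene,
      timepoint = timepoints,
      replicate = seq_len(n_replicates)
    )
    g_idx <- match(expr$gene, gene)
    t_idx <- match(expr$timepoint, timepoints)
    expr$sample_id <- sprintf("%s_%gm_r%d", genotype, expr$timepoint,
                              expr$replicate)
    expr$log2_expr <- baseline[g_idx] + offsets[cbind(g_idx, t_idx)] +
      rnorm(nrow(expr), 0, noise_sd)

    structure(
      list(expression = expr, truth = truth,
           config = list(n_genes = n_genes, timepoints = timepoints,
                         n_replicates = n_replicates,
                         n_cyclic_udu = n_cyclic_udu,
                         n_cyclic_dud = n_cyclic_dud,
                         n_monotonic = n_monotonic, amplitude = amplitude,
                         noise_sd = noise_sd, baseline_mean = baseline_mean,
                         baseline_sd = baseline_sd, genotype = genotype,
                         seed = seed)),
      class = "timecourse_sim"
    )
  })
}

#' Simulate an ECM proteomics table with genotype-specific cyclic proteins
#'
#' Generates log2 intensities for decellularized-tissue proteomics across two
#' genotypes and four ages. Planted "cyclic" proteins are present (above the
#' detection floor) only in the designated genotype and only at the 2nd and
#' 4th ages (the 11/19-month phase); background proteins are present in every
#' sample. Structurally absent measurements are `NA`. On top of that,
#' missing-completely-at-random dropout at rate `missingness` is applied to
#' every present intensity, planted and background alike, mimicking stochastic
#' peptide-level missingness of data-independent acquisition runs.
#'
#' @param n_background Number of always-present background proteins.
#' @param n_cyclic Number of planted cyclic proteins (the motivating dataset
#'   reported 16).
#' @param genotypes Character vector of two genotype labels.
#' @param cyclic_genotype Genotype carrying the cyclic proteins (default the
#'   second genotype).
#' @param timepoints Ordered ages in months; cyclic proteins are present at
#'   `timepoints[c(2, 4)]`.
#' @param n_replicates Replicates per genotype x timepoint.
#' @param missingness MCAR dropout rate in `[0, 1]`.
#' @param detection_floor Log2 intensity below which a value counts as not
#'   detected.
#' @param mean_log2_intensity,intensity_sd Present-intensity distribution
#'   (log2 scale); the mean must sit above the floor.
#' @param seed Integer seed.
#' @return An object of class `proteome_sim`: list with `intensities` (tibble:
#'   `protein`, `genotype`, `timepoint`, `replicate`, `intensity` with `NA`
#'   for missing), `truth` (tibble: `protein`, `class`), `config`.
#' @examples
#' sim <- simulate_proteome(n_background = 20, n_cyclic = 4, seed = 1)
#' dplyr::count(sim$intensities, is.na(intensity))
#' @export
simulate_proteome <- function(n_background = 300,
                              n_cyclic = 16,
                              genotypes = c("BL6_C57", "BL6_NZB"),
                              cyclic_genotype = genotypes[2],
                              timepoints = c(3, 11, 14, 19),
                              n_replicates = 5,
                              missingness = 0,
                              detection_floor = 15,
                              mean_log2_intensity = 20,
                              intensity_sd = 1.5,
                              seed = NULL) {
  if (length(genotypes) != 2) stop_config("genotypes", "exactly two genotypes")
  if (!cyclic_genotype %in% genotypes) {
    stop_config("cyclic_genotype", "must be one of `genotypes`")
  }
  if (length(timepoints) != 4) stop_config("timepoints", "exactly 4 timepoints")
  if (missingness < 0 || missingness > 1) {
    stop_config("missingness", "rate must be in [0, 1]")
  }
  if (n_replicates < 1) stop_config("n_replicates", "must be >= 1")
  if (mean_log2_intensity <= detection_floor) {
    stop_config("mean_log2_intensity", "must exceed detection_floor")
  }

  with_seed(seed, {
    protein <- c(sprintf("cyc_prot_%03d", seq_len(n_cyclic)),
                 sprintf("bg_prot_%03d", seq_len(n_background)))
    truth <- tibble::tibble(
      protein = protein,
      class = c(rep("cyclic", n_cyclic), rep("background", n_background))
    )
    on_tp <- timepoints[c(2, 4)]
    tab <- tidyr::expand_grid(
      protein = protein,
      genotype = genotypes,
      timepoint = timepoints,
      replicate = seq_len(n_replicates)
    ) |>
      dplyr::left_join(truth, by = "protein") |>
      dplyr::mutate(
        present = .data$class == "background" |
          (.data$genotype == cyclic_genotype & .data$timepoint %in% on_tp),
        intensity = ifelse(
          .data$present,
          rnorm(dplyr::n(), mean_log2_intensity, intensity_sd),
          NA_real_
        ),
        intensity = ifelse(
          .data$present & runif(dplyr::n()) < missingness,
          NA_real_, .data$intensity
        )
      ) |>
      dplyr::select(!dplyr::all_of(c("present", "class")))

    structure(
      list(intensities = tab, truth = truth,
           config = list(n_background = n_background, n_cyclic = n_cyclic,
                         genotypes = genotypes,
                         cyclic_genotype = cyclic_genotype,
                         timepoints = timepoints, n_replicates = n_replicates,
                         missingness = missingness,
                         detection_floor = detection_floor,
                         mean_log2_intensity = mean_log2_intensity,
                         intensity_sd = intensity_sd, seed = seed)),
      class = "proteome_sim"
    )
  })
}

#' Default cyclical cell-type composition across the four ages
#'
#' Luminal sub-type proportions alternate between the 3/14-month phase
#' (HS-rich) and the 11/19-month phase (mixed-lineage-rich), reproducing the
#' reported pattern of lower HS/LE, AV/LE and ME/LE ratios at 11 and 19
#' months. Rows sum to 1 over `HS`, `AV`, `HS_AV`, `ME`.
#'
#' @param timepoints Ages in months.
#' @return Tibble with columns `timepoint`, `HS`, `AV`, `HS_AV`, `ME`.
#' @export
default_composition <- function(timepoints = c(3, 11, 14, 19)) {
  phase2 <- seq_along(timepoints) %% 2 == 0 # 11m, 19m
  tibble::tibble(
    timepoint = timepoints,
    HS = ifelse(phase2, 0.24, 0.36),
    AV = ifelse(phase2, 0.24, 0.28),
    HS_AV = ifelse(phase2, 0.32, 0.16),
    ME = 0.20
  )
}

#' Simulate a marker-structured single-cell counts matrix
#'
#' Draws cells of four mammary epithelial types (HS, AV, HS-AV, ME) with a
#' planted per-timepoint composition. A cell expresses each gene of its own
#' marker panel with probability `marker_rate`, with counts
#' `1 + Poisson(marker_strength - 1)`; HS-AV cells express both the HS and the
#' AV panels. All other genes (including the other panels and
#' `n_background_genes` filler genes) are expressed at `background_rate` with
#' count `1 + Poisson(1)`. With `background_rate = 0` the construction is
#' separable and [annotate_cells()] recovers every true label.
#'
#' @param composition Data frame as from [default_composition()]: one row per
#'   timepoint with type fractions summing to 1.
#' @param cells_per_sample Cells drawn per timepoint sample.
#' @param marker_rate Probability a cell expresses each own-panel marker.
#' @param marker_strength Mean count of an expressed marker (>= 1).
#' @param background_rate Probability of background expression per gene.
#' @param n_background_genes Filler genes beyond the panel genes.
#' @param panel Marker panels, as [marker_panels()].
#' @param seed Integer seed.
#' @return An object of class `cells_sim`: list with `counts` (sparse
#'   dgCMatrix, cells x genes), `cells` (tibble: `barcode`, `sample_id`,
#'   `timepoint`, `true_label`), `panel`, `config`.
#' @examples
#' sim <- simulate_cells(cells_per_sample = 100, seed = 1)
#' table(sim$cells$true_label)
#' @export
simulate_cells <- function(composition = default_composition(),
                           cells_per_sample = 2000,
                           marker_rate = 1,
                           marker_strength = 10,
                           background_rate = 0.02,
                           n_background_genes = 50,
                           panel = marker_panels(),
                           seed = NULL) {
  composition <- tibble::as_tibble(composition)
  types <- c("HS", "AV", "HS_AV", "ME")
  if (!all(c("timepoint", types) %in% names(composition))) {
    stop_config("composition", "needs columns timepoint, HS, AV, HS_AV, ME")
  }
  frac <- as.matrix(composition[types])
  if (any(frac < 0) || any(abs(rowSums(frac) - 1) > 1e-8)) {
    stop_config("composition", "type fractions must be >= 0 and sum to 1")
  }
  if (marker_rate < 0 || marker_rate > 1) stop_config("marker_rate", "in [0, 1]")
  if (background_rate < 0 || background_rate > 1) {
    stop_config("background_rate", "in [0, 1]")
  }
  if (marker_strength < 1) stop_config("marker_strength", "must be >= 1")

  genes <- unique(c(panel$HS, panel$AV, panel$ME, panel$proliferating,
                    panel$regulon,
                    sprintf("filler_%03d", seq_len(n_background_genes))))
  panel_of <- list(HS = panel$HS, AV = panel$AV,
                   HS_AV = c(panel$HS, panel$AV), ME = panel$ME)

  with_seed(seed, {
    cells <- purrr::pmap_dfr(composition, function(timepoint, HS, AV, HS_AV, ME, ...) {
      lab <- sample(types, cells_per_sample, replace = TRUE,
                    prob = c(HS, AV, HS_AV, ME))
      tibble::tibble(
        timepoint = timepoint,
        sample_id = sprintf("tp_%gm", timepoint),
        true_label = lab
      )
    }) |>
      dplyr::mutate(barcode = sprintf("cell_%06d", dplyr::row_number())) |>
      dplyr::relocate(dplyr::all_of("barcode"))

    n_cells <- nrow(cells)
    ii <- integer(0); jj <- integer(0); xx <- integer(0)
    gene_index <- setNames(seq_along(genes), genes)
    for (ty in types) {
      rows <- which(cells$true_label == ty)
      mk <- panel_of[[ty]]
      if (!length(rows)) next
      # own-panel marker expression
      on <- matrix(runif(length(rows) * length(mk)) < marker_rate,
                   nrow = length(rows))
      cnt <- matrix(1L + rpois(length(rows) * length(mk), marker_strength - 1),
                    nrow = length(rows))
      cnt[!on] <- 0L
      nz <- which(cnt > 0, arr.ind = TRUE)
      ii <- c(ii, rows[nz[, 1]])
      jj <- c(jj, gene_index[mk][nz[, 2]])
      xx <- c(xx, cnt[nz])
      # background expression over the remaining genes
      other <- setdiff(genes, mk)
      if (background_rate > 0) {
        onb <- matrix(runif(length(rows) * length(other)) < background_rate,
                      nrow = length(rows))
        nzb <- which(onb, arr.ind = TRUE)
        if (nrow(nzb)) {
          ii <- c(ii, rows[nzb[, 1]])
          jj <- c(jj, gene_index[other][nzb[, 2]])
          xx <- c(xx, 1L + rpois(nrow(nzb), 1))
        }
      }
    }
    counts <- Matrix::sparseMatrix(
      i = ii, j = jj, x = xx, dims = c(n_cells, length(genes)),
      dimnames = list(cells$barcode, genes)
    )

    structure(
      list(counts = counts, cells = cells, panel = panel,
           config = list(composition = composition,
                         cells_per_sample = cells_per_sample,
                         marker_rate = marker_rate,
                         marker_strength = marker_strength,
                         background_rate = background_rate,
                         n_background_genes = n_background_genes,
                         seed = seed)),
      class = "cells_sim"
    )
  })
}

#' Simulate a breast-cancer cohort with signature-linked age and survival
#'
#' Emulates the cohort-level analysis: a fraction of patients
#' (`frac_high`) carry a coordinately up-shifted gene signature; their ages at
#' diagnosis are drawn from a (possibly bimodal) Gaussian mixture, the
#' remaining patients from a unimodal mixture; overall survival is exponential
#' with a group-specific hazard and independently exponentially censored.
#'
#' @param n_samples Number of patients.
#' @param age_mixture_high,age_mixture_low Lists of `c(weight, mean, sd)`
#'   components (years); weights must sum to 1. Defaults: bimodal 45/65-year
#'   peaks for signature-high, a single 65-year peak for signature-low.
#' @param hazard_high,hazard_low Exponential event rates per year (> 0).
#' @param censor_rate Independent exponential censoring rate per year (> 0).
#' @param frac_high Fraction of signature-high patients, in `[0, 1]`.
#' @param signature_genes Character vector of signature gene ids (non-empty).
#' @param n_background_genes Non-signature genes in the expression matrix.
#' @param signature_shift Log2 up-shift of signature genes in high patients.
#' @param noise_sd Per-measurement Gaussian noise (log2 scale).
#' @param seed Integer seed.
#' @return An object of class `cohort_sim`: list with `cohort` (tibble:
#'   `sample_id`, `age_years`, `os_time` (years), `os_event` (0/1),
#'   `group_true`), `expression` (numeric matrix, genes x samples, log2),
#'   `signature_genes`, `config`.
#' @examples
#' sim <- simulate_cohort(n_samples = 60, seed = 1)
#' head(sim$cohort)
#' @export
simulate_cohort <- function(n_samples = 300,
                            age_mixture_high = list(c(0.5, 45, 3), c(0.5, 65, 3)),
                            age_mixture_low = list(c(1, 65, 8)),
                            hazard_high = 0.10,
                            hazard_low = 0.05,
                            censor_rate = 0.04,
                            frac_high = 1 / 3,
                            signature_genes = sprintf("SIG_%03d", 1:79),
                            n_background_genes = 921,
                            signature_shift = 2,
                            noise_sd = 1,
                            seed = NULL) {
  check_mixture <- function(mix, field) {
    w <- vapply(mix, `[`, numeric(1), 1)
    if (abs(sum(w) - 1) > 1e-8) stop_config(field, "weights must sum to 1")
    if (any(vapply(mix, `[`, numeric(1), 3) <= 0)) {
      stop_config(field, "component sds must be > 0")
    }
  }
  check_mixture(age_mixture_high, "age_mixture_high")
  check_mixture(age_mixture_low, "age_mixture_low")
  if (hazard_high <= 0 || hazard_low <= 0) {
    stop_config("hazard_high/hazard_low", "rates must be > 0")
  }
  if (censor_rate <= 0) stop_config("censor_rate", "must be > 0")
  if (frac_high < 0 || frac_high > 1) stop_config("frac_high", "in [0, 1]")
  if (!length(signature_genes)) {
    stop_config("signature_genes", "must be non-empty")
  }

  draw_mixture <- function(n, mix) {
    w <- vapply(mix, `[`, numeric(1), 1)
    comp <- sample(seq_along(mix), n, replace = TRUE, prob = w)
    mu <- vapply(mix, `[`, numeric(1), 2)[comp]
    sd <- vapply(mix, `[`, numeric(1), 3)[comp]
    rnorm(n, mu, sd)
  }

  with_seed(seed, {
    n_high <- round(n_samples * frac_high)
    group <- c(rep("high", n_high), rep("low", n_samples - n_high))
    age <- numeric(n_samples)
    age[group == "high"] <- draw_mixture(n_high, age_mixture_high)
    age[group == "low"] <- draw_mixture(n_samples - n_high, age_mixture_low)
    age <- pmax(age, 18)

    haz <- ifelse(group == "high", hazard_high, hazard_low)
    t_event <- rexp(n_samples, haz)
    t_cens <- rexp(n_samples, censor_rate)
    os_time <- pmin(t_event, t_cens)
    os_event <- as.integer(t_event <= t_cens)

    cohort <- tibble::tibble(
      sample_id = sprintf("pt_%04d", seq_len(n_samples)),
      age_years = age,
      os_time = os_time,
      os_event = os_event,
      group_true = group
    )

    genes <- c(signature_genes,
               sprintf("BG_%04d", seq_len(n_background_genes)))
    baseline <- rnorm(length(genes), 6, 2)
    expr <- matrix(rnorm(length(genes) * n_samples, 0, noise_sd),
                   nrow = length(genes)) + baseline
    expr[seq_along(signature_genes), group == "high"] <-
      expr[seq_along(signature_genes), group == "high"] + signature_shift
    dimnames(expr) <- list(genes, cohort$sample_id)

    structure(
      list(cohort = cohort, expression = expr,
           signature_genes = signature_genes,
           config = list(n_samples = n_samples,
                         age_mixture_high = age_mixture_high,
                         age_mixture_low = age_mixture_low,
                         hazard_high = hazard_high, hazard_low = hazard_low,
                         censor_rate = censor_rate, frac_high = frac_high,
                         n_background_genes = n_background_genes,
                         signature_shift = signature_shift,
                         noise_sd = noise_sd, seed = seed)),
      class = "cohort_sim"
    )
  })
}
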