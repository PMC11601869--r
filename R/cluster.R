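#' Per-timepoint mean expression profiles
#'
#' Averages replicates within each timepoint, giving one profile vector per
#' age (genes x timepoints matrix) ready for [cluster_timepoints()].
#'
#' @param data A `timecourse_sim` or data frame with columns `gene`,
#'   `timepoint`, `log2_expr`.
#' @return Numeric matrix, genes as rows, one column per timepoint labelled
#'   `<age>m`.
#' @export
timepoint_profiles <- function(data) {
  if (inherits(data, "timecourse_sim")) data <- data$expression
  wide <- data |>
    dplyr::group_by(.data$gene, .data$timepoint) |>
    dplyr::summarise(mean_expr = mean(.data$log2_expr), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "mean_expr",
                       names_glue = "{timepoint}m")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$gene
  m
}

#' Hierarchically cluster timepoint profiles
#'
#' Average-linkage hierarchical clustering of per-timepoint mean expression
#' profiles on correlation distance (1 - Pearson), with the two-cluster cut
#' returned as an unordered partition of timepoint labels. In cyclical aging
#' the expected partition pairs the 3/14-month profiles against the
#' 11/19-month profiles. Deterministic given input order; ties merge
#' lowest-index first (the [stats::hclust()] convention).
#'
#' @param profiles Numeric matrix with one column per timepoint (as from
#'   [timepoint_profiles()]); needs >= 2 columns and a common gene index.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param metric `"correlation"` (1 - Pearson) or `"euclidean"`.
#' @return Object of class `timepoint_clustering`: list with `hclust`, the
#'   two-cluster `partition` (list of two character vectors), and the
#'   distance matrix.
#' @examples
#' sim <- simulate_timecourse(n_genes = 500, n_cyclic_udu = 50, seed = 1)
#' cluster_timepoints(timepoint_profiles(sim))$partition
#' @export
cluster_timepoints <- function(profiles, linkage = "average",
                               metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  if (!is.matrix(profiles) || ncol(profiles) < 2) {
    stop("`profiles` must be a matrix with >= 2 timepoint columns.",
         call. = FALSE)
  }
  if (metric == "correlation") {
    sds <- apply(profiles, 2, stats::sd)
    if (any(sds == 0)) {
      stop(sprintf("profile `%s` is constant; correlation undefined.",
                   colnames(profiles)[which(sds == 0)[1]]), call. = FALSE)
    }
    d <- as.dist(1 - cor(profiles))
  } else {
    d <- stats::dist(t(profiles))
  }
  hc <- hclust(d, method = linkage)
  grp <- cutree(hc, k = 2)
  partition <- unname(split(names(grp), grp))
  structure(
    list(hclust = hc, partition = partition, dist = d, metric = metric,
         linkage = linkage),
    class = "timepoint_clustering"
  )
}

#' @export
print.timepoint_clustering <- function(x, ...) {
  cat("Timepoint clustering (", x$metric, " distance, ", x$linkage,
      " linkage)\n", sep = "")
  cat("2-group partition: {", paste(x$partition[[1]], collapse = ", "),
      "} vs {", paste(x$partition[[2]], collapse = ", "), "}\n")
  invisible(x)
}

#' Test whether a clustering pairs the two phases of cyclical aging
#'
#' Convenience predicate: does the 2-cluster cut equal the given partition
#' (order-insensitive)?
#'
#' @param clustering A `timepoint_clustering`.
#' @param pair One of the two expected groups, e.g. `c("11m", "19m")`.
#' @return Logical scalar.
#' @export
partition_matches <- function(clustering, pair) {
  p <- lapply(clustering$partition, sort)
  pair <- sort(pair)
  identical(p[[1]], pair) || identical(p[[2]], pair)
}

#' Export a timepoint dendrogram as Newick
#'
#' @param clustering A `timepoint_clustering`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(clustering, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the `ape` package is required for Newick export.", call. = FALSE)
  }
  phy <- ape::as.phylo(clustering$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
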