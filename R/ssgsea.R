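#' Single-sample gene-set enrichment score (ssGSEA)
#'
#' Rank-based running-sum enrichment of a gene set within one sample. Genes
#' are ranked by decreasing expression (ties broken by stable gene-id order).
#' Walking down the ranking, `P_in` accumulates the rank-weight mass
#' `|N - i + 1|^alpha` of set genes (normalised to 1 over the set) and
#' `P_out` accumulates uniform mass over non-set genes; the score is the SUM
#' of the running deviations `P_in - P_out` (the ssGSEA convention, not the
#' max-deviation GSEA convention). `alpha = 0.25` follows common ssGSEA
#' practice; `alpha = 0` weights all set genes equally. The score depends on
#' the expression vector only through its ranks, so any strictly increasing
#' transform leaves it unchanged.
#'
#' @param expr Named numeric vector of expression values for one sample.
#' @param gene_set Character vector of set gene ids.
#' @param alpha Rank-weight exponent (>= 0).
#' @return A single number.
#' @examples
#' expr <- c(g1 = 4, g2 = 3, g3 = 2, g4 = 1)
#' ssgsea_score(expr, "g1", alpha = 0) # 1 + 2/3 + 1/3 + 0 = 2
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25) {
  if (is.null(names(expr))) stop("`expr` must be named by gene.", call. = FALSE)
  if (alpha < 0) stop("`alpha` must be >= 0.", call. = FALSE)
  in_set <- names(expr) %in% gene_set
  n_in <- sum(in_set)
  if (n_in == 0 || n_in == length(expr)) {
    stop("degenerate set: it must contain >= 1 and < all genes of `expr`.",
         call. = FALSE)
  }
  # decreasing value; ties broken by stable gene-id order
  ord <- order(-expr, names(expr), method = "radix")
  in_ord <- in_set[ord]
  n <- length(expr)
  w <- (n - seq_len(n) + 1)^alpha
  w[!in_ord] <- 0
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_ord) / (n - n_in)
  sum(p_in - p_out)
}

#' Score every sample of an expression matrix against a gene set
#'
#' @param expr Numeric matrix, genes x samples, with dimnames; or a data
#'   frame with a `gene` column and one column per sample.
#' @param gene_set Character vector of set gene ids (genes absent from the
#'   matrix are ignored).
#' @param alpha Rank-weight exponent, see [ssgsea_score()].
#' @return Tibble with `sample_id` and `score`.
#' @export
score_samples <- function(expr, gene_set, alpha = 0.25) {
  if (is.data.frame(expr)) {
    g <- expr$gene
    expr <- as.matrix(expr[setdiff(names(expr), "gene")])
    rownames(expr) <- g
  }
  gs <- intersect(gene_set, rownames(expr))
  if (!length(gs)) stop("no signature gene is present in `expr`.", call. = FALSE)
  tibble::tibble(
    sample_id = colnames(expr),
    score = apply(expr, 2, ssgsea_score, gene_set = gs, alpha = alpha)
  )
}

#' Top-tertile stratification of enrichment scores
#'
#' Orders samples by decreasing score and labels the top `ceiling(n/3)` as
#' `high`, the rest `low`. Boundary ties are resolved by stable sample-id
#' order and flagged with a warning.
#'
#' @param scores Tibble with `sample_id` and `score` (as from
#'   [score_samples()]), `n >= 3`.
#' @return The input with a `group` column added (`high`/`low`).
#' @examples
#' tertile_stratify(tibble::tibble(sample_id = letters[1:9], score = 1:9))
#' @export
tertile_stratify <- function(scores) {
  n <- nrow(scores)
  if (n < 3) stop("tertile stratification needs >= 3 samples.", call. = FALSE)
  n_high <- ceiling(n / 3)
  ord <- order(-scores$score, scores$sample_id, method = "radix")
  grp <- rep("low", n)
  grp[ord[seq_len(n_high)]] <- "high"
  boundary <- scores$score[ord[n_high]]
  if (n_high < n && scores$score[ord[n_high + 1]] == boundary) {
    warning("ties at the tertile boundary resolved by sample-id order.",
            call. = FALSE)
  }
  dplyr::mutate(scores, group = grp)
}
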