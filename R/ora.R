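#' Hypergeometric over-representation analysis
#'
#' Local replacement for web-service enrichment: for each gene set, the
#' upper-tail hypergeometric probability `P(X >= overlap)` of drawing the
#' observed overlap when `length(query)` genes are sampled from the universe
#' without replacement, with BH adjustment across sets. Sets are intersected
#' with the universe first.
#'
#' @param query Character vector of genes of interest (must be contained in
#'   `universe`).
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Character vector of all assayed genes (non-empty).
#' @return Tibble with `set`, `set_size`, `overlap`, `expected`, `fold`,
#'   `p`, `q`, ordered as given.
#' @examples
#' ora_enrichment(c("a", "b"), list(s1 = c("a", "b", "c")), letters[1:10])
#' @export
ora_enrichment <- function(query, gene_sets, universe) {
  if (!length(universe)) stop("`universe` must be non-empty.", call. = FALSE)
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe)) {
    stop("`query` must be a subset of `universe`.", call. = FALSE)
  }
  if (setequal(query, universe)) {
    warning("query equals the universe; every p-value is 1 by construction.",
            call. = FALSE)
  }
  n_u <- length(universe)
  n_q <- length(query)
  res <- purrr::imap_dfr(gene_sets, function(gs, nm) {
    gs <- intersect(unique(gs), universe)
    k <- length(intersect(gs, query))
    m <- length(gs)
    # P(X >= k), X ~ Hypergeom(m set genes, n_u - m others, n_q draws)
    p <- if (k == 0) 1 else phyper(k - 1, m, n_u - m, n_q, lower.tail = FALSE)
    expected <- n_q * m / n_u
    tibble::tibble(set = nm, set_size = m, overlap = k,
                   expected = expected,
                   fold = ifelse(expected > 0, k / expected, NA_real_),
                   p = p)
  })
  res$q <- bh_adjust(res$p)
  res
}
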