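# Independent re-derivations used as test oracles.

# ssGSEA running sum recomputed position by position from scratch.
ssgsea_brute <- function(expr, gene_set, alpha) {
  ord <- order(-expr, names(expr), method = "radix")
  genes <- names(expr)[ord]
  n <- length(genes)
  in_set <- genes %in% gene_set
  wtot <- sum((n - which(in_set) + 1)^alpha)
  score <- 0
  for (i in seq_len(n)) {
    p_in <- sum((n - (1:i)[in_set[1:i]] + 1)^alpha) / wtot
    p_out <- sum(!in_set[1:i]) / (n - sum(in_set))
    score <- score + (p_in - p_out)
  }
  score
}
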