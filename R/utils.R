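# Internal helpers.

# Evaluate `code` under a local RNG seed, restoring the caller's RNG state.
# A NULL seed leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("`seed` must be a single integer.", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a reproducible sub-seed for a named pipeline stage from a master
# seed. Keeps results independent across stages while driven by one seed.
stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 1009L + as.integer(h %% 104729L)) %% 2147483587L
}

stop_config <- function(field, msg) {
  stop(sprintf("configuration error in `%s`: %s", field, msg), call. = FALSE)
}
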