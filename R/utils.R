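# Deterministic substream seeds: one master integer seed fans out to n
# child seeds (< 2^31) so per-cell / per-curve randomness is reproducible
# independently of evaluation order.
substream_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# standard error of the mean (sample SD, n-1 denominator)
sem <- function(x) stats::sd(x) / sqrt(length(x))
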