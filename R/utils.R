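# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library code never clobbers user RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed for a (chromosome, stratum) pair so per-chromosome
# work is reproducible regardless of iteration order. Kept below 2^31.
derive_seed <- function(seed, chrom, j = 0L) {
  h <- sum(utf8ToInt(as.character(chrom)) * seq_along(utf8ToInt(as.character(chrom))))
  as.integer((as.numeric(seed) * 48271 + h * 7919 + as.numeric(j) * 104729) %% 2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.finite(x) && x == round(x) && x >= 0
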