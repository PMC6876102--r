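library(data.table)

# Fragment table builder: one complex from explicit coordinates.
frags <- function(starts, ends, cid = "c1", chrom = "chr2L") {
  data.table(chrom = chrom, start = as.numeric(starts),
             end = as.numeric(ends), cid = cid)
}

# The three-fragment complex used throughout the documentation:
# (chr2L,100,500), (chr2L,1000,1500), (chr2L,6000,6500).
oc8 <- function(cid = "OC8") {
  frags(c(100, 1000, 6000), c(500, 1500, 6500), cid = cid)
}

toy_sizes <- c(chr2L = 1e7, chr3R = 1e7)

# Brute-force Benjamini-Hochberg step-up: returns the rejection mask.
bh_mask_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= alpha * seq_len(m) / m)
  mask <- logical(m)
  if (length(ok)) mask[o[seq_len(max(ok))]] <- TRUE
  mask
}

# Literal double-loop expanded-pair statistics (occurrence-weighted).
pair_stats_oracle <- function(combo, occurrences = rep(1L, length(combo))) {
  members <- lapply(strsplit(combo, ",", fixed = TRUE), sort)
  sizes <- lengths(members)
  pa <- lapply(members, function(m) {
    out <- character(0)
    for (r in seq_along(m)) for (s in seq_along(m)) {
      if (r < s) out <- c(out, paste(m[r], m[s], sep = "|"))
    }
    out
  })
  a <- b <- numeric(length(combo))
  for (i in seq_along(combo)) {
    for (y in seq_along(combo)) {
      if (sizes[y] == sizes[i]) {
        for (w in pa[[y]]) if (w %in% pa[[i]]) a[i] <- a[i] + occurrences[y]
      }
      if (sizes[y] > sizes[i] && all(members[[i]] %in% members[[y]])) {
        b[i] <- b[i] + occurrences[y]
      }
    }
  }
  x <- a + b * sizes * (sizes - 1) / 2
  k <- vapply(seq_along(combo),
              function(i) sum(x[sizes == sizes[i]]), numeric(1))
  data.table(combo = combo, N_tads = sizes, a = a, b = b, x = x, k = k)
}

# Exact mean signal of a bedGraph over [s, e), uncovered basepairs = 0.
exact_bg_mean <- function(bg, s, e) {
  ov <- pmax(0, pmin(bg$end, e) - pmax(bg$start, s))
  sum(ov * bg$value) / (e - s)
}
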