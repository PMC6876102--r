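#' Enrichment-test configuration
#'
#' @param n_samples random placements per complex used to build the
#'   empirical null (default 10,000).
#' @param fdr false-discovery rate for the BH step (default 0.1).
#' @param seed integer RNG seed; each chromosome derives its own sub-seed.
#' @return list of class `mcia_enrich_config`.
#' @export
enrichment_config <- function(n_samples = 10000L, fdr = 0.1, seed = 1L) {
  stopifnot(n_samples >= 100, fdr > 0, fdr < 1, is_count(seed))
  structure(list(n_samples = as.integer(n_samples), fdr = fdr,
                 seed = as.integer(seed)),
            class = "mcia_enrich_config")
}

#' Bin a bedGraph signal into fixed-width bins
#'
#' Each bin's value is the basepair-weighted mean of the overlapping
#' bedGraph intervals, treating uncovered basepairs as signal 0 (so a bin
#' value is `sum(overlap_bp * value) / bin_size`). The binned track turns
#' coverage lookups into O(1) index arithmetic.
#'
#' @param bedgraph a `data.table`/data.frame with columns `chrom`, `start`,
#'   `end`, `value` (sorted, non-overlapping), or a path readable by
#'   [read_bedgraph()].
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param bin_size bin width in bp (default 10).
#' @return Named list of `mcia_track` objects, one per chromosome in
#'   `chrom_sizes` (all-zero where the bedGraph has no intervals).
#' @export
bin_coverage <- function(bedgraph, chrom_sizes, bin_size = 10) {
  if (is.character(bedgraph)) bedgraph <- read_bedgraph(bedgraph)
  bg <- as.data.table(bedgraph)
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(bg)))
  check_bedgraph(bg)
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  out <- list()
  for (ch in names(chrom_sizes)) {
    len <- chrom_sizes[[ch]]
    nb <- as.integer(ceiling(len / bin_size))
    acc <- numeric(nb)
    iv <- bg[chrom == ch]
    if (nrow(iv)) {
      if (any(iv$end > len)) stopf("bedGraph interval beyond %s end", ch)
      s <- iv$start; e <- iv$end; v <- iv$value
      b1 <- floor(s / bin_size) + 1   # first overlapped bin
      b2 <- ceiling(e / bin_size)     # last overlapped bin
      one <- b1 == b2
      # interval within a single bin
      if (any(one)) {
        w <- (e[one] - s[one]) * v[one]
        ag <- rowsum(w, b1[one])
        ii <- as.integer(rownames(ag))
        acc[ii] <- acc[ii] + ag[, 1L]
      }
      multi <- which(!one)
      if (length(multi)) {
        # partial head and tail bins
        wh <- (b1[multi] * bin_size - s[multi]) * v[multi]
        ag <- rowsum(wh, b1[multi]); ii <- as.integer(rownames(ag))
        acc[ii] <- acc[ii] + ag[, 1L]
        wt <- (e[multi] - (b2[multi] - 1) * bin_size) * v[multi]
        ag <- rowsum(wt, b2[multi]); ii <- as.integer(rownames(ag))
        acc[ii] <- acc[ii] + ag[, 1L]
        # full interior bins via a difference array
        f1 <- b1[multi] + 1L; f2 <- b2[multi] - 1L
        has <- f2 >= f1
        if (any(has)) {
          d <- numeric(nb + 1L)
          ag <- rowsum(v[multi][has] * bin_size, f1[has])
          ii <- as.integer(rownames(ag)); d[ii] <- d[ii] + ag[, 1L]
          ag <- rowsum(v[multi][has] * bin_size, f2[has] + 1L)
          ii <- as.integer(rownames(ag)); d[ii] <- d[ii] - ag[, 1L]
          acc <- acc + cumsum(d)[seq_len(nb)]
        }
      }
    }
    out[[ch]] <- structure(list(chrom = ch, bin_size = bin_size,
                                values = acc / bin_size),
                           class = "mcia_track")
  }
  out
}

# Simple bin-mean over the bins overlapped by [s, e); `cum` is c(0, cumsum(values)).
frag_bin_mean <- function(s, e, bin_size, cum, nb) {
  b1 <- pmax(1L, pmin(nb, floor(s / bin_size) + 1L))
  b2 <- pmax(b1, pmin(nb, ceiling(e / bin_size)))
  (cum[b2 + 1L] - cum[b1]) / (b2 - b1 + 1L)
}

#' Mean binding coverage of a complex
#'
#' `covg` is the mean over fragments of the mean binned signal across each
#' fragment's span (a simple lookup over fully and partially overlapped
#' bins).
#'
#' @param fragments fragment table of one complex (`start`, `end`), or an
#'   `mcia_complexes` holding a single complex.
#' @param cov an `mcia_track` of binned coverage for the complex's
#'   chromosome (one element of [bin_coverage()]).
#' @return Numeric scalar `covg >= 0`.
#' @export
complex_coverage <- function(fragments, cov) {
  if (inherits(fragments, "mcia_complexes")) fragments <- fragments$fragments
  stopifnot(inherits(cov, "mcia_track"))
  cum <- c(0, cumsum(cov$values))
  nb <- length(cov$values)
  mean(frag_bin_mean(fragments$start, fragments$end, cov$bin_size, cum, nb))
}

#' Empirical enrichment p-value of one complex
#'
#' The complex is rigidly shifted (inter-fragment spacing preserved) to
#' `n_samples` random positions drawn uniformly among placements that keep
#' the whole complex within `[0, chrom_length)`; the raw p-value is the
#' proportion of placements whose coverage strictly exceeds the observed
#' coverage.
#'
#' @param fragments fragment table of one complex, sorted by position.
#' @param cov an `mcia_track` of binned coverage.
#' @param chrom_length chromosome length in bp.
#' @param cfg an [enrichment_config()].
#' @return list with `covg` (observed), `raw_p`, and `testable` (`FALSE`
#'   when the complex span is at least the chromosome length, in which case
#'   `raw_p` is `NA`).
#' @export
enrichment_pvalue <- function(fragments, cov, chrom_length,
                              cfg = enrichment_config()) {
  fr <- as.data.table(fragments)
  obs <- complex_coverage(fr, cov)
  span <- max(fr$end) - min(fr$start)
  if (span >= chrom_length) {
    return(list(covg = obs, raw_p = NA_real_, testable = FALSE))
  }
  cum <- c(0, cumsum(cov$values))
  nb <- length(cov$values)
  with_seed(cfg$seed, {
    shifts <- sample.int(chrom_length - span + 1, cfg$n_samples,
                         replace = TRUE) - 1L
  })
  p <- shifted_exceed_fraction(fr, cov, cum, nb, shifts, obs)
  list(covg = obs, raw_p = p, testable = TRUE)
}

# Fraction of placements (new span starts in `shifts`) with covg > obs.
shifted_exceed_fraction <- function(fr, cov, cum, nb, shifts, obs) {
  off_s <- fr$start - min(fr$start)
  off_e <- fr$end - min(fr$start)
  tot <- numeric(length(shifts))
  for (l in seq_along(off_s)) {
    tot <- tot + frag_bin_mean(shifts + off_s[l], shifts + off_e[l],
                               cov$bin_size, cum, nb)
  }
  mean(tot / length(off_s) > obs)
}

#' Remove fragments overlapping repeat regions
#'
#' Fragments overlapping any repeat interval are dropped; complexes left
#' with fewer than 2 fragments are removed entirely.
#'
#' @param x an `mcia_complexes` object.
#' @param repeats repeat annotation: a data.frame with `chrom`, `start`,
#'   `end` columns, a `GRanges`, or a BED file path.
#' @return A filtered `mcia_complexes` object.
#' @export
filter_repeats <- function(x, repeats) {
  stopifnot(inherits(x, "mcia_complexes"))
  if (is.character(repeats)) {
    dt <- fread(repeats, header = FALSE, sep = "\t",
                colClasses = list(character = 1))
    repeats <- data.table(chrom = dt[[1L]], start = as.numeric(dt[[2L]]),
                          end = as.numeric(dt[[3L]]))
  }
  if (!methods::is(repeats, "GRanges")) {
    rp <- as.data.table(repeats)
    if (nrow(rp) == 0L) return(x)
    repeats <- GenomicRanges::GRanges(
      rp$chrom, IRanges::IRanges(start = rp$start + 1, end = rp$end))
  }
  fr <- x$fragments
  gr <- GenomicRanges::GRanges(
    fr$chrom, IRanges::IRanges(start = fr$start + 1, end = fr$end))
  hit <- IRanges::overlapsAny(gr, repeats)
  kept <- fr[!hit]
  keep_ids <- kept[, .N, by = .(chrom, cid)][N >= 2L, cid]
  kept <- kept[cid %in% keep_ids]
  structure(list(fragments = setkey(copy(kept), chrom, cid, start)[],
                 chrom_sizes = x$chrom_sizes),
            class = "mcia_complexes")
}

#' Enrichment test over a set of complexes
#'
#' Computes each complex's observed coverage and empirical shift-null
#' p-value ([enrichment_pvalue()]), BH-adjusts per chromosome and labels
#' complexes `pass` (adjusted p <= fdr), `fail`, or `untestable`. Each
#' complex draws its placements from a sub-seed derived from `cfg$seed` and
#' its ID, so results do not depend on iteration order.
#'
#' @param x an `mcia_complexes` object (repeat-filtered if desired, see
#'   [filter_repeats()]).
#' @param cov named list of `mcia_track`s from [bin_coverage()].
#' @param cfg an [enrichment_config()].
#' @return list of class `mcia_enrich_result` with `master` (`data.table`:
#'   `cid`, `chrom`, `n`, `covg`, `raw_p`, `adj_p`, `category`),
#'   `complexes` (the input) and `cfg`.
#' @export
run_enrichment_test <- function(x, cov, cfg = enrichment_config()) {
  stopifnot(inherits(x, "mcia_complexes"))
  ct <- complex_table(x)
  chroms <- sort(unique(ct$chrom))
  rows <- list()
  for (ch in chroms) {
    if (is.null(cov[[ch]])) stopf("no coverage track for chromosome %s", ch)
    trk <- cov[[ch]]
    if (all(trk$values == 0)) {
      warnf("coverage on %s is identically zero; enrichment test is degenerate", ch)
    }
    len <- x$chrom_sizes[[ch]]
    cum <- c(0, cumsum(trk$values))
    nb <- length(trk$values)
    frs <- split(x$fragments[chrom == ch], by = "cid")
    cti <- ct[chrom == ch]
    res <- data.table(cid = cti$cid, chrom = ch, n = cti$n,
                      covg = NA_real_, raw_p = NA_real_)
    for (i in seq_len(nrow(res))) {
      fr <- frs[[res$cid[i]]]
      obs <- complex_coverage(fr, trk)
      res$covg[i] <- obs
      span <- max(fr$end) - min(fr$start)
      if (span >= len) next  # untestable: flagged by raw_p = NA
      sd_i <- derive_seed(cfg$seed, ch, sum(utf8ToInt(res$cid[i])))
      with_seed(sd_i, {
        shifts <- sample.int(len - span + 1, cfg$n_samples,
                             replace = TRUE) - 1L
      })
      res$raw_p[i] <- shifted_exceed_fraction(fr, trk, cum, nb, shifts, obs)
    }
    res[, adj_p := stats::p.adjust(raw_p, method = "BH")]
    res[, category := fcase(is.na(raw_p), "untestable",
                            adj_p <= cfg$fdr, "pass",
                            default = "fail")]
    rows[[ch]] <- res
  }
  master <- rbindlist(rows)
  setorder(master, chrom, cid)
  structure(list(master = master, complexes = x, cfg = cfg),
            class = "mcia_enrich_result")
}

#' @export
print.mcia_enrich_result <- function(x, ...) {
  tb <- table(x$master$category)
  cat("mcia enrichment test\n")
  for (nm in names(tb)) cat(sprintf("  %-10s %d\n", nm, tb[[nm]]))
  invisible(x)
}
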