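#' Split complexes at gaps exceeding a maximum span
#'
#' Before building the 1D track, fragments more than `max_gap` apart are
#' separated so that long-range (likely spurious or inter-domain) complexes
#' do not bridge unrelated regions. The default of 100 kb reflects the
#' upper range of typical TAD sizes.
#'
#' @param x an `mcia_complexes` object.
#' @param max_gap maximum allowed F2F gap in bp (default 1e5).
#' @return An `mcia_complexes` with each complex cut at every gap larger
#'   than `max_gap`; sub-complexes carry deterministic `.k` suffixes (a
#'   complex left whole keeps its ID).
#' @export
split_distant <- function(x, max_gap = 100000) {
  stopifnot(inherits(x, "mcia_complexes"))
  fr <- copy(x$fragments)
  setorder(fr, chrom, cid, start)
  fr[, grp := cumsum(c(TRUE, start[-1L] - end[-.N] > max_gap)),
     by = .(chrom, cid)]
  fr[, newrun := max(grp) > 1L, by = .(chrom, cid)]
  fr[newrun == TRUE, cid := paste0(cid, ".", grp)]
  fr[, c("grp", "newrun") := NULL]
  structure(list(fragments = setkey(fr, chrom, cid, start)[],
                 chrom_sizes = x$chrom_sizes),
            class = "mcia_complexes")
}

#' Weighted complex-span coverage track
#'
#' Each complex with n >= 2 fragments contributes linearly: the value n is
#' added to every bin overlapped by its span `[start(first), end(last))`.
#' This avoids the quadratic over-contribution of pair enumeration while
#' keeping fragment-rich complexes influential. Singletons are skipped.
#'
#' @param x an `mcia_complexes` object (normally pre-split with
#'   [split_distant()]).
#' @param bin_size bin width in bp (default 1000).
#' @param chrom chromosome; defaults to the single chromosome present.
#' @return list of class `mcia_track`: `chrom`, `bin_size`, `values`
#'   (one non-negative value per bin, length `ceiling(len / bin_size)`).
#' @export
weighted_span_coverage <- function(x, bin_size = 1000, chrom = NULL) {
  stopifnot(inherits(x, "mcia_complexes"))
  if (is.null(chrom)) {
    chrom <- unique(x$fragments$chrom)
    if (length(chrom) != 1L) stopf("specify `chrom`: several present")
  }
  len <- x$chrom_sizes[[chrom]]
  nb <- as.integer(ceiling(len / bin_size))
  ct <- complex_table(x)
  ct <- ct[ct$chrom == chrom & ct$n >= 2L]
  vals <- numeric(nb)
  if (nrow(ct)) {
    b1 <- pmin(nb, floor(ct$span_start / bin_size) + 1L)
    b2 <- pmin(nb, ceiling(ct$span_end / bin_size))
    # difference-array accumulation of n over [b1, b2]
    d <- numeric(nb + 1L)
    agg1 <- rowsum(ct$n, b1)
    d[as.integer(rownames(agg1))] <- d[as.integer(rownames(agg1))] + agg1[, 1L]
    agg2 <- rowsum(ct$n, b2 + 1L)
    ii <- as.integer(rownames(agg2))
    ok <- ii <= nb + 1L
    d[ii[ok]] <- d[ii[ok]] - agg2[ok, 1L]
    vals <- cumsum(d)[seq_len(nb)]
  }
  structure(list(chrom = chrom, bin_size = bin_size, values = vals),
            class = "mcia_track")
}

# Walk an edge outward (dir -1 left, +1 right) while the track stays above
# `floor`, tolerating short interruptions of up to `tol` bins; returns the
# outermost above-floor bin reached.
edge_walk <- function(rv, b, floor, tol, dir, max_walk = 16L) {
  last_good <- b
  i <- b + dir
  bad <- 0L
  while (i >= 1L && i <= length(rv) && abs(i - b) <= max_walk) {
    if (rv[i] > floor) {
      last_good <- i
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad > tol) break
    }
    i <- i + dir
  }
  last_good
}

# One level of the Haar (= biorthogonal 1.1) analysis filter bank.
haar_step <- function(v) {
  if (length(v) %% 2L == 1L) v <- c(v, v[length(v)])  # symmetric-ish pad
  idx <- seq(1L, length(v), by = 2L)
  list(approx = (v[idx] + v[idx + 1L]) / sqrt(2),
       detail = (v[idx] - v[idx + 1L]) / sqrt(2))
}

#' Low-pass wavelet smoothing of a signal track
#'
#' Multilevel discrete wavelet decomposition with the "bior1.1" wavelet
#' (identical to the Haar pair); all detail coefficients up to `level` are
#' zeroed and the signal reconstructed, which replaces the track by its
#' local low-frequency component (block averages of width `2^level` bins
#' up to boundary handling) while preserving sharp large-scale change
#' points. Output is cropped to the input length and clamped at 0.
#'
#' @param track an `mcia_track` from [weighted_span_coverage()], or a plain
#'   numeric vector.
#' @param wavelet wavelet name; `"bior1.1"` and `"haar"` (the same filter
#'   pair) are supported.
#' @param level decomposition level (default 3). If the track is shorter
#'   than `2^level` the level is reduced with a warning.
#' @return An object of the same kind as the input with smoothed values.
#' @export
wavelet_smooth <- function(track, wavelet = "bior1.1", level = 3L) {
  if (!wavelet %in% c("bior1.1", "haar"))
    stopf("unsupported wavelet '%s' (use bior1.1/haar)", wavelet)
  v <- if (inherits(track, "mcia_track")) track$values else as.numeric(track)
  nv <- length(v)
  if (nv < 2L) return(track)
  max_lev <- floor(log2(nv))
  if (level > max_lev) {
    warnf("track of %d bins supports level %d at most; reducing", nv, max_lev)
    level <- max_lev
  }
  lens <- integer(level)
  a <- v
  for (l in seq_len(level)) {      # analysis: keep only the approximation
    lens[l] <- length(a)
    a <- haar_step(a)$approx
  }
  for (l in rev(seq_len(level))) { # synthesis with zeroed details
    a <- rep(a, each = 2L) / sqrt(2)
    a <- a[seq_len(lens[l])]
  }
  a <- pmax(a, 0)
  if (inherits(track, "mcia_track")) {
    track$values <- a
    track
  } else {
    a
  }
}

#' Segment a smoothed track into TADs and gaps
#'
#' Candidate TADs are maximal runs of bins whose smoothed signal exceeds a
#' floor (by default 5% of the 95th percentile of the positive smoothed
#' values -- anchoring the floor to the high-signal regime keeps it robust
#' when sparse background coverage dominates the positive-bin count). The
#' low-pass reconstruction is blocky, so candidate edges are refined on
#' the raw track when it is supplied: each edge walks outward from the
#' candidate while the raw signal stays above a floor proportional to the
#' candidate's own plateau, so boundaries snap to the extent of the
#' underlying coverage at the scale of one complex span. Candidates shorter
#' than
#' `min_tad_bins` are dropped and the regions between consecutive TADs are
#' reported as gaps.
#'
#' @param smoothed an `mcia_track` of smoothed values (see
#'   [wavelet_smooth()]).
#' @param raw optional `mcia_track` of the unsmoothed values used for
#'   boundary refinement.
#' @param min_signal absolute signal floor; default 5% of the 95th
#'   percentile of the positive bins of `smoothed`.
#' @param min_tad_bins minimum TAD width in bins (default 10).
#' @return `data.table` with columns `chrom`, `start`, `end` (bp,
#'   bin-aligned for unrefined edges), `kind` (`"TAD"`/`"gap"`), sorted and
#'   non-overlapping, TADs and gaps alternating.
#' @export
segment_tads <- function(smoothed, raw = NULL, min_signal = NULL,
                         min_tad_bins = 10L) {
  stopifnot(inherits(smoothed, "mcia_track"))
  v <- smoothed$values
  bs <- smoothed$bin_size
  if (is.null(min_signal)) {
    pos <- v[v > 0]
    min_signal <- if (length(pos)) {
      0.05 * stats::quantile(pos, 0.95, names = FALSE)
    } else {
      Inf
    }
  }
  above <- v > min_signal
  if (!any(above)) {
    return(data.table(chrom = character(0), start = numeric(0),
                      end = numeric(0), kind = character(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- data.table(b1 = starts[r$values], b2 = ends[r$values])

  if (!is.null(raw)) {
    rv <- if (inherits(raw, "mcia_track")) raw$values else as.numeric(raw)
    stopifnot(length(rv) == length(v))
    # Each edge walks outward while the raw signal stays above a floor set
    # relative to the candidate's own plateau (4% of its maximum raw value).
    # The coverage ramp at a domain edge is one complex span wide, so a
    # plateau-proportional floor lands within a few bins of the true edge
    # while staying above stray low-weight background spans.
    tol <- 2L  # low bins tolerated before the walk stops
    # ambient background: positive raw signal outside every candidate
    # (stray spans crossing the gaps); the walk floor must clear it while
    # staying far below the candidate's own plateau
    out <- rep(TRUE, length(rv))
    for (i in seq_len(nrow(cand))) out[cand$b1[i]:cand$b2[i]] <- FALSE
    bgv <- rv[out & rv > 0]
    bg <- if (length(bgv)) stats::median(bgv) else 0
    # the refinement corrects the 2^level block quantization of the
    # smoothed candidate, so each edge moves at most two blocks (16 bins)
    for (i in seq_len(nrow(cand))) {
      e1 <- cand$b1[i]; e2 <- cand$b2[i]
      raw_floor <- max(2 * bg, 0.01 * max(rv[e1:e2]))
      while (e1 < e2 && rv[e1] <= raw_floor) e1 <- e1 + 1L
      while (e2 > e1 && rv[e2] <= raw_floor) e2 <- e2 - 1L
      set(cand, i, "b1", edge_walk(rv, e1, raw_floor, tol, -1L))
      set(cand, i, "b2", edge_walk(rv, e2, raw_floor, tol, +1L))
    }
    # refinement may make neighbours touch; merge any overlap
    setorder(cand, b1)
    cand[, grp := cumsum(c(TRUE, b1[-1L] > cummax(b2[-.N]) + 1L))]
    cand <- cand[, .(b1 = min(b1), b2 = max(b2)), by = grp][, grp := NULL]
  }
  cand <- cand[b2 - b1 + 1L >= min_tad_bins]
  if (nrow(cand) == 0L) {
    return(data.table(chrom = character(0), start = numeric(0),
                      end = numeric(0), kind = character(0)))
  }
  tads <- cand[, .(chrom = smoothed$chrom, start = (b1 - 1) * bs,
                   end = b2 * bs, kind = "TAD")]
  out <- tads
  if (nrow(tads) > 1L) {
    gaps <- data.table(chrom = smoothed$chrom,
                       start = tads$end[-nrow(tads)],
                       end = tads$start[-1L], kind = "gap")
    gaps <- gaps[end > start]
    out <- rbind(tads, gaps)
  }
  setorder(out, start)
  out[]
}

#' Call TADs from multiplex complexes
#'
#' End-to-end caller: complexes are cut at gaps larger than `max_gap`
#' ([split_distant()]), converted to a weighted span-coverage track per
#' chromosome ([weighted_span_coverage()]), low-pass smoothed with a
#' level-`level` "bior1.1" wavelet decomposition ([wavelet_smooth()]) and
#' segmented into TADs and interleaving gaps ([segment_tads()]).
#'
#' @param x an `mcia_complexes` object (typically the significant complexes
#'   of [run_distance_test()]).
#' @param bin_size bin width in bp (default 1000).
#' @param species preset for `max_gap`/`min_tad_bins`; `"drosophila"`
#'   (100 kb, 10 bins) is provided, or `NULL` to use the explicit values.
#' @param max_gap,min_tad_bins,min_signal,wavelet,level see the individual
#'   steps.
#' @return list of class `mcia_tads`: `tads` (`data.table` of `chrom`,
#'   `start`, `end`, `kind`, plus `tad_id` for TAD rows), `tracks` (per
#'   chromosome raw and smoothed `mcia_track`s) and the parameters used.
#' @export
call_tads <- function(x, bin_size = 1000, species = "drosophila",
                      max_gap = 100000, min_tad_bins = 10L,
                      min_signal = NULL, wavelet = "bior1.1", level = 3L) {
  stopifnot(inherits(x, "mcia_complexes"))
  if (!is.null(species)) {
    preset <- switch(species,
                     drosophila = list(max_gap = 100000, min_tad_bins = 10L),
                     stopf("unknown species preset '%s'", species))
    max_gap <- preset$max_gap
    min_tad_bins <- preset$min_tad_bins
  }
  xs <- split_distant(x, max_gap = max_gap)
  chroms <- sort(unique(xs$fragments$chrom))
  out <- list()
  tracks <- list()
  for (ch in chroms) {
    raw <- weighted_span_coverage(xs, bin_size = bin_size, chrom = ch)
    sm <- wavelet_smooth(raw, wavelet = wavelet, level = level)
    seg <- segment_tads(sm, raw = raw, min_signal = min_signal,
                        min_tad_bins = min_tad_bins)
    out[[ch]] <- seg
    tracks[[ch]] <- list(raw = raw, smoothed = sm)
  }
  tads <- rbindlist(out)
  if (nrow(tads)) {
    setorder(tads, chrom, start)
    tads[, tad_id := NA_character_]
    tads[kind == "TAD", tad_id := paste0("TAD_", chrom, "_", seq_len(.N)),
         by = chrom]
  } else {
    tads <- data.table(chrom = character(0), start = numeric(0),
                       end = numeric(0), kind = character(0),
                       tad_id = character(0))
  }
  structure(list(tads = tads, tracks = tracks,
                 params = list(bin_size = bin_size, max_gap = max_gap,
                               min_tad_bins = min_tad_bins,
                               wavelet = wavelet, level = level)),
            class = "mcia_tads")
}

#' @export
print.mcia_tads <- function(x, ...) {
  td <- x$tads[kind == "TAD"]
  cat(sprintf("mcia TAD call: %d TADs on %d chromosome(s)", nrow(td),
              length(unique(td$chrom))))
  if (nrow(td)) {
    cat(sprintf("; median size %g kb", stats::median(td$end - td$start) / 1000))
  }
  cat("\n")
  invisible(x)
}
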