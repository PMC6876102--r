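#' Simulation configuration
#'
#' Describes a synthetic multiplex chromatin-interaction dataset with known
#' ground truth: planted TADs populated by compact intra-TAD complexes,
#' uniform long-range noise complexes, artificial multiplets built by
#' concatenating independent singlets (the droplet co-encapsulation model),
#' and a peaked binding-coverage track with peak-bound complexes for the
#' enrichment test.
#'
#' Intra-complex gaps are drawn log-uniformly from `gap_range` (default
#' 2-8 kb), a deliberately tight spread: evenly spaced fragments are the
#' singlet signature the entropy filter relies on. Fragment counts default
#' to `2 + Poisson(8)`, the fragment-rich regime in which the
#' class-stratified distance test has power (see the methods vignette).
#'
#' @param chrom chromosome name (default `"chrS"`).
#' @param chrom_length chromosome length in bp (default 5 Mb).
#' @param tads optional data.frame of planted TADs (`start`, `end`); when
#'   `NULL`, `n_tads` TADs with sizes uniform in `tad_size_range` are
#'   placed left to right with inter-TAD gaps of at least `min_tad_gap`.
#' @param n_tads,tad_size_range,min_tad_gap automatic TAD placement
#'   parameters (defaults 5 TADs of 100-500 kb, gaps >= 200 kb).
#' @param complexes_per_tad intra-TAD complexes planted per TAD.
#' @param frags_per_complex function drawing `m` fragment counts (>= 2).
#' @param frag_len_mean,frag_len_sd fragment length distribution in bp
#'   (normal, floored at 50).
#' @param gap_range intra-complex F2F gap range in bp (log-uniform).
#' @param noise_fraction share of all complexes whose fragments are uniform
#'   over the chromosome.
#' @param multiplet_fraction share of all complexes that are multiplets
#'   (concatenations of 2, or 3 with probability `triplet_share`,
#'   independent singlets from distinct TADs).
#' @param triplet_share probability that a multiplet is a triplet.
#' @param peaks optional data.frame of coverage peaks (`center`, `width`,
#'   `height`); when `NULL` and `peak_bound_fraction > 0` or
#'   `n_peaks > 0`, `n_peaks` Gaussian peaks are placed uniformly.
#' @param n_peaks,peak_width,peak_height,baseline coverage-track parameters
#'   (defaults: 10 peaks, 2 kb wide, height 30 over baseline 1).
#' @param baseline_noise_sd,noise_block log-scale standard deviation and
#'   correlation length (bp) of the multiplicative background noise applied
#'   to the baseline, emulating uneven accessibility/mappability (defaults
#'   0.3 and 200 bp; the lognormal is mean-corrected). A noisy background
#'   keeps the enrichment null non-degenerate, as in real coverage data.
#' @param peak_bound_fraction share of all complexes whose fragments are
#'   placed inside peak regions.
#' @param seed integer RNG seed.
#' @return list of class `mcia_sim_config`.
#' @export
sim_config <- function(chrom = "chrS", chrom_length = 5e6,
                       tads = NULL, n_tads = 5L,
                       tad_size_range = c(1e5, 5e5), min_tad_gap = 2e5,
                       complexes_per_tad = 100L,
                       frags_per_complex = function(m) 2L + rpois(m, 8),
                       frag_len_mean = 500, frag_len_sd = 100,
                       gap_range = c(2000, 8000),
                       noise_fraction = 0, multiplet_fraction = 0,
                       triplet_share = 0.15,
                       peaks = NULL, n_peaks = 10L, peak_width = 2000,
                       peak_height = 30, baseline = 1,
                       baseline_noise_sd = 0.3, noise_block = 200,
                       peak_bound_fraction = 0, seed = 1L) {
  stopifnot(chrom_length > 0,
            noise_fraction >= 0, noise_fraction <= 1,
            multiplet_fraction >= 0, multiplet_fraction <= 1,
            peak_bound_fraction >= 0, peak_bound_fraction <= 1,
            noise_fraction + multiplet_fraction + peak_bound_fraction < 1,
            triplet_share >= 0, triplet_share <= 1,
            gap_range[1] >= 1, gap_range[2] >= gap_range[1],
            is_count(seed))
  structure(as.list(environment()), class = "mcia_sim_config")
}

#' Generate a synthetic multiplex dataset with ground truth
#'
#' Deterministic for a fixed seed. Complex counts: intra-TAD complexes are
#' `complexes_per_tad * n_tads`; the noise / multiplet / peak-bound counts
#' are set so that they make up their configured fractions of the total.
#'
#' @param cfg an [sim_config()].
#' @param out_dir optional directory; when given, writes `complexes.tsv`
#'   (master format), `truth.tsv`, `coverage.bedgraph`, `chrom.sizes` and
#'   `tads.bed` there.
#' @return list of class `mcia_sim`: `complexes` (an `mcia_complexes`),
#'   `truth` (`data.table`: `cid`, `origin` in
#'   intra_tad/noise/doublet/triplet/peak_bound, `tads`, `n_parts`,
#'   `cut_after` -- for multiplets, the comma-separated fragment indices
#'   after which the true junctions lie), `tads`, `peaks`, `coverage`
#'   (bedGraph `data.table`), `chrom_sizes`, `cfg`.
#' @export
simulate_dataset <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "mcia_sim_config"))
  with_seed(cfg$seed, {
    tads <- plant_tads(cfg)
    peaks <- plant_peaks(cfg)

    n_intra <- cfg$complexes_per_tad * nrow(tads)
    other_frac <- cfg$noise_fraction + cfg$multiplet_fraction +
      cfg$peak_bound_fraction
    M <- if (n_intra > 0) round(n_intra / (1 - other_frac)) else
      stopf("complexes_per_tad must be positive")
    n_noise <- round(M * cfg$noise_fraction)
    n_mult <- round(M * cfg$multiplet_fraction)
    n_peak <- round(M * cfg$peak_bound_fraction)
    if (n_peak > 0 && nrow(peaks) == 0L)
      stopf("peak_bound_fraction > 0 requires peaks")

    frag_list <- list()
    truth <- list()
    serial <- 0L
    new_id <- function() {
      serial <<- serial + 1L
      sprintf("C%06d", serial)
    }

    # --- intra-TAD singlets ---
    for (i in seq_len(n_intra)) {
      ti <- ((i - 1L) %% nrow(tads)) + 1L
      fr <- singlet_fragments(cfg, tads$start[ti], tads$end[ti])
      id <- new_id()
      frag_list[[id]] <- data.table(chrom = cfg$chrom, start = fr$start,
                                    end = fr$end, cid = id)
      truth[[id]] <- data.table(cid = id, origin = "intra_tad",
                                tads = tads$tad_id[ti], n_parts = 1L,
                                cut_after = NA_character_)
    }

    # --- uniform noise complexes ---
    for (i in seq_len(n_noise)) {
      nf <- max(2L, cfg$frags_per_complex(1L))
      lens <- frag_lengths(cfg, nf)
      st <- sort(round(runif(nf, 0, cfg$chrom_length - max(lens) - 1)))
      id <- new_id()
      frag_list[[id]] <- data.table(chrom = cfg$chrom, start = st,
                                    end = st + lens, cid = id)
      truth[[id]] <- data.table(cid = id, origin = "noise",
                                tads = NA_character_, n_parts = 1L,
                                cut_after = NA_character_)
    }

    # --- multiplets: concatenated independent singlets ---
    for (i in seq_len(n_mult)) {
      parts <- if (runif(1) < cfg$triplet_share) 3L else 2L
      parts <- min(parts, nrow(tads))
      tis <- sort(sample.int(nrow(tads), parts))  # distinct TADs, in order
      subs <- lapply(tis, function(ti)
        singlet_fragments(cfg, tads$start[ti], tads$end[ti]))
      id <- new_id()
      fr <- rbindlist(lapply(subs, function(s)
        data.table(chrom = cfg$chrom, start = s$start, end = s$end, cid = id)))
      sizes <- vapply(subs, function(s) length(s$start), integer(1))
      frag_list[[id]] <- fr
      truth[[id]] <- data.table(
        cid = id, origin = if (parts == 2L) "doublet" else "triplet",
        tads = paste(tads$tad_id[tis], collapse = ","), n_parts = parts,
        cut_after = paste(cumsum(sizes)[-parts], collapse = ","))
    }

    # --- peak-bound complexes ---
    for (i in seq_len(n_peak)) {
      nf <- max(2L, cfg$frags_per_complex(1L))
      lens <- frag_lengths(cfg, nf)
      pk <- sample.int(nrow(peaks), nf, replace = TRUE)
      if (nrow(peaks) >= 2L && length(unique(pk)) == 1L) {
        pk[1L] <- if (pk[2L] == 1L) 2L else 1L  # force two distinct peaks
      }
      lo <- -peaks$width[pk] / 2
      hi <- pmax(lo + 1, peaks$width[pk] / 2 - lens)
      st <- round(peaks$center[pk] + runif(nf, lo, hi))
      st <- pmax(0, pmin(st, cfg$chrom_length - lens - 1))
      o <- order(st)
      id <- new_id()
      frag_list[[id]] <- data.table(chrom = cfg$chrom, start = st[o],
                                    end = st[o] + lens[o], cid = id)
      truth[[id]] <- data.table(cid = id, origin = "peak_bound",
                                tads = NA_character_, n_parts = 1L,
                                cut_after = NA_character_)
    }

    coverage <- peak_coverage(cfg, peaks)
    cs <- stats::setNames(cfg$chrom_length, cfg$chrom)
    cplx <- as_complexes(rbindlist(frag_list), cs)
    truth <- rbindlist(truth)
    setorder(truth, cid)
    out <- structure(list(complexes = cplx, truth = truth, tads = tads,
                          peaks = peaks, coverage = coverage,
                          chrom_sizes = cs, cfg = cfg),
                     class = "mcia_sim")
  })
  if (!is.null(out_dir)) write_sim(out, out_dir)
  out
}

plant_tads <- function(cfg) {
  if (!is.null(cfg$tads)) {
    td <- as.data.table(cfg$tads)[order(start)]
    if (any(td$start[-1L] < td$end[-nrow(td)])) stopf("planted TADs overlap")
    if (max(td$end) > cfg$chrom_length) stopf("TAD beyond chromosome end")
    td[, tad_id := paste0("TAD_", cfg$chrom, "_", .I)]
    return(td[, .(chrom = cfg$chrom, start, end, tad_id)])
  }
  sizes <- round(runif(cfg$n_tads, cfg$tad_size_range[1], cfg$tad_size_range[2]))
  slack <- cfg$chrom_length - sum(sizes) - (cfg$n_tads + 1L) * cfg$min_tad_gap
  if (slack < 0) stopf("TADs do not fit the chromosome: reduce n_tads/sizes")
  w <- runif(cfg$n_tads + 1L)
  extra <- floor(slack * w / sum(w))
  gaps <- cfg$min_tad_gap + extra          # n_tads + 1 gaps incl. both ends
  starts <- cumsum(gaps[seq_len(cfg$n_tads)]) +
    cumsum(c(0, sizes[-cfg$n_tads]))
  data.table(chrom = cfg$chrom, start = starts, end = starts + sizes,
             tad_id = paste0("TAD_", cfg$chrom, "_", seq_len(cfg$n_tads)))
}

plant_peaks <- function(cfg) {
  if (!is.null(cfg$peaks)) return(as.data.table(cfg$peaks))
  if (cfg$n_peaks == 0L) {
    return(data.table(center = numeric(0), width = numeric(0),
                      height = numeric(0)))
  }
  margin <- 2 * cfg$peak_width
  data.table(center = round(runif(cfg$n_peaks, margin,
                                  cfg$chrom_length - margin)),
             width = cfg$peak_width, height = cfg$peak_height)
}

frag_lengths <- function(cfg, nf) {
  pmax(50, round(rnorm(nf, cfg$frag_len_mean, cfg$frag_len_sd)))
}

# One compact complex inside [tad_start, tad_end): log-uniform gaps.
singlet_fragments <- function(cfg, tad_start, tad_end) {
  nf <- max(2L, cfg$frags_per_complex(1L))
  lens <- frag_lengths(cfg, nf)
  gaps <- round(exp(runif(nf - 1L, log(cfg$gap_range[1]),
                          log(cfg$gap_range[2]))))
  span <- sum(lens) + sum(gaps)
  avail <- (tad_end - tad_start)
  if (sum(lens) >= avail) stopf("fragments larger than TAD: infeasible config")
  if (span > 0.9 * avail) {
    scale <- (0.9 * avail - sum(lens)) / sum(gaps)
    gaps <- pmax(1, floor(gaps * scale))
    span <- sum(lens) + sum(gaps)
  }
  s0 <- round(runif(1, tad_start, tad_end - span - 1))
  starts <- s0 + cumsum(c(0, lens[-nf] + gaps))
  list(start = starts, end = starts + lens)
}

# Baseline (with correlated lognormal background noise, emulating uneven
# chromatin accessibility and mappability) plus Gaussian binding peaks,
# rendered as a run-length bedGraph at 10 bp.
peak_coverage <- function(cfg, peaks, bin = 10) {
  nb <- as.integer(ceiling(cfg$chrom_length / bin))
  v <- rep(cfg$baseline, nb)
  if (cfg$baseline_noise_sd > 0) {
    bins_per_block <- max(1L, as.integer(cfg$noise_block / bin))
    nblk <- as.integer(ceiling(nb / bins_per_block))
    noise <- exp(rnorm(nblk, -cfg$baseline_noise_sd^2 / 2,
                       cfg$baseline_noise_sd))
    v <- v * rep(noise, each = bins_per_block)[seq_len(nb)]
  }
  if (nrow(peaks)) {
    mids <- (seq_len(nb) - 0.5) * bin
    for (i in seq_len(nrow(peaks))) {
      sdv <- peaks$width[i] / 4
      sel <- which(abs(mids - peaks$center[i]) < 4 * peaks$width[i])
      v[sel] <- v[sel] +
        peaks$height[i] * exp(-(mids[sel] - peaks$center[i])^2 / (2 * sdv^2))
    }
  }
  vr <- round(v, 3)
  r <- rle(vr)
  ends <- pmin(cumsum(r$lengths) * bin, cfg$chrom_length)
  starts <- c(0, ends[-length(ends)])
  data.table(chrom = cfg$chrom, start = starts, end = ends, value = r$values)
}

write_sim <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_complexes(sim$complexes, file.path(out_dir, "complexes.tsv"))
  fwrite(sim$truth, file.path(out_dir, "truth.tsv"), sep = "\t")
  fwrite(sim$coverage, file.path(out_dir, "coverage.bedgraph"), sep = "\t",
         col.names = FALSE, scipen = 50)
  writeLines(sprintf("%s\t%d", names(sim$chrom_sizes),
                     as.integer(sim$chrom_sizes)),
             file.path(out_dir, "chrom.sizes"))
  write_bed(sim$tads[, .(chrom, start, end, tad_id)],
            file.path(out_dir, "tads.bed"))
  invisible(out_dir)
}

#' @export
print.mcia_sim <- function(x, ...) {
  tb <- table(x$truth$origin)
  cat(sprintf("mcia simulation: %d complexes on %s (%g bp), %d TADs, %d peaks\n",
              nrow(x$truth), x$cfg$chrom, x$cfg$chrom_length, nrow(x$tads),
              nrow(x$peaks)))
  for (nm in names(tb)) cat(sprintf("  %-10s %d\n", nm, tb[[nm]]))
  invisible(x)
}
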