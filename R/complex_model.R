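#' Chromatin complex containers and distance primitives
#'
#' A "complex" is the set of genomic fragments sharing one barcode (a GEM in
#' ChIA-Drop, a cluster barcode in SPRITE). Complexes are stored as a plain
#' fragment table -- one row per fragment with columns `chrom`, `start`,
#' `end` (0-based half-open, BED convention) and `cid` (the barcode) --
#' wrapped together with the chromosome sizes in an S3 object of class
#' `mcia_complexes`.
#'
#' @name complexes
NULL

#' Build a complexes object from a fragment table
#'
#' Fragments are grouped by complex ID, sorted by position, and overlapping
#' or book-ended fragments within one complex are merged. IDs whose
#' fragments span several chromosomes are split into per-chromosome
#' sub-complexes (all downstream tests are intra-chromosomal) with a
#' deterministic `"/chrom"` suffix.
#'
#' @param fragments data.frame with columns `chrom`, `start`, `end`, `cid`.
#' @param chrom_sizes named numeric vector of chromosome lengths (bp), e.g.
#'   from [read_chrom_sizes()].
#' @return An object of class `mcia_complexes`: a list with elements
#'   `fragments` (a `data.table` keyed by `chrom`, `cid`, `start`) and
#'   `chrom_sizes`.
#' @export
as_complexes <- function(fragments, chrom_sizes) {
  fr <- as.data.table(fragments)[, .(chrom = as.character(chrom),
                                     start = as.numeric(start),
                                     end = as.numeric(end),
                                     cid = as.character(cid))]
  if (nrow(fr) == 0L) stopf("no fragments supplied")
  if (anyNA(fr)) stopf("fragment table contains missing values")
  if (any(fr$start >= fr$end)) {
    i <- which(fr$start >= fr$end)[1L]
    stopf("fragment %d has start >= end (%s:%g-%g)", i, fr$chrom[i],
          fr$start[i], fr$end[i])
  }
  if (any(fr$start < 0)) stopf("negative fragment start")
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  bad <- setdiff(unique(fr$chrom), names(chrom_sizes))
  if (length(bad)) stopf("chromosome(s) not in size map: %s",
                         paste(bad, collapse = ", "))
  over <- fr$end > chrom_sizes[fr$chrom]
  if (any(over)) {
    i <- which(over)[1L]
    stopf("fragment exceeds chromosome length: %s:%g-%g (size %g)",
          fr$chrom[i], fr$start[i], fr$end[i], chrom_sizes[fr$chrom[i]])
  }

  # split trans-chromosomal IDs deterministically
  nchr <- fr[, uniqueN(chrom), by = cid]
  multi <- nchr[V1 > 1L, cid]
  if (length(multi)) {
    fr[cid %in% multi, cid := paste(cid, chrom, sep = "/")]
  }

  # merge overlapping/book-ended fragments within a complex
  setorder(fr, chrom, cid, start, end)
  fr[, grp := {
    cme <- cummax(end)
    cumsum(c(TRUE, start[-1L] > cme[-length(cme)]))
  }, by = .(chrom, cid)]
  fr <- fr[, .(start = min(start), end = max(end)),
           by = .(chrom, cid, grp)][, grp := NULL]
  setkey(fr, chrom, cid, start)

  structure(list(fragments = fr[], chrom_sizes = chrom_sizes),
            class = "mcia_complexes")
}

validate_chrom_sizes <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stopf("chrom_sizes must be a named vector")
  cs <- as.numeric(chrom_sizes)
  names(cs) <- names(chrom_sizes)
  if (any(!is.finite(cs)) || any(cs <= 0)) stopf("chromosome sizes must be positive")
  cs
}

#' Read a two-column chrom.sizes file
#'
#' @param path path to a tab-delimited file with columns chromosome, length.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = list(character = 1))
  if (ncol(dt) < 2L) stopf("chrom.sizes file needs two columns: %s", path)
  validate_chrom_sizes(stats::setNames(as.numeric(dt[[2L]]), dt[[1L]]))
}

#' Read a complexes master file
#'
#' The master format is BED-like, one fragment per line, tab-delimited:
#' `chrom  start  end  complexID` with optional trailing columns (ignored on
#' input). Fragments are grouped into complexes by ID; see [as_complexes()]
#' for the normalization applied.
#'
#' @param path path to the complexes file.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @return An `mcia_complexes` object.
#' @export
read_complexes <- function(path, chrom_sizes) {
  dt <- tryCatch(
    fread(path, header = FALSE, sep = "\t", fill = TRUE,
          colClasses = list(character = 1)),
    error = function(e) stopf("cannot parse %s: %s", path, conditionMessage(e)))
  if (ncol(dt) < 4L) stopf("%s: expected >= 4 tab-delimited columns", path)
  st <- suppressWarnings(as.numeric(dt[[2L]]))
  en <- suppressWarnings(as.numeric(dt[[3L]]))
  bad <- which(is.na(st) | is.na(en) | !nzchar(dt[[1L]]) | is.na(dt[[4L]]))
  if (length(bad)) stopf("%s: malformed line %d", path, bad[1L])
  as_complexes(data.table(chrom = dt[[1L]], start = st, end = en,
                          cid = as.character(dt[[4L]])), chrom_sizes)
}

#' @export
print.mcia_complexes <- function(x, ...) {
  ct <- complex_table(x)
  cat(sprintf("mcia_complexes: %d complexes, %d fragments on %d chromosome(s)\n",
              nrow(ct), nrow(x$fragments), length(unique(ct$chrom))))
  cat(sprintf("  fragments per complex: %d-%d (median %g)\n",
              min(ct$n), max(ct$n), stats::median(ct$n)))
  invisible(x)
}

#' Per-complex summary table
#'
#' @param x an `mcia_complexes` object.
#' @return `data.table` with one row per complex: `cid`, `chrom`, `n`
#'   (fragment count), `span_start`, `span_end`.
#' @export
complex_table <- function(x) {
  stopifnot(inherits(x, "mcia_complexes"))
  x$fragments[, .(n = .N, span_start = min(start), span_end = max(end)),
              by = .(chrom, cid)]
}

#' Neighboring-distance profile of a complex
#'
#' For sorted, non-overlapping fragments the i-th fragment-to-fragment (F2F)
#' distance is `start(frag[i+1]) - end(frag[i])`, floored at 1 bp so the
#' probability vector is always well defined. `d_tot` is their sum and
#' `p_f2f = x_f2f / d_tot`.
#'
#' @param fragments data.frame of one complex's fragments (columns `start`,
#'   `end`), sorted by position, or an `mcia_complexes` with a single complex.
#' @return list with `x_f2f` (length n-1), `d_tot`, `p_f2f`. A single-fragment
#'   complex yields the empty profile (`x_f2f` of length 0, `d_tot = 0`).
#' @export
distance_profile <- function(fragments) {
  if (inherits(fragments, "mcia_complexes")) fragments <- fragments$fragments
  st <- as.numeric(fragments$start)
  en <- as.numeric(fragments$end)
  nf <- length(st)
  if (nf < 2L) {
    return(list(x_f2f = numeric(0), d_tot = 0, p_f2f = numeric(0)))
  }
  if (is.unsorted(st)) stopf("fragments must be sorted by start")
  x <- pmax(st[-1L] - en[-nf], 1)
  list(x_f2f = x, d_tot = sum(x), p_f2f = x / sum(x))
}

# Long table of F2F gaps for all complexes: cid, chrom, idx, gap.
f2f_gap_table <- function(x) {
  fr <- if (inherits(x, "mcia_complexes")) x$fragments else x
  fr[, if (.N >= 2L) .(idx = seq_len(.N - 1L),
                       gap = pmax(start[-1L] - end[-.N], 1)),
     by = .(chrom, cid)]
}

#' Write complexes in the master format
#'
#' One fragment per line: chrom, start, end, complexID, plus optional
#' annotation columns taken from `annot` (matched by `cid`).
#'
#' @param x an `mcia_complexes` object.
#' @param path output path.
#' @param annot optional data.frame with a `cid` column plus columns to
#'   append to every fragment line (e.g. category, adjusted p-value).
#' @return `path`, invisibly.
#' @export
write_complexes <- function(x, path, annot = NULL) {
  stopifnot(inherits(x, "mcia_complexes"))
  out <- copy(x$fragments)
  if (!is.null(annot)) {
    an <- as.data.table(annot)
    stopifnot("cid" %in% names(an))
    out <- an[out, on = "cid"]
    extra <- setdiff(names(an), "cid")
  } else {
    extra <- character(0)
  }
  setcolorder(out, c("chrom", "start", "end", "cid", extra))
  setorder(out, chrom, cid, start)
  fwrite(out, path, sep = "\t", col.names = FALSE, scipen = 50)
  invisible(path)
}

#' Write complexes as juicer .short pairwise contacts
#'
#' Each complex with n >= 2 fragments is expanded into all n(n-1)/2
#' unordered fragment pairs, one line per pair in juicer's 8-column short
#' format (`str1 chr1 pos1 frag1 str2 chr2 pos2 frag2`). Strands are fixed
#' to 0, restriction-fragment fields to 0 and 1, and positions are fragment
#' midpoints on the 1-based scale. Single-fragment complexes are skipped.
#'
#' @param x an `mcia_complexes` object.
#' @param path output path.
#' @return Number of pair lines written, invisibly.
#' @export
write_short <- function(x, path) {
  stopifnot(inherits(x, "mcia_complexes"))
  fr <- x$fragments[, .(chrom, start, end, cid)]
  fr <- fr[, if (.N >= 2L) .SD, by = .(chrom, cid)]
  if (nrow(fr) == 0L) {
    writeLines(character(0), path)
    return(invisible(0L))
  }
  fr[, mid := floor((start + end) / 2) + 1]
  pairs <- fr[, {
    ij <- which(upper.tri(diag(.N)), arr.ind = TRUE)
    .(p1 = mid[ij[, 1L]], p2 = mid[ij[, 2L]])
  }, by = .(chrom, cid)]
  out <- pairs[, .(str1 = 0L, chr1 = chrom, pos1 = p1, frag1 = 0L,
                   str2 = 0L, chr2 = chrom, pos2 = p2, frag2 = 1L)]
  fwrite(out, path, sep = "\t", col.names = FALSE, scipen = 50)
  invisible(nrow(out))
}

#' Write intervals as BED
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name` (any further columns are appended).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  dt <- as.data.table(intervals)
  stopifnot(all(c("chrom", "start", "end") %in% names(dt)))
  setcolorder(dt, c("chrom", "start", "end"))
  setorder(dt, chrom, start)
  fwrite(dt, path, sep = "\t", col.names = FALSE, scipen = 50)
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path path to a 4-column bedGraph (chrom, start, end, value).
#'   Intervals must be sorted and non-overlapping within each chromosome.
#' @return `data.table` with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t",
              colClasses = list(character = 1))
  if (ncol(dt) < 4L) stopf("%s: bedGraph needs 4 columns", path)
  setnames(dt, 1:4, c("chrom", "start", "end", "value"))
  dt <- dt[, .(chrom, start = as.numeric(start), end = as.numeric(end),
               value = as.numeric(value))]
  check_bedgraph(dt)
  dt
}

check_bedgraph <- function(dt) {
  if (any(dt$start >= dt$end)) stopf("bedGraph interval with start >= end")
  bad <- dt[order(chrom, start), any(start[-1L] < end[-.N]), by = chrom][V1 == TRUE]
  if (nrow(bad)) stopf("overlapping bedGraph intervals on %s", bad$chrom[1L])
  invisible(TRUE)
}
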