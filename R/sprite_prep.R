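#' Read a SPRITE clusters file
#'
#' The default dialect is one cluster per line: a barcode followed by
#' tab-separated read entries of the form `chrom:position`. Because cluster
#' file layouts vary between releases, the entry separator and the
#' chrom/position splitter are configurable.
#'
#' @param path path to the clusters text file.
#' @param sep field separator between barcode and read entries (default
#'   tab).
#' @param pos_sep separator between chromosome and position within an entry
#'   (default `":"`); the first two fields are used, so entries with extra
#'   `:`-separated annotation still parse.
#' @return `data.table` with columns `barcode`, `chrom`, `pos`, sorted by
#'   barcode and position within chromosome.
#' @export
read_sprite_clusters <- function(path, sep = "\t", pos_sep = ":") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("%s: empty clusters file", path)
  parts <- strsplit(lines, sep, fixed = TRUE)
  nread <- lengths(parts) - 1L
  if (any(nread < 1L)) stopf("%s: line %d has no read entries", path,
                             which(nread < 1L)[1L])
  bc <- rep(vapply(parts, `[[`, "", 1L), nread)
  entries <- unlist(lapply(parts, `[`, -1L), use.names = FALSE)
  ep <- strsplit(entries, pos_sep, fixed = TRUE)
  chroms <- vapply(ep, `[[`, "", 1L)
  pos <- suppressWarnings(as.numeric(vapply(ep, `[[`, "", 2L)))
  if (anyNA(pos)) stopf("%s: unparseable read position '%s'", path,
                        entries[which(is.na(pos))[1L]])
  dt <- data.table(barcode = bc, chrom = chroms, pos = pos)
  setorder(dt, barcode, chrom, pos)
  dt[]
}

#' Convert SPRITE clusters to chromatin complexes
#'
#' Pre-processing sweep: reads are restricted to `target_chrom`; within
#' each cluster a left-to-right pass drops any read closer than `min_sep`
#' to the previously retained read (greedy de-duplication of binned PCR
#' duplicates); survivors become fragments `[pos, pos + extend)`; clusters
#' with fewer than `min_frags` or more than `max_frags` surviving fragments
#' are dropped.
#'
#' @param clusters `data.table` from [read_sprite_clusters()] (columns
#'   `barcode`, `chrom`, `pos`).
#' @param target_chrom chromosome to keep (e.g. `"chr18"`).
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param extend fragment length added to each read position (default
#'   1000 bp).
#' @param min_sep minimum distance to the previously retained read (default
#'   10,000 bp).
#' @param min_frags,max_frags retained-fragment bounds per cluster
#'   (defaults 2 and 500).
#' @return An `mcia_complexes` object.
#' @export
clusters_to_complexes <- function(clusters, target_chrom, chrom_sizes,
                                  extend = 1000, min_sep = 10000,
                                  min_frags = 2L, max_frags = 500L) {
  cl <- as.data.table(clusters)[chrom == target_chrom]
  if (nrow(cl) == 0L) stopf("no reads on %s", target_chrom)
  setorder(cl, barcode, pos)
  cl[, keep := greedy_min_sep(pos, min_sep), by = barcode]
  cl <- cl[keep == TRUE]
  cl <- cl[, if (.N >= min_frags && .N <= max_frags) .SD, by = barcode]
  if (nrow(cl) == 0L) stopf("no cluster satisfies the fragment bounds")
  len <- validate_chrom_sizes(chrom_sizes)[[target_chrom]]
  as_complexes(data.table(chrom = target_chrom,
                          start = cl$pos,
                          end = pmin(cl$pos + extend, len),
                          cid = cl$barcode),
               chrom_sizes)
}

# Greedy sweep: keep a read iff it is >= min_sep from the last KEPT read.
greedy_min_sep <- function(pos, min_sep) {
  keep <- logical(length(pos))
  last <- -Inf
  for (i in seq_along(pos)) {
    if (pos[i] - last >= min_sep) {
      keep[i] <- TRUE
      last <- pos[i]
    }
  }
  keep
}
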