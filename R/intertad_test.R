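#' TAD set contacted by a complex
#'
#' A fragment is assigned to a TAD when its midpoint lies inside; the
#' complex's TAD combination is the set of TADs containing at least
#' `min_frags` of its fragments.
#'
#' @param fragments fragment table of one complex (columns `chrom`, `start`,
#'   `end`).
#' @param tads TAD table: `chrom`, `start`, `end`, `tad_id` (disjoint
#'   intervals), e.g. the `tads` element of [call_tads()] restricted to
#'   `kind == "TAD"`.
#' @param min_frags minimum fragments per TAD (default 2).
#' @return Character vector of TAD IDs (possibly empty), sorted.
#' @export
complex_tad_set <- function(fragments, tads, min_frags = 2L) {
  fr <- as.data.table(fragments)
  hits <- assign_tads(fr, tads)
  tab <- table(hits[!is.na(hits)])
  sort(as.character(names(tab))[tab >= min_frags])
}

# Midpoint-in-interval TAD assignment; returns tad_id per fragment (NA in gaps).
assign_tads <- function(fr, tads) {
  td <- as.data.table(tads)
  if ("kind" %in% names(td)) td <- td[kind == "TAD"]
  stopifnot(all(c("chrom", "start", "end", "tad_id") %in% names(td)))
  out <- rep(NA_character_, nrow(fr))
  for (ch in unique(fr$chrom)) {
    ti <- td[chrom == ch][order(start)]
    if (nrow(ti) == 0L) next
    sel <- which(fr$chrom == ch)
    mids <- floor((fr$start[sel] + fr$end[sel]) / 2)
    k <- findInterval(mids, ti$start)
    inside <- k >= 1L & mids < ti$end[pmax(k, 1L)]
    out[sel[inside]] <- ti$tad_id[k[inside]]
  }
  out
}

#' Expanded-pair statistics for TAD combinations
#'
#' Combinations are grouped into classes `G_j` by the number of TADs
#' involved. For a combination `TC_i` of size N with pair set `Pa(TC_i)`
#' (all N(N-1)/2 TAD pairs):
#' \describe{
#'   \item{a}{occurrence-weighted number of pairs shared with same-class
#'     combinations, `sum over y in G_N of mult(y) * |Pa(y) n Pa(TC_i)|`
#'     (includes `TC_i`'s own pairs);}
#'   \item{b}{occurrence-weighted number of higher-class combinations that
#'     strictly contain `TC_i`;}
#'   \item{x}{`a + b * N(N-1)/2`, the expanded-pair count crediting each
#'     containing combination with a full pair set;}
#'   \item{k}{`sum of x over the class`, the shared trial count.}
#' }
#'
#' @param combos data.frame with columns `combo` (comma-separated sorted
#'   TAD IDs) and `occurrences` (complex count, default 1).
#' @return `data.table` with `combo`, `N_tads`, `occurrences`, `a`, `b`,
#'   `x`, `k`, `class_size` (number of distinct combinations in the class).
#' @export
expanded_pair_stats <- function(combos) {
  dt <- as.data.table(combos)
  stopifnot("combo" %in% names(dt))
  if (!"occurrences" %in% names(dt)) dt[, occurrences := 1L]
  dt <- dt[, .(occurrences = sum(occurrences)), by = combo]
  members <- lapply(strsplit(dt$combo, ",", fixed = TRUE),
                    function(m) sort(unique(m)))
  dt[, N_tads := lengths(members)]
  if (any(dt$N_tads < 2L)) stopf("combinations must involve >= 2 TADs")

  pair_sets <- lapply(members, function(m) {
    ij <- utils::combn(m, 2L)
    paste(ij[1L, ], ij[2L, ], sep = "|")
  })

  dt[, `:=`(a = 0, b = 0)]
  for (j in sort(unique(dt$N_tads))) {
    idx <- which(dt$N_tads == j)
    # occurrence-weighted multiplicity of every pair within the class
    pool <- unlist(pair_sets[idx], use.names = FALSE)
    wts <- rep(dt$occurrences[idx], each = j * (j - 1L) / 2L)
    cnt <- rowsum(wts, pool)
    pair_count <- stats::setNames(cnt[, 1L], rownames(cnt))
    for (i in idx) {
      dt$a[i] <- sum(pair_count[pair_sets[[i]]], na.rm = TRUE)
    }
  }
  # strict-superset counts across higher classes
  for (i in seq_len(nrow(dt))) {
    mi <- members[[i]]
    sup <- which(dt$N_tads > dt$N_tads[i])
    if (length(sup)) {
      contains <- vapply(sup, function(s) all(mi %in% members[[s]]), logical(1))
      dt$b[i] <- sum(dt$occurrences[sup[contains]])
    }
  }
  dt[, x := a + b * N_tads * (N_tads - 1L) / 2]
  dt[, `:=`(k = sum(x), class_size = .N), by = N_tads]
  dt[]
}

#' One-sided binomial test for a TAD combination
#'
#' Tests whether the expanded-pair count `x` of a combination is larger
#' than expected if the `k` class trials were distributed uniformly over
#' the `class_size` combinations of its class (success probability
#' `1/class_size`); the alternative is "greater".
#'
#' @param x number of successes (expanded-pair count).
#' @param k number of trials (class-wise sum of x).
#' @param class_size number of distinct combinations in the class.
#' @return Exact upper-tail probability `P(X >= x | k, 1/class_size)`;
#'   `1` when `k = 0`.
#' @export
binomial_combo_test <- function(x, k, class_size) {
  stopifnot(all(x >= 0), all(x <= k | k == 0), all(class_size >= 1))
  p0 <- 1 / class_size
  out <- stats::pbinom(x - 1, size = k, prob = p0, lower.tail = FALSE)
  out[k == 0] <- 1
  out
}

#' Inter-TAD binomial test
#'
#' Maps every complex to its TAD combination ([complex_tad_set()]), counts
#' combination occurrences across complexes, computes expanded-pair
#' statistics ([expanded_pair_stats()]) and assigns each combination an
#' exact one-sided binomial p-value ([binomial_combo_test()]), BH-adjusted
#' across all tested combinations.
#'
#' @param x an `mcia_complexes` object (typically significant complexes).
#' @param tads TAD table as in [complex_tad_set()], or an `mcia_tads`
#'   result.
#' @param fdr false-discovery rate (default 0.1).
#' @param min_frags minimum fragments per TAD for membership (default 2).
#' @return `data.table` with one row per combination involving >= 2 TADs:
#'   `combo`, `N_tads`, `occurrences`, `a`, `b`, `x`, `k`, `class_size`,
#'   `raw_p`, `adj_p`, `significant`.
#' @export
run_intertad_test <- function(x, tads, fdr = 0.1, min_frags = 2L) {
  stopifnot(inherits(x, "mcia_complexes"))
  if (inherits(tads, "mcia_tads")) tads <- tads$tads
  fr <- x$fragments
  hits <- data.table(cid = fr$cid, tad = assign_tads(fr, tads))
  combo_dt <- hits[!is.na(tad), .(cnt = .N), by = .(cid, tad)][cnt >= min_frags]
  combos <- combo_dt[, .(combo = paste(sort(tad), collapse = ","),
                         N = uniqueN(tad)), by = cid][N >= 2L]
  if (nrow(combos) == 0L) {
    warnf("no complex touches >= 2 TADs with >= %d fragments", min_frags)
    return(data.table(combo = character(0), N_tads = integer(0),
                      occurrences = integer(0), a = numeric(0), b = numeric(0),
                      x = numeric(0), k = numeric(0), class_size = integer(0),
                      raw_p = numeric(0), adj_p = numeric(0),
                      significant = logical(0)))
  }
  tab <- combos[, .(occurrences = .N), by = combo]
  st <- expanded_pair_stats(tab)
  st[, raw_p := binomial_combo_test(x, k, class_size)]
  st[, adj_p := stats::p.adjust(raw_p, method = "BH")]
  st[, significant := adj_p <= fdr]
  setorder(st, adj_p, combo)
  st[]
}
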