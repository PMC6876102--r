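#' Distance-test configuration
#'
#' Parameters for the two-stage resampling distance test and its entropy
#' filter.
#'
#' @param fdr false-discovery rate for the Benjamini-Hochberg step (default
#'   0.1).
#' @param tau second-cut ratio: when a complex is split, a cut is also made
#'   at the second-largest gap if it is at least `max/tau` (default 2).
#' @param sample_size number of expected complexes drawn per fragment class
#'   when building the empirical null (default 100,000).
#' @param seed integer RNG seed; every (chromosome, class) stratum derives
#'   its own sub-seed from it, so results are reproducible and independent
#'   of iteration order.
#' @param max_frags_fail optional fragment-count cap: insignificant
#'   complexes with more fragments are sent straight to `fail1` (used for
#'   SPRITE data, where the cap is 100).
#' @param min_complexes minimum number of testable complexes required on a
#'   chromosome; chromosomes below the floor are skipped with a warning.
#' @return list of class `mcia_dist_config`.
#' @export
distance_test_config <- function(fdr = 0.1, tau = 2, sample_size = 100000L,
                                 seed = 1L, max_frags_fail = NULL,
                                 min_complexes = 20L) {
  stopifnot(fdr > 0, fdr < 1, tau >= 1, sample_size >= 1000, is_count(seed))
  structure(list(fdr = fdr, tau = tau, sample_size = as.integer(sample_size),
                 seed = as.integer(seed),
                 max_frags_fail = if (is.null(max_frags_fail)) NULL
                                  else as.integer(max_frags_fail),
                 min_complexes = as.integer(min_complexes)),
            class = "mcia_dist_config")
}

#' Normalized Shannon entropy of a probability vector
#'
#' `H_norm(p) = sum(p_i * log2(1/p_i)) / log2(length(p))`, with the
#' convention `0 * log2(1/0) = 0`. Values lie in `[0, 1]`: 1 for the uniform
#' vector (evenly spaced fragments), near 0 when a single gap dominates (the
#' multiplet signature).
#'
#' @param p numeric probability vector (entries >= 0 summing to 1). For a
#'   complex with n fragments this is `p_f2f`, of length n - 1.
#' @return `H_norm` in `[0, 1]`, or `NA_real_` when `length(p) < 2` (a
#'   two-fragment complex has a single gap and its entropy is undefined).
#' @export
normalized_entropy <- function(p) {
  if (length(p) < 2L) return(NA_real_)
  if (any(p < 0)) stopf("probability vector has negative entries")
  if (abs(sum(p) - 1) > 1e-6) stopf("probability vector does not sum to 1")
  nz <- p > 0
  -sum(p[nz] * log2(p[nz])) / log2(length(p))
}

# Vectorized H_norm over the columns of a (k x m) matrix of distances.
col_entropy <- function(mat) {
  k <- nrow(mat)
  tot <- colSums(mat)
  p <- sweep(mat, 2L, tot, "/")
  pl <- p * log2(p)
  pl[p == 0] <- 0
  -colSums(pl) / log2(k)
}

#' Build the per-class empirical null for one chromosome
#'
#' All observed F2F distances on the chromosome are pooled into a bucket
#' `B`; for each fragment class `F_j` present, `sample_size` expected
#' complexes are generated by drawing `j - 1` distances i.i.d. with
#' replacement from `B`. Only each expected complex's total distance and the
#' class mean normalized Shannon entropy (for j >= 3) are retained.
#'
#' @param x an `mcia_complexes` object or a fragment `data.table`.
#' @param cfg a [distance_test_config()].
#' @param chrom chromosome to build the null for; defaults to the single
#'   chromosome present.
#' @param classes integer vector of fragment classes j to build; defaults to
#'   all classes observed among complexes with n >= 2.
#' @return list of class `mcia_null` with elements `chrom`, `bucket` (the
#'   pooled distances) and `classes`, a named list mapping `j` to a list
#'   with `j`, `d_tot_samples` (sorted), `mean_entropy` (`NA` for j = 2) and
#'   `sample_size`.
#' @export
build_null <- function(x, cfg = distance_test_config(), chrom = NULL,
                       classes = NULL) {
  fr <- if (inherits(x, "mcia_complexes")) x$fragments else as.data.table(x)
  if (is.null(chrom)) {
    chrom <- unique(fr$chrom)
    if (length(chrom) != 1L) stopf("specify `chrom`: several present")
  }
  fr <- fr[fr$chrom == chrom]
  gaps <- f2f_gap_table(fr)
  if (nrow(gaps) == 0L) stopf("no complex with >= 2 fragments on %s: empty bucket", chrom)
  if (is.null(classes)) {
    classes <- sort(unique(fr[, .N, by = cid][N >= 2L, N]))
  }
  nulls <- structure(list(chrom = chrom, bucket = gaps$gap,
                          cfg = cfg, classes = list()),
                     class = "mcia_null")
  for (j in classes) nulls <- add_null_class(nulls, as.integer(j))
  nulls
}

# Sample one class's null (chunked so memory stays bounded for large j).
add_null_class <- function(nulls, j) {
  key <- as.character(j)
  if (!is.null(nulls$classes[[key]])) return(nulls)
  cfg <- nulls$cfg
  k <- j - 1L
  ss <- cfg$sample_size
  B <- nulls$bucket
  d_tot <- numeric(ss)
  ent_sum <- 0
  with_seed(derive_seed(cfg$seed, nulls$chrom, j), {
    done <- 0L
    chunk <- max(1L, min(ss, as.integer(2e6 / k)))
    while (done < ss) {
      m <- min(chunk, ss - done)
      draws <- matrix(B[sample.int(length(B), k * m, replace = TRUE)],
                      nrow = k)
      d_tot[(done + 1L):(done + m)] <- if (k == 1L) draws[1L, ] else colSums(draws)
      if (k >= 2L) ent_sum <- ent_sum + sum(col_entropy(draws))
      done <- done + m
    }
  })
  nulls$classes[[key]] <- list(j = j, d_tot_samples = sort(d_tot),
                               mean_entropy = if (k >= 2L) ent_sum / ss else NA_real_,
                               sample_size = ss)
  nulls
}

#' Raw resampling p-value of an observed total distance
#'
#' The proportion of expected complexes in the class null whose total
#' distance is strictly smaller than the observed total distance. Small
#' p-values therefore correspond to unusually compact complexes.
#'
#' @param d_tot_obs numeric vector of observed total F2F distances.
#' @param null one class entry of an [build_null()] result (list with sorted
#'   `d_tot_samples` and `sample_size`).
#' @return numeric vector of raw p-values in `[0, 1]`.
#' @export
raw_pvalue <- function(d_tot_obs, null) {
  s <- null$d_tot_samples
  findInterval(d_tot_obs, s, left.open = TRUE) / null$sample_size
}

#' Benjamini-Hochberg adjustment with a significance mask
#'
#' @param pvals numeric vector of raw p-values.
#' @param fdr false-discovery rate.
#' @return list with `adj_p` (BH step-up adjusted p-values) and
#'   `significant` (`adj_p <= fdr`).
#' @export
bh_adjust <- function(pvals, fdr = 0.1) {
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adj_p = adj, significant = adj <= fdr)
}

#' Split a complex at its dominating gap(s)
#'
#' If the complex's normalized entropy is below `threshold` it is cut at the
#' largest F2F gap (left-most on ties); additionally at the second-largest
#' gap when that gap is at least `max/tau` (a triplet signature). Otherwise
#' the complex is returned unchanged.
#'
#' @param fragments sorted fragment table of one complex (columns `chrom`,
#'   `start`, `end`, `cid`), n >= 3.
#' @param threshold entropy threshold, normally the class mean entropy of
#'   the expected null (see [build_null()]).
#' @param tau second-cut ratio (see [distance_test_config()]).
#' @return list of 1-3 fragment `data.table`s ordered by position. When
#'   split, sub-complex IDs get deterministic suffixes `.1`, `.2`, `.3` and
#'   the cut gap indices are attached as `attr(, "cuts")`.
#' @export
entropy_split <- function(fragments, threshold, tau = 2) {
  fr <- as.data.table(fragments)
  if (nrow(fr) < 3L) stopf("entropy_split needs n >= 3 fragments")
  prof <- distance_profile(fr)
  H <- normalized_entropy(prof$p_f2f)
  if (H >= threshold) {
    return(structure(list(fr), cuts = integer(0), entropy = H))
  }
  cuts <- split_cuts(prof$x_f2f, tau)
  parts <- split_at(fr, cuts)
  structure(parts, cuts = cuts, entropy = H)
}

# Cut positions (gap indices) for a below-threshold complex.
split_cuts <- function(x, tau) {
  s1 <- which.max(x)                      # left-most maximal gap
  cuts <- s1
  if (length(x) >= 2L) {
    rest <- x
    rest[s1] <- -Inf
    s2 <- which.max(rest)
    if (x[s2] >= x[s1] / tau) cuts <- sort(c(s1, s2))
  }
  cuts
}

split_at <- function(fr, cuts) {
  bounds <- c(0L, cuts, nrow(fr))
  lapply(seq_len(length(bounds) - 1L), function(i) {
    part <- fr[(bounds[i] + 1L):bounds[i + 1L]]
    part[, cid := paste0(cid, ".", i)]
    part
  })
}

#' Two-stage distance test with entropy filtering
#'
#' Runs, separately for each chromosome: (1) the first resampling distance
#' test with BH adjustment per fragment class (`pass1` / `fail1` / `defer`),
#' (2) the entropy filter on deferred complexes, splitting suspected
#' doublets and triplets at their dominating gaps, and (3) the second
#' distance test on the filtered set (`pass2` / `fail2`). Significant
#' complexes are `pass1` and `pass2`.
#'
#' @param x an `mcia_complexes` object.
#' @param cfg a [distance_test_config()].
#' @return list of class `mcia_dist_result`:
#'   \describe{
#'   \item{master}{`data.table` with one row per final complex unit: `cid`,
#'     `chrom`, `n`, `d_tot`, `entropy`, `raw_p`, `adj_p`, `category`
#'     (pass1/fail1/pass2/fail2/singleton/unassigned), `parent` (the original
#'     complex ID for split sub-complexes, else `NA`) and `stage` (1 or 2).}
#'   \item{complexes}{`mcia_complexes` holding the fragments of every final
#'     unit (split sub-complexes carry their suffixed IDs).}
#'   \item{summary}{per-step counts: tested, pass1, fail1, defer, split
#'     singlets/doublets/triplets, pass2, fail2, singleton.}
#'   \item{cfg}{the configuration used.}
#'   }
#' @export
run_distance_test <- function(x, cfg = distance_test_config()) {
  stopifnot(inherits(x, "mcia_complexes"), inherits(cfg, "mcia_dist_config"))
  ct <- complex_table(x)
  chroms <- sort(unique(ct$chrom))
  masters <- list()
  frag_out <- list()
  splits <- c(singlets = 0L, doublets = 0L, triplets = 0L)
  for (ch in chroms) {
    res <- dist_test_chrom(x$fragments[chrom == ch], cfg, ch)
    masters[[ch]] <- res$master
    frag_out[[ch]] <- res$fragments
    ss <- attr(res$master, "split_stats")
    if (!is.null(ss)) splits <- splits + ss
  }
  master <- rbindlist(masters)
  setorder(master, chrom, cid)
  fr <- rbindlist(frag_out)
  out_cplx <- structure(list(fragments = setkey(fr, chrom, cid, start)[],
                             chrom_sizes = x$chrom_sizes),
                        class = "mcia_complexes")
  structure(list(master = master, complexes = out_cplx,
                 summary = c(summarize_dist(master), splits), cfg = cfg),
            class = "mcia_dist_result")
}

dist_test_chrom <- function(fr, cfg, ch) {
  ct <- fr[, .(n = .N), by = cid]
  gaps <- f2f_gap_table(fr)
  testable <- ct[n >= 2L]
  empty_master <- function(cat) {
    data.table(cid = ct$cid, chrom = ch, n = ct$n, d_tot = NA_real_,
               entropy = NA_real_, raw_p = NA_real_, adj_p = NA_real_,
               category = cat, parent = NA_character_, stage = 0L)
  }
  if (nrow(testable) < cfg$min_complexes) {
    warnf("chromosome %s has %d testable complexes (< %d): skipped",
          ch, nrow(testable), cfg$min_complexes)
    return(list(master = empty_master("unassigned"), fragments = copy(fr)))
  }

  nulls <- build_null(fr, cfg, chrom = ch)

  # ---- first distance test, BH per fragment class ----
  obs <- gaps[, .(d_tot = sum(gap)), by = cid][ct, on = "cid"]
  obs[, entropy := NA_real_]
  ge3 <- gaps[cid %in% ct[n >= 3L, cid]]
  if (nrow(ge3)) {
    H <- ge3[, .(entropy = {
      p <- gap / sum(gap)
      -sum(ifelse(p > 0, p * log2(p), 0)) / log2(.N)
    }), by = cid]
    obs[H, entropy := i.entropy, on = "cid"]
  }
  obs[, `:=`(raw_p = NA_real_, adj_p = NA_real_)]
  for (j in sort(unique(obs[n >= 2L, n]))) {
    nul <- nulls$classes[[as.character(j)]]
    sel <- obs$n == j
    obs[sel, raw_p := raw_pvalue(d_tot, nul)]
    obs[sel, adj_p := stats::p.adjust(raw_p, method = "BH")]
  }
  frag_cap <- if (is.null(cfg$max_frags_fail)) Inf else cfg$max_frags_fail
  obs[, category := fcase(
    n < 2L, "singleton",
    adj_p <= cfg$fdr, "pass1",
    n == 2L, "fail1",
    n > frag_cap, "fail1",
    default = "defer")]
  obs[, `:=`(parent = NA_character_, stage = fifelse(n >= 2L, 1L, 0L))]

  # ---- entropy filter on the deferred pool ----
  defer_ids <- obs[category == "defer", cid]
  defer_frags <- if (length(defer_ids)) split(fr[cid %in% defer_ids], by = "cid")
                 else list()
  nmap <- stats::setNames(obs$n, obs$cid)
  split_units <- vector("list", length(defer_ids))  # second-test pool
  lineage <- vector("list", length(defer_ids))
  names(split_units) <- names(lineage) <- defer_ids
  for (id in defer_ids) {
    j <- nmap[[id]]
    thr <- nulls$classes[[as.character(j)]]$mean_entropy
    parts <- entropy_split(defer_frags[[id]], thr, cfg$tau)
    if (length(parts) == 1L) {
      # unchanged: the complex itself is retested
      split_units[[id]] <- defer_frags[[id]]
      lineage[[id]] <- data.table(cid = id, parent = NA_character_,
                                  n_parts = 1L)
    } else {
      sub <- rbindlist(parts)
      split_units[[id]] <- sub
      lineage[[id]] <- data.table(cid = sapply(parts, function(p) p$cid[1L]),
                                  parent = id,
                                  n_parts = length(parts))
    }
  }
  lin <- rbindlist(lineage)
  pool <- rbindlist(split_units)

  master <- obs[category != "defer",
                .(cid, chrom = ch, n, d_tot, entropy, raw_p, adj_p, category,
                  parent, stage)]

  n_singlet_parents <- if (nrow(lin)) sum(lin[is.na(parent), n_parts == 1L]) else 0L
  n_doublets <- if (nrow(lin)) uniqueN(lin[n_parts == 2L, parent]) else 0L
  n_triplets <- if (nrow(lin)) uniqueN(lin[n_parts == 3L, parent]) else 0L

  # ---- second distance test on the filtered pool ----
  if (nrow(lin)) {
    ct2 <- pool[, .(n = .N), by = cid][lin[, .(cid, parent)], on = "cid"]
    gaps2 <- f2f_gap_table(pool)
    obs2 <- gaps2[, .(d_tot = sum(gap)), by = cid][ct2, on = "cid"]
    ent2 <- gaps2[cid %in% ct2[n >= 3L, cid],
                  .(entropy = {
                    p <- gap / sum(gap)
                    -sum(ifelse(p > 0, p * log2(p), 0)) / log2(.N)
                  }), by = cid]
    obs2[, entropy := NA_real_]
    if (nrow(ent2)) obs2[ent2, entropy := i.entropy, on = "cid"]
    obs2[, `:=`(raw_p = NA_real_, adj_p = NA_real_)]
    for (j in sort(unique(obs2[n >= 2L, n]))) {
      nulls <- add_null_class(nulls, as.integer(j))   # on-demand classes
      nul <- nulls$classes[[as.character(j)]]
      sel <- which(obs2$n == j)
      obs2[sel, raw_p := raw_pvalue(d_tot, nul)]
      obs2[sel, adj_p := stats::p.adjust(raw_p, method = "BH")]
    }
    obs2[, category := fcase(
      n < 2L, "singleton",
      adj_p <= cfg$fdr, "pass2",
      default = "fail2")]
    obs2[, stage := fifelse(n >= 2L, 2L, 0L)]
    master <- rbind(master,
                    obs2[, .(cid, chrom = ch, n, d_tot, entropy, raw_p,
                             adj_p, category, parent, stage)])
  }

  attr(master, "split_stats") <- c(singlets = n_singlet_parents,
                                   doublets = n_doublets,
                                   triplets = n_triplets)

  final_ids <- master$cid
  frags <- rbind(fr[cid %in% final_ids],
                 if (nrow(lin)) pool[cid %in% final_ids] else NULL)
  frags <- unique(frags)
  list(master = master, fragments = frags)
}

summarize_dist <- function(master) {
  cats <- c("pass1", "fail1", "pass2", "fail2", "singleton", "unassigned")
  counts <- sapply(cats, function(cc) sum(master$category == cc))
  c(counts, significant = sum(master$category %in% c("pass1", "pass2")))
}

#' Extract the significant complexes from a distance-test result
#'
#' @param result an `mcia_dist_result` from [run_distance_test()], or an
#'   enrichment result from [run_enrichment_test()].
#' @return An `mcia_complexes` object restricted to significant complexes
#'   (`pass1`/`pass2`, or `pass` for the enrichment test).
#' @export
significant_complexes <- function(result) {
  keep <- result$master[category %in% c("pass1", "pass2", "pass"), cid]
  structure(list(fragments = result$complexes$fragments[cid %in% keep],
                 chrom_sizes = result$complexes$chrom_sizes),
            class = "mcia_complexes")
}

#' @export
print.mcia_dist_result <- function(x, ...) {
  cat("mcia distance test\n")
  s <- x$summary
  for (nm in names(s)) cat(sprintf("  %-12s %d\n", nm, s[[nm]]))
  invisible(x)
}
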