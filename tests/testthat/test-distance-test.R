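cfg_fast <- distance_test_config(sample_size = 20000L, seed = 7L,
                                 min_complexes = 1L)

test_that("null construction matches i.i.d. resampling expectations", {
  # bucket B = {500, 4500} from the worked-example complex; an expected
  # complex of class 3 sums two draws, so E[d_tot] = 2 * mean(B) = 5000
  x <- as_complexes(oc8(), toy_sizes)
  nulls <- build_null(x, cfg_fast)
  expect_identical(sort(unique(nulls$bucket)), c(500, 4500))
  n3 <- nulls$classes[["3"]]
  expect_length(n3$d_tot_samples, 20000L)
  expect_true(all(n3$d_tot_samples %in% c(1000, 5000, 9000)))
  expect_equal(mean(n3$d_tot_samples), 5000, tolerance = 0.03)
  # identical seeds give identical samples
  nulls2 <- build_null(x, cfg_fast)
  expect_identical(n3$d_tot_samples, nulls2$classes[["3"]]$d_tot_samples)
})

test_that("a singleton bucket yields degenerate nulls with entropy one", {
  x <- as_complexes(frags(c(0, 1200), c(500, 1700), cid = "P"), toy_sizes)
  nulls <- build_null(x, cfg_fast, classes = c(3L, 4L))
  expect_true(all(nulls$classes[["3"]]$d_tot_samples == 2 * 700))
  expect_true(all(nulls$classes[["4"]]$d_tot_samples == 3 * 700))
  expect_equal(nulls$classes[["3"]]$mean_entropy, 1)
  expect_equal(nulls$classes[["4"]]$mean_entropy, 1)
  # class 2 nulls have no defined entropy
  nulls2 <- build_null(x, cfg_fast, classes = 2L)
  expect_true(is.na(nulls2$classes[["2"]]$mean_entropy))
})

test_that("raw p-value is the proportion of strictly smaller null totals", {
  null <- list(d_tot_samples = sort(c(1, 2, 3, 4, 10)), sample_size = 5L)
  expect_equal(raw_pvalue(5, null), 0.8)
  expect_equal(raw_pvalue(0.5, null), 0)
  expect_equal(raw_pvalue(11, null), 1)
  # equality is not "smaller"
  expect_equal(raw_pvalue(3, null), 0.4)
  null2 <- list(d_tot_samples = c(1, 2, 2, 3), sample_size = 4L)
  expect_equal(raw_pvalue(2, null2), 0.25)
  # monotone non-decreasing in the observed distance
  obs <- sort(runif(50, 0, 12))
  expect_false(is.unsorted(raw_pvalue(obs, null)))
})

test_that("BH adjustment matches the hand oracle and edge cases", {
  r <- bh_adjust(c(0.01, 0.02, 0.03, 0.5), fdr = 0.1)
  expect_equal(r$adj_p, c(0.04, 0.04, 0.04, 0.5))
  expect_identical(r$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(bh_adjust(0.07)$adj_p, 0.07)
  expect_equal(bh_adjust(rep(0.3, 6))$adj_p, rep(0.3, 6))
})

test_that("BH significance mask equals an exhaustive step-up oracle", {
  set.seed(11)
  for (rep in 1:1000) {
    m <- sample(1:20, 1)
    p <- round(runif(m), 3)  # rounding provokes ties
    alpha <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    expect_identical(bh_adjust(p, alpha)$significant,
                     bh_mask_oracle(p, alpha))
  }
})

test_that("normalized entropy matches hand-computed values and bounds", {
  expect_equal(normalized_entropy(c(0.1, 0.9)),
               (0.1 * log2(10) + 0.9 * log2(10 / 9)) / log2(2))
  expect_equal(normalized_entropy(c(0.1, 0.9)), 0.469, tolerance = 1e-3)
  expect_equal(normalized_entropy(c(0.5, 0.5)), 1)
  expect_equal(normalized_entropy(rep(1 / 3, 3)), 1)
  expect_equal(normalized_entropy(c(1, 0)), 0)
  # undefined for a single-gap (two-fragment) profile
  expect_true(is.na(normalized_entropy(1)))
  expect_error(normalized_entropy(c(0.6, 0.6)), "sum")
})

test_that("entropy stays in [0,1], is 1 only at uniform, falls as one gap dominates", {
  set.seed(5)
  for (i in 1:1000) {
    k <- sample(2:10, 1)
    p <- runif(k)
    p <- p / sum(p)
    H <- normalized_entropy(p)
    expect_true(H >= 0 && H <= 1 + 1e-12)
  }
  # monotone decrease as a single component takes over
  w <- seq(0.5, 0.99, by = 0.07)
  H <- vapply(w, function(z) normalized_entropy(c(z, rep((1 - z) / 4, 4))),
              numeric(1))
  expect_false(is.unsorted(rev(H)))
})

test_that("entropy filter splits at the dominating gap(s)", {
  # H = 0.469 < 0.7: one cut at the larger gap -> {f1,f2} and {f3}
  parts <- entropy_split(oc8(), threshold = 0.7, tau = 2)
  expect_length(parts, 2L)
  expect_identical(attr(parts, "cuts"), 2L)
  expect_equal(nrow(parts[[1]]), 2L)
  expect_equal(parts[[2]]$start, 6000)
  expect_identical(parts[[1]]$cid[1], "OC8.1")
  # second cut not taken: 500 < 4500 / 2
  # equally spaced complex is left alone
  even <- frags(c(0, 2000, 4000), c(1000, 3000, 5000))
  expect_length(entropy_split(even, threshold = 0.7), 1L)
  # gaps [4000, 100, 4500] with tau = 2: both cuts (4000 >= 4500/2)
  tri <- frags(c(0, 4100, 4300, 8900), c(100, 4200, 4400, 9000))
  expect_lt(normalized_entropy(distance_profile(tri)$p_f2f), 0.8)
  parts3 <- entropy_split(tri, threshold = 0.8, tau = 2)
  expect_length(parts3, 3L)
  expect_identical(attr(parts3, "cuts"), c(1L, 3L))
  expect_equal(vapply(parts3, nrow, integer(1)), c(1L, 2L, 1L))
  # ... but not with tau = 1.05 (4000 < 4500/1.05 is false -> still two cuts);
  # use a clearly sub-threshold ratio instead
  tri2 <- frags(c(0, 1100, 1300, 9900), c(100, 1200, 1400, 10000))
  parts2 <- entropy_split(tri2, threshold = 0.8, tau = 2)
  expect_length(parts2, 2L)  # second gap 1000 < 8500/2
})

test_that("ties in the maximal gap cut left-most", {
  fr <- frags(c(0, 1100, 2200, 2400), c(100, 1200, 2300, 2500))
  # gaps: 1000, 1000, 100 -> cut at index 1 (plus second cut at index 2)
  parts <- entropy_split(fr, threshold = 1, tau = 2)
  expect_identical(attr(parts, "cuts")[1], 1L)
})

test_that("the full distance test separates planted signal from noise", {
  sim <- simulate_dataset(sim_config(complexes_per_tad = 120,
                                     noise_fraction = 0.5, seed = 21))
  cfg <- distance_test_config(sample_size = 5000L, seed = 9L)
  res <- run_distance_test(sim$complexes, cfg)
  m <- merge(res$master, sim$truth, by = "cid")
  rate <- m[, .(sig = mean(category %in% c("pass1", "pass2"))), by = origin]
  expect_gt(rate[origin == "intra_tad", sig], 0.85)
  expect_lt(rate[origin == "noise", sig], 0.1)
  # every tested input complex lands in exactly one final category
  expect_true(all(res$master$category %in%
                    c("pass1", "fail1", "pass2", "fail2", "singleton")))
  expect_identical(anyDuplicated(res$master$cid), 0L)
})

test_that("split sub-complexes preserve the parent fragment multiset", {
  sim <- simulate_dataset(sim_config(complexes_per_tad = 60,
                                     multiplet_fraction = 0.3,
                                     triplet_share = 0.2, seed = 13))
  cfg <- distance_test_config(sample_size = 5000L, seed = 2L)
  res <- run_distance_test(sim$complexes, cfg)
  kids <- res$master[!is.na(parent)]
  expect_gt(nrow(kids), 0L)
  expect_true(all(kids[, .N, by = parent]$N <= 3L))
  for (pid in unique(kids$parent)[1:10]) {
    pf <- sim$complexes$fragments[cid == pid, .(start, end)]
    kf <- res$complexes$fragments[cid %in% kids[parent == pid, cid],
                                  .(start, end)]
    expect_equal(data.table::setorder(kf, start),
                 data.table::setorder(pf, start), ignore_attr = TRUE)
  }
})

test_that("deferred doublets are rescued by the second test", {
  # compact complexes pass outright; wide complexes fail; doublets (two
  # compact halves joined by an 8-Mb junction) defer, split, and their
  # halves pass the second test
  set.seed(1)
  mk <- function(i, kind) {
    g <- switch(kind,
                compact = round(runif(7, 1000, 2500)),
                noise = round(runif(7, 3e5, 1.5e6)),
                doublet = c(round(runif(5, 1000, 2500)), 8e6,
                            round(runif(5, 1000, 2500))))
    nf <- length(g) + 1L
    st <- cumsum(c(round(runif(1, 0, 2e6)), rep(400, nf - 1L) + g))
    frags(st, st + 400, cid = sprintf("%s%03d", kind, i), chrom = "chrT")
  }
  fr <- rbindlist(c(lapply(1:60, mk, "compact"), lapply(1:60, mk, "noise"),
                    lapply(1:40, mk, "doublet")))
  x <- as_complexes(fr, c(chrT = 2e7))
  res <- run_distance_test(x, distance_test_config(sample_size = 5000L,
                                                   seed = 4L,
                                                   min_complexes = 5L))
  m <- copy(res$master)
  m[, kind := sub("[0-9].*", "", fifelse(is.na(parent), cid, parent))]
  expect_true(all(m[kind == "compact", category] == "pass1"))
  expect_true(all(m[kind == "noise", category] == "fail2"))
  kid <- m[kind == "doublet"]
  expect_true(all(!is.na(kid$parent)))           # every doublet was split
  expect_gt(mean(kid$category == "pass2"), 0.9)  # halves rescued
  # identical input and seed reproduce identical categories
  res2 <- run_distance_test(x, distance_test_config(sample_size = 5000L,
                                                    seed = 4L,
                                                    min_complexes = 5L))
  expect_identical(res$master, res2$master)
})

test_that("sparse chromosomes are skipped with a warning", {
  x <- as_complexes(oc8(), toy_sizes)
  cfg <- distance_test_config(sample_size = 1000L, min_complexes = 5L)
  expect_warning(res <- run_distance_test(x, cfg), "skipped")
  expect_identical(res$master$category, "unassigned")
})
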