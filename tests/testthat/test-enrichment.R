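cs_toy <- c(chrT = 10000)

test_that("bedGraph binning computes basepair-weighted bin means", {
  bg <- data.table(chrom = "chrT", start = 0, end = 100, value = 2)
  tr <- bin_coverage(bg, cs_toy, bin_size = 10)[["chrT"]]
  expect_equal(tr$values[1:10], rep(2, 10))
  expect_equal(tr$values[11:1000], rep(0, 990))
  # two half-bin intervals average within the bin
  bg2 <- data.table(chrom = "chrT", start = c(0, 5), end = c(5, 10),
                    value = c(2, 4))
  expect_equal(bin_coverage(bg2, cs_toy, 10)[["chrT"]]$values[1], 3)
  # empty bedGraph: all zeros
  bg0 <- data.table(chrom = character(0), start = numeric(0),
                    end = numeric(0), value = numeric(0))
  expect_true(all(bin_coverage(bg0, cs_toy, 10)[["chrT"]]$values == 0))
  # overlap rejected
  bg3 <- data.table(chrom = "chrT", start = c(0, 50), end = c(100, 120),
                    value = 1)
  expect_error(bin_coverage(bg3, cs_toy, 10), "overlapping")
})

test_that("binned lookups track exact bedGraph integration", {
  set.seed(41)
  # random step signal with 10-bp-aligned breakpoints integrates exactly
  bk <- sort(sample(seq(0, 10000, by = 10), 30))
  bg <- data.table(chrom = "chrT", start = head(bk, -1), end = tail(bk, -1),
                   value = round(runif(29, 0, 5), 2))
  tr <- bin_coverage(bg, cs_toy, 10)[["chrT"]]
  for (i in 1:20) {
    s <- sample(seq(0, 9000, by = 10), 1)
    e <- s + sample(seq(10, 990, by = 10), 1)
    expect_equal(complex_coverage(frags(s, e, chrom = "chrT"), tr),
                 exact_bg_mean(bg, s, e))
  }
  # unaligned fragments stay within the largest within-bin jump
  jump <- max(abs(diff(tr$values)))
  for (i in 1:20) {
    s <- sample(0:9000, 1)
    e <- s + sample(25:900, 1)
    expect_lt(abs(complex_coverage(frags(s, e, chrom = "chrT"), tr) -
                    exact_bg_mean(bg, s, e)), jump + 1e-9)
  }
})

test_that("complex coverage is the mean of fragment means", {
  bg <- data.table(chrom = "chrT", start = c(0, 5000),
                   end = c(1000, 6000), value = c(2, 4))
  tr <- bin_coverage(bg, cs_toy, 10)[["chrT"]]
  fr <- frags(c(100, 5100), c(600, 5600), chrom = "chrT")
  expect_equal(complex_coverage(fr, tr), 3)
  # fragments over empty signal
  fr0 <- frags(c(7000, 8000), c(7400, 8400), chrom = "chrT")
  expect_equal(complex_coverage(fr0, tr), 0)
  # a fragment spanning exactly one bin reads that bin
  expect_equal(complex_coverage(frags(5020, 5030, chrom = "chrT"), tr), 4)
})

test_that("shift-null p-values behave at the degenerate extremes", {
  flat <- structure(list(chrom = "chrT", bin_size = 10,
                         values = rep(3, 1000)), class = "mcia_track")
  fr <- frags(c(1000, 3000), c(1500, 3500), chrom = "chrT")
  cfg <- enrichment_config(n_samples = 500, seed = 5)
  # constant coverage: strict inequality never holds
  expect_equal(enrichment_pvalue(fr, flat, 10000, cfg)$raw_p, 0)
  # complex sitting on the unique peak of a zero track
  vals <- numeric(1000); vals[101:160] <- 8
  peaky <- structure(list(chrom = "chrT", bin_size = 10, values = vals),
                     class = "mcia_track")
  on_peak <- frags(1000, 1600, chrom = "chrT")
  expect_equal(enrichment_pvalue(on_peak, peaky, 10000, cfg)$raw_p, 0)
  # a complex wider than the chromosome is untestable
  wide <- frags(c(0, 9800), c(100, 10000), chrom = "chrT")
  r <- enrichment_pvalue(wide, peaky, 10000, cfg)
  expect_false(r$testable)
  expect_true(is.na(r$raw_p))
})

test_that("off-peak placement probability matches the analytic fraction", {
  # single 600-bp peak on a zero track; a 100-bp fragment placed off-peak
  # exceeds its zero coverage whenever the shift touches the peak
  vals <- numeric(1000); vals[501:560] <- 4
  trk <- structure(list(chrom = "chrT", bin_size = 10, values = vals),
                   class = "mcia_track")
  fr <- frags(8000, 8100, chrom = "chrT")
  cfg <- enrichment_config(n_samples = 20000, seed = 3)
  p <- enrichment_pvalue(fr, trk, 10000, cfg)$raw_p
  # placements 0..9900 (9901 of them); touching starts 4901..5599
  analytic <- 699 / 9901
  se <- sqrt(analytic * (1 - analytic) / 20000)
  expect_lt(abs(p - analytic), 4 * se)
})

test_that("Monte-Carlo p-values converge to exhaustive shift enumeration", {
  set.seed(12)
  vals <- pmax(0, rnorm(1000, 1, 0.5)); vals[301:340] <- 6
  trk <- structure(list(chrom = "chrT", bin_size = 10, values = vals),
                   class = "mcia_track")
  fr <- frags(c(2000, 2800), c(2400, 3200), chrom = "chrT")
  obs <- complex_coverage(fr, trk)
  span <- 3200 - 2000
  exact <- mean(vapply(0:(10000 - span), function(s) {
    complex_coverage(frags(c(s, s + 800), c(s + 400, s + 1200),
                           chrom = "chrT"), trk) > obs
  }, logical(1)))
  cfg <- enrichment_config(n_samples = 5000, seed = 77)
  p <- enrichment_pvalue(fr, trk, 10000, cfg)$raw_p
  se <- sqrt(exact * (1 - exact) / 5000)
  expect_lt(abs(p - exact), 3 * se)
  # invariant to rescaling the whole track
  trk2 <- trk; trk2$values <- trk$values * 7.5
  expect_identical(enrichment_pvalue(fr, trk2, 10000, cfg)$raw_p, p)
})

test_that("repeat filtering drops masked fragments and shrunken complexes", {
  fr <- rbind(frags(c(100, 1000, 6000), c(500, 1500, 6500), cid = "keep3"),
              frags(c(100, 6000), c(500, 6500), cid = "drop2"))
  x <- as_complexes(fr, toy_sizes)
  rmsk <- data.table(chrom = "chr2L", start = 5900, end = 6600)
  filt <- filter_repeats(x, rmsk)
  ct <- complex_table(filt)
  expect_identical(ct$cid, "keep3")
  expect_equal(ct$n, 2L)
  # empty repeat set: unchanged
  filt0 <- filter_repeats(x, rmsk[0])
  expect_equal(nrow(filt0$fragments), nrow(x$fragments))
})

test_that("the enrichment test separates peak-bound from background complexes", {
  sim <- simulate_dataset(sim_config(complexes_per_tad = 60,
                                     peak_bound_fraction = 0.5, seed = 19))
  cov <- bin_coverage(sim$coverage, sim$chrom_sizes, bin_size = 10)
  er <- run_enrichment_test(sim$complexes, cov,
                            enrichment_config(n_samples = 500, seed = 4))
  m <- merge(er$master, sim$truth, by = "cid")
  rates <- m[, .(pass = mean(category == "pass")), by = origin]
  expect_gt(rates[origin == "peak_bound", pass], 0.9)
  expect_lt(rates[origin == "intra_tad", pass], 0.2)
  expect_true(all(er$master$category %in% c("pass", "fail", "untestable")))
})
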