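test_that("histogram binning matches a naive per-value loop", {
  set.seed(5)
  v <- rlnorm(5000, log(100), 0.4)
  h <- build_histogram(v, bin_origin = 20, bin_width = 0.35)
  # independent oracle: loop over values, place each in its bin
  counts <- integer(1024)
  overflow <- 0L
  for (x in v) {
    k <- floor((x - 20) / 0.35)
    if (k >= 0 && k <= 1023) counts[k + 1L] <- counts[k + 1L] + 1L
    else overflow <- overflow + 1L
  }
  expect_identical(h$counts, counts)
  expect_identical(h$overflow, overflow)
  expect_equal(sum(h$counts) + h$overflow, length(v))
})

test_that("histogram edge conventions: half-open bins, single-bin case", {
  h <- build_histogram(c(5, 5.4, 5.999), bin_origin = 5, bin_width = 1)
  expect_equal(sum(h$counts > 0), 1L)
  expect_equal(h$counts[1], 3)
  # a value exactly on a right edge belongs to the next bin
  h2 <- build_histogram(c(6), bin_origin = 5, bin_width = 1)
  expect_equal(h2$counts[2], 1)
  expect_warning(build_histogram(numeric(0), 0, 1), "empty")
  expect_error(protein_histogram(1:10), "1024 channels")
})

test_that("alignment recovers itself with zero SSR", {
  v <- toy_population(40000, seed = 3)
  # "experimental" histogram: the aligner's own subsample binned on its
  # natural amino-acid scale; the identity must then be the optimum
  set.seed(1)                 # mirror the aligner's subsample
  sub <- sample(v, 30000, replace = FALSE)
  rng <- range(sub)
  w <- diff(rng) / 1024 * (1 + 1e-9)
  exph <- build_histogram(sub, rng[1], w, scale = "fluorescence_units")
  al <- align_distributions(v, exph, sample_size = 30000, seed = 1)
  expect_equal(al$SSR, 0)
  expect_equal(al$bin_origin, rng[1], tolerance = 1e-6)
  expect_equal(al$bin_width, w, tolerance = 1e-6)
})

test_that("alignment recovers planted affine transforms within a grid step", {
  v <- toy_population(40000, seed = 11)
  set.seed(99)
  n_ok <- 0L
  n_try <- 20L
  for (i in seq_len(n_try)) {
    gain <- runif(1, 0.5, 3)
    offset <- runif(1, -0.2, 0.5) * mean(v) * gain
    m <- instrument_model(fu_per_aa = gain, offset = offset,
                          CV_instrument = 0, n_events = 30000)
    exph <- synthesize_experiment(v, m, seed = 100 + i)
    al <- align_distributions(v, exph, seed = 100 + i)
    # truth on the aa axis: width = exp_width / gain
    w_true <- exph$bin_width / gain
    o_true <- (exph$bin_origin - offset) / gain
    # grid step of the final refinement (median diff is robust to the
    # near-duplicate natural candidate)
    g <- al$grid
    step_w <- stats::median(diff(sort(unique(g$width))))
    step_o <- stats::median(diff(sort(unique(g$origin))))
    tol_w <- max(step_w * 1.5, 1e-6 * w_true)
    tol_o <- max(step_o * 1.5, 1e-6 * max(abs(o_true), w_true))
    if (abs(al$bin_width - w_true) <= tol_w &&
        abs(al$bin_origin - o_true) <= tol_o)
      n_ok <- n_ok + 1L
  }
  expect_identical(n_ok, n_try)
})

test_that("SSR certificate: optimum is the minimum over the searched grid", {
  v <- toy_population(35000, seed = 2)
  exph <- synthesize_experiment(v, instrument_model(CV_instrument = 0.03),
                                seed = 4)
  al <- align_distributions(v, exph, seed = 4)
  expect_true(all(al$grid$SSR >= al$SSR - 1e-9))
  # shuffling the experimental channels destroys the optimum
  set.seed(8)
  shuffled <- protein_histogram(sample(exph$counts), exph$bin_origin,
                                exph$bin_width)
  ssr_shuffled <- sum((shuffled$counts -
                         (exph$counts - al$residual_curve))^2)
  expect_gt(ssr_shuffled, al$SSR)
})

test_that("frozen alignment reuse reproduces and transfers the scale", {
  v <- toy_population(40000, seed = 21)
  exph <- synthesize_experiment(v, instrument_model(CV_instrument = 0.02),
                                seed = 5)
  al <- align_distributions(v, exph, seed = 5)
  # reusing on the reference population reproduces the reference SSR
  re <- reuse_alignment(al, v, experimental = exph)
  expect_equal(re$SSR, al$SSR)
  # a smaller-cell population binned on the frozen scale shifts left
  v_small <- v * 0.6
  re_small <- reuse_alignment(al, v_small)
  m_ref <- distribution_stats(re$histogram)[["mean"]]
  m_small <- distribution_stats(re_small$histogram)[["mean"]]
  expect_lt(m_small, m_ref)
  # frozen scale with different subsample seeds: SSR varies by < 5%
  ssrs <- vapply(1:5, function(s)
    reuse_alignment(al, v, experimental = exph, seed = s)$SSR, numeric(1))
  expect_lt(stats::sd(ssrs) / mean(ssrs), 0.05)
})

test_that("distribution statistics on histograms and raw values agree", {
  # symmetric two-channel histogram -> mean at the midpoint
  counts <- integer(1024); counts[c(100, 200)] <- 50
  h <- protein_histogram(counts, bin_origin = 0, bin_width = 1)
  st <- distribution_stats(h)
  expect_equal(st[["mean"]], (99.5 + 199.5) / 2)
  # single-channel histogram -> SD = 0, CV = 0
  counts1 <- integer(1024); counts1[300] <- 80
  st1 <- distribution_stats(protein_histogram(counts1))
  expect_equal(st1[["sd"]], 0)
  expect_equal(st1[["cv"]], 0)
  expect_equal(st1[["mode"]], 299.5)
  # raw vs finely binned values agree within half a bin width
  v <- toy_population(20000, seed = 9)
  w <- diff(range(v)) / 1024 * 1.0001
  hv <- build_histogram(v, min(v), w)
  sr <- distribution_stats(v); sh <- distribution_stats(hv)
  expect_lt(abs(sr[["mean"]] - sh[["mean"]]), w / 2)
  expect_lt(abs(sr[["median"]] - sh[["median"]]), w)
  expect_lt(abs(sr[["sd"]] - sh[["sd"]]), w)
})

test_that("histogram CSV round trip preserves counts and scale", {
  v <- toy_population(5000, seed = 13)
  h <- build_histogram(v, min(v), diff(range(v)) / 1024 * 1.001)
  path <- tempfile(fileext = ".csv")
  write_histogram_csv(h, path)
  h2 <- read_histogram_csv(path)
  expect_equal(h2$counts, h$counts)
  expect_equal(h2$bin_origin, h$bin_origin, tolerance = 1e-9)
  expect_equal(h2$bin_width, h$bin_width, tolerance = 1e-9)
  unlink(path)
})
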