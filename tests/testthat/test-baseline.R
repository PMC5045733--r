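test_that("steady-state average is a plain per-q mean over the region", {
  ds <- secsaxs_dataset(c(0.01, 0.02),
                        rbind(rep(5, 12), c(rep(0, 2), 1:10)),
                        matrix(1, 2, 12))
  expect_equal(steady_state_average(ds, 3, 12), c(5, 5.5))
  expect_warning(steady_state_average(ds, 5, 12), "shorter")
  ds0 <- secsaxs_dataset(0.01, matrix(0, 1, 15), matrix(1, 1, 15))
  expect_equal(steady_state_average(ds0, 1, 15), 0)
  expect_error(steady_state_average(ds, 3, 20), "outside")
})

test_that("gaussian smoothing preserves constants, sums and the kernel", {
  y <- rep(3.5, 40)
  expect_equal(gaussian_smooth(y), y)

  # interior-supported bump keeps its sum under a normalized kernel
  bump <- c(rep(0, 15), dnorm(seq(-3, 3, length.out = 11)), rep(0, 15))
  expect_equal(sum(gaussian_smooth(bump)), sum(bump), tolerance = 1e-12)

  # unit impulse returns the kernel weights themselves
  imp <- c(rep(0, 10), 1, rep(0, 10))
  sm <- gaussian_smooth(imp, points = 7)
  w <- secsaxs:::gaussian_kernel(7)
  expect_equal(sm[8:14], w)

  expect_error(gaussian_smooth(y, points = 6), "odd")
  expect_error(gaussian_smooth(y[1:4], points = 7), "exceeds")
})

test_that("integral baseline recovers forward-simulated fouling exactly", {
  tt <- 1:400
  s <- eval_gaussian(tt, 100, 120, 15)
  for (gamma in c(1e-4, 1e-3, 1e-2)) {
    sim <- forward_foul(s, gamma)
    I_BL <- mean(sim$observed[360:400] - s[360:400])
    res <- integral_baseline(sim$observed, mean(sim$observed[360:400]),
                             region_end = 360, epsilon = 0, max_iter = 50)
    expect_false(res$skipped)
    expect_equal(res$gamma, gamma, tolerance = 1e-6)
    peak <- max(s)
    expect_lt(sqrt(mean((res$B - sim$baseline)^2)) / peak, 1e-6)
    # baseline monotone, pinned to zero at the first frame
    expect_equal(res$B[1], 0)
    expect_true(all(diff(res$B) >= -1e-12))
    # plateau matches the steady-state average
    expect_equal(mean(res$B[360:400]), mean(sim$observed[360:400]),
                 tolerance = 1e-6)
  }
})

test_that("integral baseline degenerate branches behave as documented", {
  # I_BL = 0: no correction needed
  res0 <- integral_baseline(rnorm(50), 0, region_end = 40)
  expect_equal(res0$B, numeric(50))
  expect_equal(res0$iterations, 0L)

  # negative integral: correction would add signal -> skip ("0s")
  resn <- integral_baseline(rep(-1, 50), 0.5, region_end = 40)
  expect_true(resn$skipped)
  expect_equal(resn$B, numeric(50))
})

test_that("dataset-level correction restores proportional chromatograms", {
  # single species, fouling on, no noise: after correction the
  # chromatograms at different q must be strictly proportional again
  spec <- single_species_spec(seed = 3, gamma = 1e-3, noise_frac = 0)
  spec$noise_floor <- 0
  gen <- generate_sec_saxs(spec)
  ds <- gen$dataset
  ds$S[] <- 1  # weights immaterial here
  region <- list(t_s1 = 170, t_sm = 200)
  br <- apply_integral_baseline(ds, region, max_iter = 50)
  corr <- br$corrected

  # trailing half-height region of the peak, scaled chromatograms overlap
  peak_q <- c(1, 10, 25)
  prof <- gen$truth$profiles[, 1]
  half <- which(prof > 0.5 * max(prof))
  trail <- seq(max(half), max(half) + 15)
  scaled <- vapply(peak_q, function(i) {
    corr$I[i, trail] / max(corr$I[i, ])
  }, numeric(length(trail)))
  spread <- apply(scaled, 1, function(v) diff(range(v)) / mean(v))
  expect_lt(max(spread), 0.01)

  # corrected tail sits at zero
  expect_lt(max(abs(rowMeans(corr$I[, 170:200]))) / max(ds$I), 1e-4)

  # gamma recovered per q
  expect_equal(unname(br$gamma[!br$skipped]),
               rep(1e-3, sum(!br$skipped)), tolerance = 0.01)

  # idempotence: correcting corrected data is a no-op
  br2 <- apply_integral_baseline(corr, region, max_iter = 50)
  expect_lt(max(abs(br2$corrected$I - corr$I)) / max(ds$I), 1e-6)

  # zero-fouling data pass through essentially unchanged (the EMG tail
  # leaves a ~1e-6 residual steady-state level, so the correction is not
  # exactly the identity)
  spec0 <- single_species_spec(seed = 3, gamma = 0, noise_frac = 0)
  spec0$noise_floor <- 0
  ds0 <- generate_sec_saxs(spec0)$dataset
  ds0$S[] <- 1
  br0 <- apply_integral_baseline(ds0, region, max_iter = 50)
  expect_lt(max(abs(br0$corrected$I - ds0$I)) / max(ds0$I), 1e-4)
})

test_that("corrected-signal bias stays within noise at 1% sigma", {
  spec <- single_species_spec(seed = 13, gamma = 1e-3, noise_frac = 0.01)
  gen <- generate_sec_saxs(spec)
  ds <- gen$dataset
  br <- suppressWarnings(
    apply_integral_baseline(ds, list(t_s1 = 170, t_sm = 200), max_iter = 50))
  resid <- br$corrected$I - gen$truth$signal
  tail_bias <- abs(rowMeans(resid[, 150:200]))
  tail_sigma <- apply(ds$S[, 150:200], 1, mean) / sqrt(51)
  ok <- !br$skipped
  expect_true(mean(tail_bias[ok] <= 2 * pmax(tail_sigma[ok],
                                             0.01 * max(gen$truth$signal))) > 0.95)
})

test_that("find_best_region reads both indicators and suggests correctly", {
  q <- seq(0.005, 0.1, length.out = 30)
  nq <- length(q)
  set.seed(31)
  s0 <- 0.01
  mkframes <- function(level, nt) {
    matrix(level + rnorm(nq * nt, 0, s0), nq, nt)
  }
  blanks <- secsaxs_dataset(q, mkframes(0, 60), matrix(s0, nq, 60))
  ref <- blank_reference(blanks, window = 15)

  # elution peak then flat positive plateau: the last windows are chosen
  # and the integral baseline is suggested
  peak <- eval_gaussian(1:120, 50, 40, 8)
  I <- outer(exp(-q * 5), peak) + 0.3 + matrix(rnorm(nq * 120, 0, s0), nq)
  ds <- secsaxs_dataset(q, I, matrix(s0, nq, 120))
  reg <- find_best_region(ds, ref, window = 15)
  expect_equal(reg$suggestion, "integral baseline")
  expect_gt(reg$t_s1, 60)  # past the elution peak
  expect_equal(reg$t_sm, 120)

  # tail statistically identical to blanks and centred on zero: no fouling
  I0 <- outer(exp(-q * 5), peak) + matrix(rnorm(nq * 120, 0, s0), nq)
  ds0 <- secsaxs_dataset(q, I0, matrix(s0, nq, 120))
  reg0 <- find_best_region(ds0, ref, window = 15)
  expect_equal(reg0$suggestion, "none/linear")

  # two flat zones, only the later one is selected
  two <- cbind(mkframes(0.5, 30), outer(exp(-q * 5), peak[1:60]) + 0.3,
               mkframes(0.3, 30))
  ds2 <- secsaxs_dataset(q, two, matrix(s0, nq, 120))
  reg2 <- find_best_region(ds2, ref, window = 15)
  expect_gt(reg2$t_s1, 90)
})

test_that("linear baseline subtracts the anchor line", {
  ch <- tibble::tibble(frame = 1:100, intensity = rep(3, 100), sigma = 1)
  out <- linear_baseline(ch, c(1, 10), c(91, 100))
  expect_equal(out$intensity, rep(0, 100))

  ramp <- tibble::tibble(frame = 1:100, intensity = 0.5 * (1:100), sigma = 1)
  expect_equal(linear_baseline(ramp, c(1, 10), c(91, 100))$intensity,
               rep(0, 100), tolerance = 1e-12)

  peak <- eval_gaussian(1:100, 50, 50, 6)
  both <- tibble::tibble(frame = 1:100,
                         intensity = 2 + 0.1 * (1:100) + peak, sigma = 1)
  out3 <- linear_baseline(both, c(1, 10), c(91, 100))
  expect_equal(out3$intensity, peak, tolerance = 1e-8)
})
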