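make_surface <- function(seed = 7, noise = 0.01, nq = 24, nt = 200,
                         kind = "EMG_GMG") {
  pk <- function(a0, a1) {
    if (kind == "EMG_GMG") peak_model(kind, a0, a1, 6, 12, 9)
    else peak_model("GAUSS", a0, a1, 6)
  }
  synthetic_spec(
    q = seq(0.008, 0.18, length.out = nq), n_frames = nt,
    species = list(synthetic_species(55, 150, pk(60, 70)),
                   synthetic_species(30, 60, pk(240, 110))),
    gamma = 0, noise_frac = noise, seed = seed)
}

test_that("svd_rank counts the components of a synthetic surface", {
  spec <- make_surface(noise = 0)
  spec$noise_floor <- 0
  ds <- generate_sec_saxs(spec)$dataset
  sv <- svd_rank(ds)
  expect_equal(sv$suggested_n, 2L)
  expect_lt(sv$singular_values[3] / sv$singular_values[1], 1e-12)

  # rank-4 plus noise: 4 values above the floor
  set.seed(5)
  M <- matrix(0, 40, 120)
  for (k in 1:4) M <- M + outer(runif(40), dnorm(1:120, 20 + 25 * k, 8)) * 50
  dsn <- secsaxs_dataset(seq(0.01, 0.2, length.out = 40),
                         M + rnorm(40 * 120, 0, 0.01 * max(M)),
                         matrix(1, 40, 120))
  svn <- svd_rank(dsn)
  expect_equal(svn$suggested_n, 4L)

  # frame permutation leaves singular values unchanged
  perm <- sample(ncol(ds$I))
  dsp <- secsaxs_dataset(ds$q, ds$I[, perm], ds$S[, perm])
  expect_equal(svd_rank(dsp)$singular_values, sv$singular_values,
               tolerance = 1e-10)
})

test_that("single-chromatogram fits recover generating parameters", {
  # one Gaussian + 0.5% noise
  set.seed(41)
  t <- 1:200
  truth <- eval_gaussian(t, 120, 90, 12)
  sig <- 0.005 * max(truth) + 0 * t
  ch <- tibble::tibble(frame = t, intensity = truth + rnorm(200, 0, sig),
                       sigma = sig)
  fit <- fit_single(ch, 1, "GAUSS", init_centers = 85)
  expect_true(fit$converged)
  expect_equal(fit$shapes$a1, 90, tolerance = 0.005)
  expect_equal(fit$shapes$a2, 12, tolerance = 0.03)
  expect_equal(fit$shapes$a0, 120, tolerance = 0.02)

  # 4 EMG+GMG peaks with shared distortions: distortions within 5%
  spec <- synthetic_spec(seed = 19, gamma = 0)
  ds <- generate_sec_saxs(spec)$dataset
  ch4 <- chromatogram(ds, ds$q[3])
  fit4 <- fit_single(ch4, 4, "EMG_GMG", init_centers = c(58, 84, 104, 128))
  expect_equal(fit4$shapes$a3[1], 12, tolerance = 0.05 * 12)
  expect_equal(fit4$shapes$a4[1], 9, tolerance = 0.05 * 9)
  expect_equal(length(unique(fit4$shapes$a3)), 1L)  # tied by default

  # symmetric Gaussians on skewed truth leave sign-structured residuals
  fitg <- fit_single(ch4, 4, "GAUSS", init_centers = c(58, 84, 104, 128))
  sel <- ch4$frame >= fitg$fit_limits[1] & ch4$frame <= fitg$fit_limits[2]
  p <- cormap_pvalue(ch4$intensity[sel], fitg$fitted[sel],
                     x = ch4$frame[sel],
                     opts = pairwise_options(q_max_cutoff = Inf))
  expect_lt(p, 0.01)
})

test_that("amplitude initialization is an exact non-negative linear solve", {
  spec <- make_surface(noise = 0)
  spec$noise_floor <- 1e-12
  gen <- generate_sec_saxs(spec)
  ds <- gen$dataset
  ch <- chromatogram(ds, ds$q[2])
  single <- fit_single(ch, 2, "EMG_GMG", init_centers = c(68, 108))
  m <- init_global(single, ds)
  expect_true(all(m$amplitudes >= 0))

  # with truth shapes the amplitudes reproduce the generator exactly
  single$shapes <- tibble::tibble(family = 1:2, a1 = c(70, 110), a2 = 6,
                                  a3 = 12, a4 = 9, a0 = c(1, 1))
  m_truth <- init_global(single, ds)
  truthA <- cbind(gen$truth$form_factors[, 1] * 60,
                  gen$truth$form_factors[, 2] * 240)
  expect_equal(m_truth$amplitudes, truthA, tolerance = 1e-8,
               ignore_attr = TRUE)

  # one-in-four subset selection is honored
  qsub <- ds$q[seq(1, length(ds$q), by = 4)]
  msub <- init_global(single, ds, q_values = qsub)
  expect_equal(msub$q, qsub)
  expect_equal(nrow(msub$amplitudes), length(qsub))
})

test_that("global fit recovers shared shapes and never degrades the SSR", {
  spec <- make_surface(seed = 29)
  gen <- generate_sec_saxs(spec)
  ds <- gen$dataset
  single <- fit_single(chromatogram(ds, ds$q[2]), 2, "EMG_GMG",
                       init_centers = c(68, 108))
  m0 <- init_global(single, ds)
  ssr_of <- function(model) {
    sel <- ds$frames >= model$fit_limits[1] & ds$frames <= model$fit_limits[2]
    basis <- secsaxs:::shape_basis(model$kind, ds$frames[sel], model$shapes)
    sum(vapply(seq_along(model$q), function(r) {
      j <- match(model$q[r], ds$q)
      sum(((ds$I[j, sel] - basis %*% model$amplitudes[r, ]) /
             ds$S[j, sel])^2)
    }, numeric(1)))
  }
  m <- global_fit(m0, ds)
  expect_true(m$converged)
  expect_lte(m$ssr, ssr_of(m0) + 1e-8)
  expect_equal(m$shapes$a1, c(70, 110), tolerance = 0.02)
  expect_equal(m$shapes$a2, c(6, 6), tolerance = 0.02 * 6)
  # the EMG/GMG distortion split is weakly identified on a surface this
  # small, but the recovered family shapes must agree with the truth
  # pointwise (distortion-parameter recovery itself is exercised at full
  # scale in the acceptance suite)
  tt <- 1:200
  for (f in 1:2) {
    fitted_shape <- secsaxs:::unit_shape("EMG_GMG", tt, m$shapes$a1[f],
                                         m$shapes$a2[f], m$shapes$a3[f],
                                         m$shapes$a4[f])
    truth_shape <- secsaxs:::unit_shape("EMG_GMG", tt, c(70, 110)[f], 6,
                                        12, 9)
    expect_lt(max(abs(fitted_shape - truth_shape)) / max(truth_shape), 0.05)
  }
  truthA <- cbind(gen$truth$form_factors[, 1] * 60,
                  gen$truth$form_factors[, 2] * 240)
  expect_gt(cor(as.vector(m$amplitudes), as.vector(truthA)), 0.999)

  # invariance under a joint global rescale of I and S
  k <- 37.5
  dsk <- secsaxs_dataset(ds$q, ds$I * k, ds$S * k)
  mk <- global_fit(init_global(single, dsk), dsk)
  expect_equal(mk$shapes$a1, m$shapes$a1, tolerance = 1e-6)
  expect_equal(mk$amplitudes, m$amplitudes * k, tolerance = 1e-4)
})

test_that("releasing the common-distortion tie helps unequal-tail truth", {
  spec <- synthetic_spec(
    q = seq(0.008, 0.18, length.out = 16), n_frames = 200,
    species = list(
      synthetic_species(55, 150, peak_model("EMG", 60, 70, 6, 14)),
      synthetic_species(30, 60, peak_model("EMG", 240, 110, 6, 4))),
    gamma = 0, noise_frac = 0.01, seed = 43)
  ds <- generate_sec_saxs(spec)$dataset
  single <- fit_single(chromatogram(ds, ds$q[2]), 2, "EMG",
                       init_centers = c(68, 108))
  m0 <- init_global(single, ds)
  tied <- global_fit(m0, ds)
  m0$common_distortion <- FALSE
  free <- global_fit(m0, ds)
  expect_lt(free$ssr, tied$ssr)
})

test_that("per-q goodness flags a deliberately biased trough", {
  spec <- make_surface(seed = 47)
  ds <- generate_sec_saxs(spec)$dataset
  sh <- tibble::tibble(family = 1:2, a1 = c(70, 110), a2 = 6, a3 = 12,
                       a4 = 9)
  m <- secsaxs:::new_decomposition_model("EMG_GMG", sh,
    matrix(0, length(ds$q), 2), ds$q,
    secsaxs:::default_fit_limits(ds$frames), TRUE)
  m <- fit_all_amplitudes(m, ds)
  rep0 <- goodness_by_q(m, ds)
  expect_true(mean(rep0$class == "red") < 0.2)

  # inject a coherent bias into the trough between the two peaks at one q
  j <- 5
  trough <- ds$frames >= 85 & ds$frames <= 100
  ds$I[j, trough] <- ds$I[j, trough] + 4 * ds$S[j, trough]
  m2 <- fit_all_amplitudes(m, ds)
  rep2 <- goodness_by_q(m2, ds)
  expect_equal(rep2$class[j], "red")

  # a perfect fit scores P = 1, chi2 = 0 (model evaluated exactly as the
  # goodness computation does, row by row)
  sel <- ds$frames >= m$fit_limits[1] & ds$frames <= m$fit_limits[2]
  basis <- secsaxs:::shape_basis(m$kind, ds$frames[sel], m$shapes)
  dse <- secsaxs_dataset(ds$q, matrix(0, length(ds$q), ncol(ds$I)), ds$S)
  for (r in seq_along(ds$q)) {
    dse$I[r, sel] <- as.vector(basis %*% m$amplitudes[r, ])
  }
  repe <- goodness_by_q(m, dse)
  expect_true(all(repe$p_value == 1))
  expect_true(all(repe$chi2 == 0))
})

test_that("back-generated frames rebuild species and propagate sigma", {
  spec <- synthetic_spec(
    q = seq(0.005, 0.15, length.out = 60), n_frames = 200,
    species = list(synthetic_species(
      30, 100, peak_model("GAUSS", 300, 90, 10))),
    gamma = 0, noise_frac = 0, noise_floor = 1e-12, seed = 3)
  gen <- generate_sec_saxs(spec)
  ds <- gen$dataset
  ds$S[] <- 1e-3
  single <- fit_single(chromatogram(ds, ds$q[2]), 1, "GAUSS",
                       init_centers = 88)
  m <- fit_all_amplitudes(global_fit(init_global(single, ds), ds), ds)
  bg <- back_generate_frames(m, ds, 1, c(70, 110), fit_error_fraction = 0)
  truth <- gen$truth$species[[1]][, ds$frames %in% bg$frames]
  expect_lt(max(abs(bg$I - truth)) / max(truth), 1e-4)
  # zero fit-error fraction reassigns the original sigmas untouched
  expect_identical(bg$S, ds$S[, ds$frames %in% bg$frames])

  # two equal overlapping families split the discrepancy 50:50
  sh <- tibble::tibble(family = 1:2, a1 = c(90, 90), a2 = c(8, 8),
                       a3 = c(6, 6), a4 = c(5, 5))
  m2 <- secsaxs:::new_decomposition_model("EMG_GMG", sh,
    matrix(1, length(ds$q), 2), ds$q, m$fit_limits, TRUE)
  bg2 <- back_generate_frames(m2, ds, 1, c(85, 95), fit_error_fraction = 1)
  sel <- ds$frames %in% bg2$frames
  basis <- secsaxs:::shape_basis("EMG_GMG", ds$frames[sel], sh)
  total <- matrix(1, length(ds$q), 1) %*% t(basis[, 1] + basis[, 2])
  disc <- abs(ds$I[, sel] - total)
  expect_equal(bg2$S, sqrt(ds$S[, sel]^2 + (disc * 0.5)^2),
               tolerance = 1e-12, ignore_attr = TRUE)

  # reconstruction identity: family sums + residual = data at fitted points
  basis_m <- secsaxs:::shape_basis(m$kind, ds$frames[sel], m$shapes)
  fitted <- m$amplitudes %*% t(basis_m)
  fams <- back_generate_frames(m, ds, 1, range(ds$frames[sel]), 0)
  expect_equal(fams$I, fitted, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("decomposition models survive a JSON round trip", {
  sh <- tibble::tibble(family = 1:2, a1 = c(70.5, 110.25), a2 = c(6, 7),
                       a3 = c(12, 12), a4 = c(9, 9))
  m <- secsaxs:::new_decomposition_model("EMG_GMG", sh,
    matrix(runif(10), 5, 2), seq(0.01, 0.05, length.out = 5), c(10, 190),
    TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  expect_equal(back$shapes, m$shapes)
  expect_equal(back$amplitudes, m$amplitudes)
  expect_equal(back$q, m$q)
  expect_equal(back$fit_limits, m$fit_limits)

  # unknown kind tags are rejected; files without a4 load as single-
  # distortion peaks
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$kind <- "SPLINE"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(path), "unknown kind")
  obj$kind <- "EMG"
  obj$shapes$a4 <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  legacy <- load_model(path)
  expect_equal(legacy$shapes$a4, c(0, 0))
})
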