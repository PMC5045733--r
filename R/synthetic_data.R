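# Synthetic SEC-SAXS fixtures. The generator reproduces the statistical
# structure the analysis modules assume: several overlapping (possibly
# skewed) elution peaks whose per-q amplitudes follow species form
# factors, capillary-fouling deposits accumulating in proportion gamma to
# the sample scattering, heteroscedastic Gaussian noise, pure-buffer
# frames, and a band-broadened concentration channel. Every dataset comes
# with its full ground truth so each analysis step can be scored.

#' Describe one synthetic species
#'
#' @param Rg Radius of gyration in Angstrom.
#' @param I0c Forward intensity per unit concentration (scale of the form
#'   factor at q = 0).
#' @param peak A [peak_model()] giving the elution profile; its area `a0`
#'   sets the species' total scattering weight.
#' @param conc_area Area of the species' concentration profile
#'   (mg/ml x frames); the concentration profile is the unit-area elution
#'   shape times this area, so scattering and concentration are strictly
#'   proportional.
#' @param form One of `"guinier"` (pure Guinier curve, exact at all q) or
#'   `"sphere"` (homogeneous sphere of equivalent Rg).
#' @return A list of class `synthetic_species`.
#' @export
synthetic_species <- function(Rg, I0c, peak, conc_area = 1,
                              form = c("guinier", "sphere")) {
  form <- match.arg(form)
  stopifnot(inherits(peak, "peak_model"), Rg > 0, I0c > 0, conc_area > 0)
  structure(list(Rg = Rg, I0c = I0c, peak = peak, conc_area = conc_area,
                 form = form),
            class = "synthetic_species")
}

#' Evaluate a species form factor
#'
#' @param sp A [synthetic_species()].
#' @param q Momentum-transfer grid (1/A).
#' @return Intensity per unit concentration at each q.
#' @export
form_factor <- function(sp, q) {
  switch(sp$form,
    guinier = sp$I0c * exp(-q^2 * sp$Rg^2 / 3),
    sphere = {
      R <- sqrt(5 / 3) * sp$Rg
      x <- q * R
      f <- ifelse(x < 1e-6, 1, 3 * (sin(x) - x * cos(x)) / x^3)
      sp$I0c * f^2
    })
}

#' Specification of a synthetic SEC-SAXS experiment
#'
#' The default layout emulates a poorly resolved oligomer ladder eluting
#' from an analytical SEC column into 240 one-second SAXS exposures: four
#' strongly tailed (EMG+GMG, shared distortions) peaks of species with R_g
#' 95, 63, 52 and 36 Angstrom (largest first), a 100-fold amplitude range,
#' mild capillary fouling, and 1% multiplicative noise with a small
#' additive floor. The q grid is dense enough at low q to hold a dozen
#' points inside the Guinier range of the largest species.
#'
#' @param q q grid in 1/A.
#' @param n_frames Number of frames.
#' @param species List of [synthetic_species()].
#' @param gamma Fouling proportionality, scalar or per-q vector (>= 0);
#'   0 disables fouling.
#' @param noise_frac Noise sd as a fraction of the local noiseless
#'   intensity (default 0.01).
#' @param noise_floor Additive noise-sd floor as a fraction of the maximum
#'   noiseless intensity (default 1e-3).
#' @param n_buffer Number of buffer-only frames for [generate_blanks()].
#' @param broadening_sd Gaussian band-broadening sd (frames) applied to the
#'   concentration channel (default 3).
#' @param seed Integer seed; the dataset is bit-reproducible given it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(q = seq(0.004, 0.2, length.out = 160L),
                           n_frames = 240L,
                           species = default_species(),
                           gamma = 2e-4,
                           noise_frac = 0.01,
                           noise_floor = 1e-3,
                           n_buffer = 60L,
                           broadening_sd = 3,
                           seed = 1L) {
  if (any(gamma < 0)) abort("gamma must be >= 0.")
  if (!(length(gamma) %in% c(1L, length(q)))) {
    abort("gamma must be scalar or one value per q point.")
  }
  structure(list(q = q, n_frames = as.integer(n_frames), species = species,
                 gamma = gamma, noise_frac = noise_frac,
                 noise_floor = noise_floor, n_buffer = as.integer(n_buffer),
                 broadening_sd = broadening_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Default four-species demonstration layout
#'
#' @return A list of four [synthetic_species()] mirroring an oligomer
#'   ladder (tetramer stack): R_g 95, 63, 52, 36 A, the smallest species
#'   dominating, all peaks sharing strongly tailing EMG+GMG distortions
#'   (a3 = 12, a4 = 9 frames on a 6-frame width).
#' @export
default_species <- function() {
  mk <- function(Rg, I0c, a0, a1, conc_area) {
    synthetic_species(Rg, I0c, peak_model("EMG_GMG", a0, a1, 6, 12, 9),
                      conc_area = conc_area)
  }
  list(
    mk(95, 400, 30, 60, 0.4),
    mk(63, 120, 80, 85, 1.2),
    mk(52, 80, 150, 105, 2.5),
    mk(36, 40, 600, 130, 12)
  )
}

#' Generate a synthetic SEC-SAXS dataset with ground truth
#'
#' Builds `I(q, t) = sum_s F_s(q) peak_s(t) + B*(q, t) + noise` where the
#' deposit history follows the fouling recursion `B*(q, t_k) =
#' B*(q, t_{k-1}) + gamma(q) * signal(q, t_{k-1})` (deposits proportional
#' to the sample scattering of the previous frame, zero at the first
#' frame). The noise sd at every point is `noise_frac * I + noise_floor *
#' max(I)` evaluated on the noiseless intensity, and the sigma matrix
#' records these true values.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `dataset` (a `secsaxs_dataset`), `truth` (list with
#'   `signal` and per-`species` surfaces, `baseline` matrix, `gamma`,
#'   `form_factors`, `concentration` tibble of per-frame species
#'   concentrations, `uv_trace` band-broadened detector trace), and the
#'   `spec`.
#' @export
generate_sec_saxs <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  q <- spec$q
  tt <- seq_len(spec$n_frames)
  nq <- length(q); nt <- length(tt)
  FF <- vapply(spec$species, form_factor, numeric(nq), q = q)
  profiles <- vapply(spec$species, function(sp) eval_peak(sp$peak, tt),
                     numeric(nt))
  species_surfaces <- lapply(seq_along(spec$species), function(s) {
    outer(FF[, s], profiles[, s])
  })
  signal <- Reduce(`+`, species_surfaces)
  gamma <- rep_len(spec$gamma, nq)
  B <- matrix(0, nq, nt)
  for (k in 2:nt) {
    B[, k] <- B[, k - 1] + gamma * signal[, k - 1]
  }
  clean <- signal + B
  sig <- spec$noise_frac * clean + spec$noise_floor * max(clean)
  I <- clean + matrix(rnorm(nq * nt, sd = as.vector(sig)), nq, nt)
  ds <- secsaxs_dataset(q, I, sig, frames = tt,
                        meta = list(source = "synthetic", seed = spec$seed))
  conc <- bind_rows(lapply(seq_along(spec$species), function(s) {
    sp <- spec$species[[s]]
    tibble(frame = tt, family = s,
           concentration = sp$conc_area * profiles[, s] / sp$peak$a0)
  }))
  uv <- synth_uv_trace(spec, tt, profiles)
  list(dataset = ds,
       truth = list(signal = signal, species = species_surfaces,
                    baseline = B, gamma = gamma, form_factors = FF,
                    profiles = profiles, concentration = conc,
                    uv_trace = uv),
       spec = spec)
}

# band-broadened UV trace: unit-area elution shapes convolved with a
# discrete Gaussian kernel (area conserved), scaled by the concentration
# areas; absorbance assumes E * pathlength = 1 per family
synth_uv_trace <- function(spec, tt, profiles) {
  if (spec$broadening_sd > 0) {
    half <- ceiling(4 * spec$broadening_sd)
    kern <- dnorm(seq(-half, half), sd = spec$broadening_sd)
    kern <- kern / sum(kern)
  } else {
    kern <- 1
    half <- 0
  }
  broadened <- vapply(seq_along(spec$species), function(s) {
    u <- profiles[, s] / spec$species[[s]]$peak$a0  # unit-area shape
    padded <- c(rep(0, half), u, rep(0, half))
    conv <- vapply(seq_along(u), function(i) {
      sum(padded[i:(i + 2 * half)] * rev(kern))
    }, numeric(1))
    spec$species[[s]]$conc_area * conv
  }, numeric(length(tt)))
  tibble(t = tt, signal = rowSums(broadened))
}

#' Generate buffer-only (blank) frames
#'
#' Zero-mean Gaussian noise frames with the spec's additive noise floor as
#' sd. With `correlate = TRUE` the noise of each frame is averaged over
#' adjacent q points (two-point kernel) and rescaled to keep the marginal
#' sd, emulating the beam-and-pixel smearing that correlates neighbouring
#' detector pixels; sampling every other q then restores independence.
#'
#' @param spec A [synthetic_spec()].
#' @param correlate Impose adjacent-q correlation (default FALSE).
#' @param seed Optional seed overriding `spec$seed + 1`.
#' @return A `secsaxs_dataset` of `spec$n_buffer` frames.
#' @export
generate_blanks <- function(spec, correlate = FALSE, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed %||% (spec$seed + 1L))
  nq <- length(spec$q); nb <- spec$n_buffer
  s0 <- spec$noise_floor  # blank frames: pure floor noise, unit max scale
  E <- matrix(rnorm(nq * nb, sd = s0), nq, nb)
  if (correlate) {
    # two-point moving average: corr 1/2 at lag 1, exactly 0 at lag 2
    E <- (E + rbind(E[-1, , drop = FALSE], E[1, , drop = FALSE])) / sqrt(2)
  }
  secsaxs_dataset(spec$q, E, matrix(s0, nq, nb),
                  meta = list(source = "synthetic blanks",
                              correlated = correlate))
}
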