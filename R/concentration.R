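# Concentration-detector channel: alignment onto the SAXS frame axis,
# decomposition constrained by the SAXS-optimized shapes, band-broadening
# reshaping at conserved area, per-frame concentrations and frame
# normalization.

#' Align a concentration trace with the SAXS frame axis
#'
#' Shifts the trace in time, then linearly interpolates it onto the SAXS
#' frame grid. With `shift = "auto"` the lag is estimated by maximising the
#' cross-correlation with a reference chromatogram. The raw signal units
#' are preserved (rescaling is for display only).
#'
#' @param trace A tibble with columns `t` (frames or seconds on the frame
#'   scale, monotone) and `signal`.
#' @param frames Target frame ordinals (e.g. `ds$frames`).
#' @param shift Lag in frame units to subtract from the trace time base, or
#'   `"auto"`.
#' @param reference Reference chromatogram tibble (`frame`, `intensity`),
#'   required for `shift = "auto"`.
#' @param min_overlap Minimum fraction of `frames` that must fall inside
#'   the shifted trace support (default 0.5).
#' @return A tibble with columns `frame` and `signal`; the applied shift is
#'   stored in attribute `"shift"`.
#' @export
align_trace <- function(trace, frames, shift = 0, reference = NULL,
                        min_overlap = 0.5) {
  if (any(diff(trace$t) <= 0)) abort("trace time base must be monotone.")
  if (identical(shift, "auto")) {
    if (is.null(reference)) abort("`shift = \"auto\"` needs a reference chromatogram.")
    shift <- estimate_shift(trace, reference)
  }
  t_shifted <- trace$t - shift
  inside <- frames >= min(t_shifted) & frames <= max(t_shifted)
  if (mean(inside) < min_overlap) {
    abort("insufficient overlap between shifted trace and frame axis.")
  }
  keep <- frames[inside]
  sig <- approx(t_shifted, trace$signal, xout = keep)$y
  out <- tibble(frame = keep, signal = sig)
  attr(out, "shift") <- shift
  out
}

# integer-lag cross-correlation peak between trace and reference
estimate_shift <- function(trace, reference) {
  on_ref <- function(lag) {
    approx(trace$t - lag, trace$signal, xout = reference$frame)$y
  }
  lags <- seq(-floor(diff(range(reference$frame)) / 2),
              floor(diff(range(reference$frame)) / 2))
  score <- vapply(lags, function(l) {
    y <- on_ref(l)
    ok <- !is.na(y)
    if (sum(ok) < 10) return(-Inf)
    suppressWarnings(stats::cor(y[ok], reference$intensity[ok]))
  }, numeric(1))
  lags[which.max(score)]
}

#' Fit the concentration trace with the SAXS peak set
#'
#' Least-squares decomposition of the aligned concentration signal using
#' the SAXS-optimized peak families: centers may move by at most
#' `center_tolerance` (relative, 2% by default) from the SAXS values,
#' widths are kept fixed by default (widths and distortions are strongly
#' coupled at this step), distortions and areas are free. Concentration
#' traces usually carry no uncertainties, so the fit is unweighted and
#' residuals are reported on an absolute scale.
#'
#' @param aligned A tibble from [align_trace()] (`frame`, `signal`).
#' @param saxs_model A `decomposition_model` (SAXS-optimized shapes).
#' @param center_tolerance Relative center bound (default 0.02).
#' @param widths_fixed Keep widths at the SAXS values (default TRUE).
#' @param maxiter Levenberg-Marquardt iteration cap.
#' @return A list of class `concentration_fit`: `peaks` (list of
#'   [peak_model()] with the fitted areas), `shapes` (tibble), `fitted`,
#'   `residuals`, `saxs_shapes`, `kind`.
#' @export
fit_concentration <- function(aligned, saxs_model, center_tolerance = 0.02,
                              widths_fixed = TRUE, maxiter = 200L) {
  stopifnot(inherits(saxs_model, "decomposition_model"))
  N <- nrow(saxs_model$shapes)
  kind <- saxs_model$kind
  nd <- n_distortions(kind)
  t <- aligned$frame; y <- aligned$signal
  sh0 <- saxs_model$shapes
  # parameter vector: centers (bounded), widths (maybe frozen), distortions
  theta0 <- as.numeric(c(sh0$a1, sh0$a2,
                         if (nd >= 1) sh0$a3, if (nd >= 2) sh0$a4))
  span <- diff(range(t))
  lo_c <- sh0$a1 * (1 - center_tolerance)
  hi_c <- sh0$a1 * (1 + center_tolerance)
  lo_w <- if (widths_fixed) sh0$a2 else pmax(sh0$a2 * 0.2, 0.5)
  hi_w <- if (widths_fixed) sh0$a2 else sh0$a2 * 5
  lower <- as.numeric(c(lo_c, lo_w, rep(-span, nd * N)))
  upper <- as.numeric(c(hi_c, hi_w, rep(span, nd * N)))
  unpack <- function(theta) {
    tibble(family = seq_len(N),
           a1 = theta[seq_len(N)],
           a2 = theta[N + seq_len(N)],
           a3 = if (nd >= 1) theta[2 * N + seq_len(N)] else rep(0, N),
           a4 = if (nd >= 2) theta[3 * N + seq_len(N)] else rep(0, N))
  }
  resid_fn <- function(theta) {
    shapes <- unpack(theta)
    basis <- shape_basis(kind, t, shapes)
    amp <- solve_amplitudes(basis, y, rep(1, length(y)))
    y - as.vector(basis %*% amp)
  }
  fit <- minpack.lm::nls.lm(par = theta0, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxiter))
  if (!fit$info %in% 1:4) {
    warn("concentration fit did not fully converge; returning best found.")
  }
  shapes <- unpack(fit$par)
  basis <- shape_basis(kind, t, shapes)
  amp <- solve_amplitudes(basis, y, rep(1, length(y)))
  fitted <- as.vector(basis %*% amp)
  peaks <- lapply(seq_len(N), function(f) {
    peak_model(kind, amp[f], shapes$a1[f], shapes$a2[f], shapes$a3[f],
               shapes$a4[f])
  })
  structure(list(peaks = peaks, shapes = mutate(shapes, a0 = amp),
                 fitted = fitted, residuals = y - fitted,
                 frame = t, signal = y,
                 saxs_shapes = sh0, kind = kind),
            class = "concentration_fit")
}

#' @export
print.concentration_fit <- function(x, ...) {
  cat("<concentration_fit> ", length(x$peaks), " x ", x$kind,
      " families, rms residual = ",
      format(sqrt(mean(x$residuals^2)), digits = 4), "\n", sep = "")
  print(x$shapes)
  invisible(x)
}

#' @export
tidy.concentration_fit <- function(x, ...) x$shapes

#' Reshape concentration peaks onto the SAXS shapes
#'
#' Band broadening between the concentration detector and the SAXS cell
#' widens the concentration peaks relative to the scattering peaks. The
#' reshaped profile keeps each concentration family's fitted area but takes
#' the SAXS family's center, width and distortions, so each reshaped family
#' is pointwise proportional to its SAXS counterpart. Area conservation is
#' exact by construction.
#'
#' @param conc_fit A [fit_concentration()] result.
#' @param saxs_model The `decomposition_model` supplying the shapes.
#' @return A list of class `reshaped_concentration`: `peaks` (SAXS shapes
#'   with concentration areas), `shapes` (tibble).
#' @export
reshape_concentration <- function(conc_fit, saxs_model) {
  stopifnot(inherits(conc_fit, "concentration_fit"),
            inherits(saxs_model, "decomposition_model"))
  if (nrow(saxs_model$shapes) != length(conc_fit$peaks)) {
    abort("family count mismatch between concentration fit and SAXS model.")
  }
  sh <- saxs_model$shapes
  areas <- vapply(conc_fit$peaks, function(p) p$a0, numeric(1))
  peaks <- lapply(seq_along(areas), function(f) {
    peak_model(saxs_model$kind, areas[f], sh$a1[f], sh$a2[f], sh$a3[f],
               sh$a4[f])
  })
  structure(list(peaks = peaks,
                 shapes = mutate(sh, a0 = areas),
                 kind = saxs_model$kind),
            class = "reshaped_concentration")
}

#' Evaluate a set of concentration peaks on a frame grid
#'
#' @param peaks A list of [peak_model()] objects (e.g. from
#'   [reshape_concentration()]).
#' @param frames Frame ordinals.
#' @return A tibble: `frame`, one `family_<i>` column per peak, `total`.
#' @export
evaluate_concentration <- function(peaks, frames) {
  vals <- vapply(peaks, function(p) eval_peak(p, frames),
                 numeric(length(frames)))
  out <- as_tibble(as.data.frame(vals))
  names(out) <- paste0("family_", seq_along(peaks))
  out <- bind_cols(tibble(frame = frames), out)
  out$total <- rowSums(vals)
  out
}

#' Per-frame concentrations from concentration peaks
#'
#' Converts each family's detector signal into mg/ml:
#' `c(family, t) = signal(t) / (E * pathlength)` for a UV signal in
#' absorbance units with extinction coefficient `E` in ml/(mg cm). A
#' refractive-index channel uses dn/dc in place of `E` analogously.
#'
#' @param peaks A list of [peak_model()] objects (reshaped concentration
#'   families).
#' @param frames Frame ordinals.
#' @param extinction Numeric vector (recycled) of extinction coefficients
#'   in ml/(mg cm), one per family.
#' @param pathlength_cm Detector path length (default 1 cm).
#' @return A tibble: `frame`, `family`, `concentration` (mg/ml).
#' @export
frame_concentrations <- function(peaks, frames, extinction,
                                 pathlength_cm = 1) {
  if (length(extinction) == 0 || any(!is.finite(extinction)) ||
      any(extinction <= 0)) {
    abort("extinction coefficients must be positive and finite.")
  }
  extinction <- rep_len(extinction, length(peaks))
  rows <- lapply(seq_along(peaks), function(f) {
    tibble(frame = frames, family = f,
           concentration = eval_peak(peaks[[f]], frames) /
             (extinction[f] * pathlength_cm))
  })
  bind_rows(rows)
}

#' Normalize frames by their concentrations
#'
#' Divides each frame's intensity and sigma by its concentration and
#' computes the inverse-variance-weighted average curve of the normalized
#' frames. For a single pure species the normalized frames should
#' superimpose within noise.
#'
#' @param ds A `secsaxs_dataset` (e.g. back-generated species frames).
#' @param conc A tibble with columns `frame` and `concentration` covering
#'   the dataset's frames, all positive.
#' @return A list: `normalized` (dataset), `average` (tibble `q`,
#'   `intensity`, `sigma` of the weighted mean curve).
#' @export
normalize_frames <- function(ds, conc) {
  stopifnot(inherits(ds, "secsaxs_dataset"))
  cvec <- conc$concentration[match(ds$frames, conc$frame)]
  if (anyNA(cvec)) abort("concentrations missing for some frames.")
  if (any(cvec <= 0)) abort("concentrations must be strictly positive.")
  I <- sweep(ds$I, 2, cvec, "/")
  S <- sweep(ds$S, 2, cvec, "/")
  nds <- secsaxs_dataset(ds$q, I, S, frames = ds$frames, time = ds$time,
                         meta = c(ds$meta, list(normalized = TRUE)))
  w <- 1 / S^2
  avg_I <- rowSums(I * w) / rowSums(w)
  avg_S <- sqrt(1 / rowSums(w))
  list(normalized = nds,
       average = tibble(q = ds$q, intensity = avg_I, sigma = avg_S))
}
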