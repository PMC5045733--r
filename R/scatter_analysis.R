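# Guinier fitting and scans, Rambo-Tainer and absolute-scale molecular
# mass, the chi * r_sigma goodness-of-fit score, and non-negative
# least-squares combination of model curves.

#' Guinier fit of a scattering curve
#'
#' Weighted linear regression of `ln I` on `q^2` (weights `(I / sigma)^2`,
#' i.e. `sigma_lnI = sigma / I`), giving the z-average radius of gyration
#' `R_g = sqrt(-3 slope)` and forward intensity `I0 = exp(intercept)`. In
#' automatic mode the upper limit is shrunk iteratively (at most 20 rounds)
#' until `q_max * R_g <= qmaxRg_limit` (default 1.3).
#'
#' @param frame A tibble with columns `q`, `intensity`, `sigma`.
#' @param q_range Optional length-2 fit interval; when `NULL` the upper
#'   limit is chosen automatically from `qmaxRg_limit`.
#' @param qmaxRg_limit Automatic-mode limit on `q_max * R_g`.
#' @param min_points Minimum number of positive-intensity points (default 5).
#' @return A list of class `guinier_result`: `Rg`, `Rg_sd`, `I0`, `I0_sd`,
#'   `q_min`, `q_max`, `qmaxRg`, `chi2`, `n_points`, `ok`, `warnings`.
#'   Unphysical fits (non-negative slope) return `ok = FALSE` with `Rg`
#'   `NA`.
#' @export
guinier_fit <- function(frame, q_range = NULL, qmaxRg_limit = 1.3,
                        min_points = 5L) {
  stopifnot(all(c("q", "intensity", "sigma") %in% names(frame)))
  auto <- is.null(q_range)
  if (auto) q_range <- range(frame$q)
  fit_once <- function(qmax) {
    sel <- frame$q >= q_range[1] & frame$q <= qmax & frame$intensity > 0 &
      frame$sigma > 0
    if (sum(sel) < min_points) return(NULL)
    q2 <- frame$q[sel]^2
    y <- log(frame$intensity[sel])
    w <- (frame$intensity[sel] / frame$sigma[sel])^2
    fit <- lm(y ~ q2, weights = w)
    slope <- coef(fit)[[2]]
    list(fit = fit, slope = slope, sel = sel,
         Rg = if (slope < 0) sqrt(-3 * slope) else NA_real_,
         q_max = max(frame$q[sel]))
  }
  res <- fit_once(q_range[2])
  if (is.null(res)) abort("fewer than `min_points` usable points in range.")
  warnings <- character(0)
  if (auto && !is.na(res$Rg)) {
    for (k in seq_len(20L)) {
      if (res$q_max * res$Rg <= qmaxRg_limit) break
      nxt <- fit_once(qmaxRg_limit / res$Rg)
      if (is.null(nxt) || is.na(nxt$Rg)) {
        warnings <- c(warnings, "auto q_max hit the minimum point count")
        break
      }
      if (abs(nxt$q_max - res$q_max) < 1e-12) { res <- nxt; break }
      res <- nxt
    }
  }
  if (is.na(res$Rg)) {
    return(structure(list(Rg = NA_real_, Rg_sd = NA_real_, I0 = NA_real_,
                          I0_sd = NA_real_, q_min = q_range[1],
                          q_max = res$q_max, qmaxRg = NA_real_,
                          chi2 = NA_real_, n_points = sum(res$sel),
                          ok = FALSE,
                          warnings = c(warnings, "positive Guinier slope (unphysical)")),
                     class = "guinier_result"))
  }
  fit <- res$fit
  cv <- vcov(fit)
  slope <- coef(fit)[[2]]; icpt <- coef(fit)[[1]]
  Rg <- sqrt(-3 * slope)
  Rg_sd <- 3 / (2 * Rg) * sqrt(cv[2, 2])
  I0 <- exp(icpt)
  I0_sd <- I0 * sqrt(cv[1, 1])
  rss <- sum(fit$weights * fit$residuals^2)
  structure(list(Rg = Rg, Rg_sd = Rg_sd, I0 = I0, I0_sd = I0_sd,
                 q_min = min(frame$q[res$sel]), q_max = res$q_max,
                 qmaxRg = res$q_max * Rg,
                 chi2 = rss / max(sum(res$sel) - 2, 1),
                 n_points = sum(res$sel), ok = TRUE, warnings = warnings),
            class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  if (x$ok) {
    cat(sprintf("<guinier_result> Rg = %.2f +/- %.2f A, I0 = %.4g +/- %.2g\n",
                x$Rg, x$Rg_sd, x$I0, x$I0_sd))
    cat(sprintf("  q range %.4g..%.4g (qmax*Rg = %.2f, n = %d, chi2 = %.3g)\n",
                x$q_min, x$q_max, x$qmaxRg, x$n_points, x$chi2))
  } else {
    cat("<guinier_result> rejected:", paste(x$warnings, collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
glance.guinier_result <- function(x, ...) {
  tibble(Rg = x$Rg, Rg_sd = x$Rg_sd, I0 = x$I0, I0_sd = x$I0_sd,
         q_min = x$q_min, q_max = x$q_max, qmaxRg = x$qmaxRg,
         chi2 = x$chi2, n_points = x$n_points, ok = x$ok)
}

#' Guinier scan over a frame series
#'
#' Applies [guinier_fit()] to every frame and flags R_g drift across the
#' series (a mixture indicator: more than one species contributing per
#' frame).
#'
#' @param ds A `secsaxs_dataset` (or list of frame tibbles).
#' @param drift_tol Relative spread of R_g (robust, median-based) above
#'   which the series is flagged as drifting (default 0.02).
#' @param ... Passed to [guinier_fit()].
#' @return A tibble with one row per frame (`frame`, `Rg`, `Rg_sd`, `I0`,
#'   `I0_sd`, `qmaxRg`, `ok`); attribute `"drift"` is `TRUE` when the
#'   relative R_g spread exceeds `drift_tol`.
#' @export
guinier_scan <- function(ds, drift_tol = 0.02, ...) {
  frames <- if (inherits(ds, "secsaxs_dataset")) {
    setNames(lapply(ds$frames, function(f) get_frame(ds, f)), ds$frames)
  } else ds
  rows <- imap(frames, function(fr, nm) {
    g <- tryCatch(guinier_fit(fr, ...), error = function(e) NULL)
    if (is.null(g)) {
      tibble(frame = as.numeric(nm), Rg = NA_real_, Rg_sd = NA_real_,
             I0 = NA_real_, I0_sd = NA_real_, qmaxRg = NA_real_, ok = FALSE)
    } else {
      tibble(frame = as.numeric(nm), Rg = g$Rg, Rg_sd = g$Rg_sd, I0 = g$I0,
             I0_sd = g$I0_sd, qmaxRg = g$qmaxRg, ok = g$ok)
    }
  })
  out <- bind_rows(rows)
  rg <- out$Rg[out$ok & !is.na(out$Rg)]
  attr(out, "drift") <- length(rg) > 1 &&
    (max(rg) - min(rg)) / median(rg) > drift_tol
  out
}

#' Rambo-Tainer molecular mass
#'
#' Computes the volume of correlation `V_c = I(0) / integral(q I(q) dq)`
#' with the integral taken up to `q_integral_max` (default 0.2 inverse
#' Angstrom) and the unmeasured low-q gap filled by the fitted Guinier
#' model from q = 0; then `Q_R = V_c^2 / R_g` and `M_w = (Q_R / c1)^c2 / 1000`
#' in kg/mol, with the protein constants `c1 = 0.1231`, `c2 = 1` of the
#' volume-of-correlation method (which yield g/mol). Warnings are issued
#' when the measured range falls short of `q_integral_max` or when
#' non-default settings are used. The calibration constants are empirical,
#' derived from real protein scattering curves; idealized shapes such as
#' homogeneous spheres read systematically low (by roughly a third) against
#' them.
#'
#' @param frame A tibble with columns `q`, `intensity` (`sigma` optional).
#' @param guinier A [guinier_fit()] result for this frame (`ok` must be
#'   `TRUE`).
#' @param q_integral_max Integration cutoff (default 0.2).
#' @param c1,c2 Mass-scaling constants (protein defaults).
#' @return A list: `Mw` (kg/mol), `Vc`, `Qr`, `warnings`.
#' @export
mw_rambo_tainer <- function(frame, guinier, q_integral_max = 0.2,
                            c1 = 0.1231, c2 = 1.0) {
  if (!isTRUE(guinier$ok)) abort("need an accepted Guinier fit.")
  warnings <- character(0)
  if (max(frame$q) < q_integral_max) {
    warnings <- c(warnings, sprintf(
      "available q range (%.3g) is below the %.3g cutoff; mass estimate may be unreliable",
      max(frame$q), q_integral_max))
  }
  if (q_integral_max != 0.2) {
    warnings <- c(warnings, "non-default integration cutoff; mass estimate may be unreliable")
  }
  sel <- frame$q <= q_integral_max
  qs <- frame$q[sel]; Is <- frame$intensity[sel]
  # fill [0, min(q)) with the Guinier extrapolation
  if (min(qs) > 0) {
    q_gap <- seq(0, min(qs), length.out = 50L)
    I_gap <- guinier$I0 * exp(-q_gap^2 * guinier$Rg^2 / 3)
    qs <- c(head(q_gap, -1L), qs)
    Is <- c(head(I_gap, -1L), Is)
  }
  integrand <- qs * Is
  integral <- sum(diff(qs) * (head(integrand, -1) + tail(integrand, -1)) / 2)
  if (integral <= 0) abort("non-positive q*I integral.")
  Vc <- guinier$I0 / integral
  Qr <- Vc^2 / guinier$Rg
  list(Mw = (Qr / c1)^c2 / 1000, Vc = Vc, Qr = Qr, warnings = warnings)
}

# electrons per gram of typical protein and classical electron radius (cm)
PROTEIN_E_PER_GRAM <- 3.22e23
R_ELECTRON_CM <- 2.8179403e-13
N_AVOGADRO <- 6.02214076e23

#' Molecular mass from absolute-scale forward intensity
#'
#' `M_w = I0 * N_A / (c * drho_M^2)` with the scattering contrast per unit
#' mass `drho_M = r_e (n_e - rho_solv * vbar)`: `n_e` electrons per gram of
#' protein, `rho_solv` the solvent electron density and `vbar` the partial
#' specific volume.
#'
#' @param I0_abs Forward intensity on absolute scale (1/cm).
#' @param c Concentration in mg/ml.
#' @param vbar Partial specific volume in ml/g (protein default 0.736).
#' @param solvent_e_density Solvent electron density in electrons per cubic
#'   nanometer (water default 334).
#' @param e_per_gram Electrons per gram of dry material.
#' @return Molecular mass in kg/mol.
#' @export
mw_from_absolute_scale <- function(I0_abs, c, vbar = 0.736,
                                   solvent_e_density = 334,
                                   e_per_gram = PROTEIN_E_PER_GRAM) {
  if (c <= 0) abort("concentration must be positive.")
  rho_solv_cm3 <- solvent_e_density * 1e21  # e/nm^3 -> e/cm^3
  drho_M <- R_ELECTRON_CM * (e_per_gram - rho_solv_cm3 * vbar)
  if (drho_M <= 0) abort("non-positive contrast (contrast-matched solvent).")
  c_g_cm3 <- c * 1e-3  # mg/ml -> g/cm^3
  (I0_abs * N_AVOGADRO / (c_g_cm3 * drho_M^2)) / 1000  # g/mol -> kg/mol
}

#' Chi and r_sigma goodness-of-fit statistics
#'
#' `chi = sqrt( sum(((I_exp - s I_calc) / sigma)^2) / (n - 1) )` with an
#' optional closed-form optimal multiplicative scale `s`, and
#' `r_sigma = sqrt(mean(sigma^2))` (RMS of the uncertainties). Their
#' product `chi * r_sigma` is invariant under a global rescaling of the
#' sigmas, making it independent of the data set's overall noise level.
#'
#' @param I_exp,I_calc Experimental and calculated intensities.
#' @param sigma_exp Experimental standard deviations (> 0).
#' @param fit_scale Optimize a multiplicative scale on `I_calc`?
#' @param rsigma_form `"rms"` (default) or `"mean"` of the sigmas.
#' @return A list of class `fit_statistics`: `chi`, `r_sigma`,
#'   `chi_r_sigma`, `n`, `scale`.
#' @export
chi_and_rsigma <- function(I_exp, I_calc, sigma_exp, fit_scale = TRUE,
                           rsigma_form = c("rms", "mean")) {
  rsigma_form <- match.arg(rsigma_form)
  n <- length(I_exp)
  if (n < 2) abort("need at least 2 points.")
  if (length(I_calc) != n || length(sigma_exp) != n) {
    abort("inputs must have equal length.")
  }
  if (any(sigma_exp <= 0)) abort("sigma must be strictly positive.")
  w <- 1 / sigma_exp^2
  s <- if (fit_scale) sum(w * I_exp * I_calc) / sum(w * I_calc^2) else 1
  chi <- sqrt(sum(((I_exp - s * I_calc) / sigma_exp)^2) / (n - 1))
  r_sigma <- if (rsigma_form == "rms") sqrt(mean(sigma_exp^2)) else
    mean(sigma_exp)
  structure(list(chi = chi, r_sigma = r_sigma, chi_r_sigma = chi * r_sigma,
                 n = n, scale = s),
            class = "fit_statistics")
}

#' Non-negative least-squares combination of model curves
#'
#' Finds sigma-weighted non-negative weights combining the model curves to
#' best fit the target, and also scores each single curve by
#' `chi * r_sigma` to report the best individual model. Model curves not on
#' the target grid are linearly interpolated (and this is recorded).
#'
#' @param target A tibble with columns `q`, `intensity`, `sigma`.
#' @param models A named list of tibbles with columns `q`, `intensity`
#'   (or numeric vectors already on the target grid).
#' @return A list of class `nnls_result`: `weights` (named, summing to the
#'   fitted total), `percent` (weights as percentages of their sum),
#'   `stats` ([chi_and_rsigma()] of the combination, scale fixed at 1),
#'   `best_single` (name), `single_scores` (named chi*r_sigma scores),
#'   `interpolated` (logical per model).
#' @export
nnls_combination <- function(target, models) {
  if (length(models) == 0) abort("empty model basis.")
  if (is.null(names(models))) names(models) <- paste0("model", seq_along(models))
  interpolated <- logical(length(models))
  basis <- vapply(seq_along(models), function(k) {
    m <- models[[k]]
    if (is.numeric(m)) return(m)
    if (length(m$q) == length(target$q) &&
        all(abs(m$q - target$q) < 1e-10)) {
      m$intensity
    } else {
      interpolated[k] <<- TRUE
      approx(m$q, m$intensity, xout = target$q, rule = 2)$y
    }
  }, numeric(nrow(target)))
  colnames(basis) <- names(models)
  w <- 1 / target$sigma
  sol <- pracma::lsqnonneg(basis * w, target$intensity * w)
  weights <- setNames(sol$x, names(models))
  combo <- as.vector(basis %*% weights)
  stats <- chi_and_rsigma(target$intensity, combo, target$sigma,
                          fit_scale = FALSE)
  singles <- vapply(seq_along(models), function(k) {
    chi_and_rsigma(target$intensity, basis[, k], target$sigma,
                   fit_scale = TRUE)$chi_r_sigma
  }, numeric(1))
  names(singles) <- names(models)
  total <- sum(weights)
  structure(list(weights = weights,
                 percent = if (total > 0) 100 * weights / total else weights,
                 stats = stats,
                 best_single = names(models)[which.min(singles)],
                 single_scores = singles,
                 interpolated = setNames(interpolated, names(models))),
            class = "nnls_result")
}

#' @export
print.nnls_result <- function(x, ...) {
  nz <- x$percent[x$weights > 0]
  cat("<nnls_result> combination ",
      paste(sprintf("%s:%.0f%%", names(nz), nz), collapse = " "),
      "\n  chi*r_sigma = ", format(x$stats$chi_r_sigma, digits = 4),
      "; best single: ", x$best_single, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.nnls_result <- function(x, ...) {
  tibble(model = names(x$weights), weight = unname(x$weights),
         percent = unname(x$percent),
         single_score = unname(x$single_scores),
         interpolated = unname(x$interpolated))
}
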