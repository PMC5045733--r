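# Multi-peak decomposition of SEC-SAXS chromatograms. Each elution
# component is a "peak family": one shape (center, width, distortions)
# shared by every q value, with a per-q amplitude (area). Shapes are
# optimized by bounded Levenberg-Marquardt least squares; for any trial
# shape the amplitudes are the exact solution of a non-negative linear
# problem, so the nonlinear search runs over the shared shape parameters
# only (variable projection). Distortions are common to all families by
# default, mirroring the assumption that all species interact with the
# column matrix in the same way.

n_distortions <- function(kind) {
  switch(kind, GAUSS = 0L, EMG = 1L, GMG = 1L, EMG_GMG = 2L)
}

# evaluate the unit-area shape of family f given the shape parameter tables
unit_shape <- function(kind, t, a1, a2, a3 = 0, a4 = 0) {
  p <- peak_model(kind, 1, a1, a2, a3, a4)
  eval_peak(p, t)
}

# n_t x N matrix of unit-area family shapes
shape_basis <- function(kind, t, shapes) {
  vapply(seq_len(nrow(shapes)), function(f) {
    unit_shape(kind, t, shapes$a1[f], shapes$a2[f], shapes$a3[f], shapes$a4[f])
  }, numeric(length(t)))
}

# non-negative weighted amplitude solve for one chromatogram
solve_amplitudes <- function(basis, y, sigma) {
  w <- 1 / sigma
  sol <- pracma::lsqnonneg(basis * w, y * w)
  sol$x
}

# pack/unpack shared shape parameters <-> optimizer vector.
# Centers are parameterized as (first center, positive gaps) so family
# identity is stable: centers can never cross during the fit.
pack_theta <- function(shapes, kind, common_distortion) {
  ctr <- shapes$a1
  th <- c(ctr[1], if (length(ctr) > 1) diff(ctr), shapes$a2)
  nd <- n_distortions(kind)
  if (nd >= 1) {
    th <- c(th, if (common_distortion) shapes$a3[1] else shapes$a3)
  }
  if (nd >= 2) {
    th <- c(th, if (common_distortion) shapes$a4[1] else shapes$a4)
  }
  as.numeric(th)
}

unpack_theta <- function(theta, N, kind, common_distortion) {
  ctr <- cumsum(theta[seq_len(N)])
  a2 <- theta[N + seq_len(N)]
  used <- 2L * N
  nd <- n_distortions(kind)
  a3 <- rep(0, N); a4 <- rep(0, N)
  if (nd >= 1) {
    if (common_distortion) {
      a3 <- rep(theta[used + 1L], N); used <- used + 1L
    } else {
      a3 <- theta[used + seq_len(N)]; used <- used + N
    }
  }
  if (nd >= 2) {
    if (common_distortion) {
      a4 <- rep(theta[used + 1L], N); used <- used + 1L
    } else {
      a4 <- theta[used + seq_len(N)]; used <- used + N
    }
  }
  tibble(family = seq_len(N), a1 = ctr, a2 = a2, a3 = a3, a4 = a4)
}

theta_bounds <- function(N, kind, common_distortion, t_range,
                         min_gap = 0.5, min_width = 0.5) {
  span <- diff(t_range)
  nd <- n_distortions(kind)
  n_dist <- if (nd == 0L) 0L else if (common_distortion) nd else nd * N
  lower <- c(t_range[1], rep(min_gap, N - 1), rep(min_width, N),
             rep(-span, n_dist))
  upper <- c(t_range[2], rep(span, N - 1), rep(span, N),
             rep(span, n_dist))
  list(lower = as.numeric(lower), upper = as.numeric(upper))
}

default_fit_limits <- function(frames, exclude_frac = 0.05) {
  n <- length(frames)
  k <- floor(n * exclude_frac)
  c(frames[k + 1L], frames[n - k])
}

#' SVD spectrum and suggested component count
#'
#' Singular value decomposition of the intensity matrix restricted to
#' `frame_range`, with an advisory component-count suggestion from the
#' largest ratio gap in the leading singular values. The full spectrum is
#' returned so the user makes the final call.
#'
#' @param ds A `secsaxs_dataset`.
#' @param frame_range Optional length-2 frame-ordinal range of signal
#'   frames.
#' @param max_consider Upper bound on the suggested count (default 8).
#' @return A list: `singular_values`, `suggested_n`, `ratios`
#'   (`sv[i] / sv[i+1]`).
#' @export
svd_rank <- function(ds, frame_range = NULL, max_consider = 8L) {
  stopifnot(inherits(ds, "secsaxs_dataset"))
  M <- ds$I
  if (!is.null(frame_range)) {
    M <- M[, ds$frames >= frame_range[1] & ds$frames <= frame_range[2],
           drop = FALSE]
  }
  if (min(dim(M)) < 2) abort("degenerate matrix: need at least 2 x 2.")
  sv <- svd(M, nu = 0, nv = 0)$d
  kmax <- min(max_consider, length(sv) - 1L)
  ratios <- sv[seq_len(kmax)] / sv[seq_len(kmax) + 1L]
  list(singular_values = sv, suggested_n = which.max(ratios),
       ratios = ratios)
}

#' Fit one chromatogram with N peaks
#'
#' Weighted (1 / sigma^2) nonlinear least squares of `N` peaks of the given
#' kind to a single chromatogram. Shapes are optimized by bounded
#' Levenberg-Marquardt; at every trial shape the peak areas are solved
#' exactly as a non-negative linear subproblem. Centers are ordered by
#' construction (first center plus positive gaps), and distortions are tied
#' across peaks unless `common_distortion = FALSE`.
#'
#' @param chrom A tibble with columns `frame`, `intensity`, `sigma`.
#' @param N Number of peaks (>= 1).
#' @param kind Peak shape: `"GAUSS"`, `"EMG"`, `"GMG"` or `"EMG_GMG"`.
#' @param init_centers Numeric vector of `N` initial centers (frames).
#'   `NULL` picks the `N` highest well-separated local maxima.
#' @param init_widths,init_distortion Optional initial values; the default
#'   distortion start is a quarter of the initial width (a mild tailing
#'   guess), which keeps the skew parameters away from the locally flat
#'   symmetric point.
#' @param common_distortion Tie distortions across peaks (default TRUE).
#' @param fit_limits Length-2 frame interval used in the residual (default:
#'   all but the first and last 5% of frames).
#' @param maxiter Levenberg-Marquardt iteration cap.
#' @return A list of class `single_fit`: `peaks` (list of [peak_model()]),
#'   `shapes` (tibble), `kind`, `fit_limits`, `converged`, `ssr`,
#'   `fitted` (model curve on the chromatogram's frames), `chrom`.
#' @export
fit_single <- function(chrom, N, kind = "EMG_GMG", init_centers = NULL,
                       init_widths = NULL, init_distortion = NULL,
                       common_distortion = TRUE, fit_limits = NULL,
                       maxiter = 200L) {
  kind <- match.arg(toupper(kind), peak_kinds)
  N <- as.integer(N)
  if (N < 1) abort("N must be >= 1.")
  t <- chrom$frame
  if (is.null(fit_limits)) fit_limits <- default_fit_limits(t)
  sel <- t >= fit_limits[1] & t <= fit_limits[2]
  ts <- t[sel]; ys <- chrom$intensity[sel]; ss <- chrom$sigma[sel]
  if (is.null(init_centers)) {
    init_centers <- pick_local_maxima(ts, ys, N)
  }
  init_centers <- sort(init_centers)
  if (length(init_centers) != N) abort("need N initial centers.")
  span <- diff(range(ts))
  if (is.null(init_widths)) init_widths <- rep(span / (4 * N), N)
  if (is.null(init_distortion)) init_distortion <- mean(init_widths) / 4
  shapes0 <- tibble(family = seq_len(N), a1 = init_centers, a2 = init_widths,
                    a3 = rep(init_distortion, N), a4 = rep(init_distortion, N))
  theta0 <- pack_theta(shapes0, kind, common_distortion)
  bnd <- theta_bounds(N, kind, common_distortion, range(ts))
  resid_fn <- function(theta) {
    shapes <- unpack_theta(theta, N, kind, common_distortion)
    basis <- shape_basis(kind, ts, shapes)
    amp <- solve_amplitudes(basis, ys, ss)
    (ys - as.vector(basis %*% amp)) / ss
  }
  fit <- minpack.lm::nls.lm(par = theta0, lower = bnd$lower,
                            upper = bnd$upper, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxiter))
  shapes <- unpack_theta(fit$par, N, kind, common_distortion)
  basis <- shape_basis(kind, ts, shapes)
  amp <- solve_amplitudes(basis, ys, ss)
  peaks <- lapply(seq_len(N), function(f) {
    peak_model(kind, amp[f], shapes$a1[f], shapes$a2[f], shapes$a3[f],
               shapes$a4[f])
  })
  fitted_all <- as.vector(shape_basis(kind, t, shapes) %*% amp)
  converged <- fit$info %in% 1:4
  if (!converged) {
    warn(paste0("single fit did not fully converge (info = ", fit$info,
                "); returning best parameters found."))
  }
  structure(list(peaks = peaks, shapes = mutate(shapes, a0 = amp),
                 kind = kind, fit_limits = fit_limits,
                 common_distortion = common_distortion,
                 converged = converged, ssr = sum(resid_fn(fit$par)^2),
                 fitted = fitted_all, chrom = chrom),
            class = "single_fit")
}

# N highest local maxima, greedily separated by at least span/(2N)
pick_local_maxima <- function(t, y, N) {
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  cand <- order(y, decreasing = TRUE)
  cand <- cand[is_max[cand] | cand %in% which.max(y)]
  min_sep <- diff(range(t)) / (2 * N)
  picked <- numeric(0)
  for (i in cand) {
    if (all(abs(t[i] - picked) >= min_sep)) picked <- c(picked, t[i])
    if (length(picked) == N) break
  }
  if (length(picked) < N) {
    picked <- c(picked, seq(min(t), max(t), length.out = N + 2)[2:(N + 1)]
                [seq_len(N - length(picked))])
  }
  sort(picked)
}

#' @export
print.single_fit <- function(x, ...) {
  cat("<single_fit> ", length(x$peaks), " x ", x$kind,
      if (x$converged) " (converged)" else " (NOT converged)",
      ", ssr = ", format(x$ssr, digits = 5), "\n", sep = "")
  print(x$shapes)
  invisible(x)
}

#' @export
tidy.single_fit <- function(x, ...) x$shapes

#' Plot a single-chromatogram fit
#'
#' @param object A `single_fit`.
#' @param ... Unused.
#' @return A ggplot: data, total fit and individual components, with the
#'   fit limits marked.
#' @export
autoplot.single_fit <- function(object, ...) {
  t <- object$chrom$frame
  comp <- purrr::imap(object$peaks, function(p, i) {
    tibble(frame = t, intensity = eval_peak(p, t),
           series = paste0("peak ", i))
  })
  df <- bind_rows(
    tibble(frame = t, intensity = object$chrom$intensity, series = "data"),
    tibble(frame = t, intensity = object$fitted, series = "fit"),
    bind_rows(comp)
  )
  ggplot(df, aes(x = .data$frame, y = .data$intensity,
                 color = .data$series)) +
    geom_line() +
    geom_vline(xintercept = object$fit_limits, linetype = 2,
               color = "red") +
    labs(x = "frame", y = "intensity") +
    theme_bw()
}

new_decomposition_model <- function(kind, shapes, amplitudes, q, fit_limits,
                                    common_distortion, fit_report = NULL) {
  structure(list(kind = kind, shapes = shapes, amplitudes = amplitudes,
                 q = q, fit_limits = fit_limits,
                 common_distortion = common_distortion,
                 fit_report = fit_report),
            class = "decomposition_model")
}

#' @export
print.decomposition_model <- function(x, ...) {
  cat("<decomposition_model> ", nrow(x$shapes), " x ", x$kind,
      " families, amplitudes for ", length(x$q), " q values\n", sep = "")
  print(x$shapes)
  invisible(x)
}

#' @export
tidy.decomposition_model <- function(x, ...) x$shapes

#' Amplitude table of a decomposition model
#'
#' @param model A `decomposition_model`.
#' @return A tibble: `q`, `family`, `a0`.
#' @export
amplitude_table <- function(model) {
  stopifnot(inherits(model, "decomposition_model"))
  N <- nrow(model$shapes)
  tibble(q = rep(model$q, times = N),
         family = rep(seq_len(N), each = length(model$q)),
         a0 = as.vector(model$amplitudes))
}

# columns of ds selected by q values (exact grid match)
match_q <- function(ds, q_values) {
  idx <- match(q_values, ds$q)
  if (anyNA(idx)) abort("some requested q values are not on the grid.")
  idx
}

#' Initialize a global decomposition from a single-chromatogram fit
#'
#' Copies the accepted shapes to every selected chromatogram and fits the
#' per-q amplitudes only. With the shapes fixed this is a linear problem,
#' solved exactly per q under the non-negativity constraint.
#'
#' @param single A [fit_single()] result.
#' @param ds A `secsaxs_dataset`.
#' @param q_values q grid values to include (default: every grid point; use
#'   e.g. `ds$q[seq(1, length(ds$q), by = 4)]` for a one-in-four subset).
#' @return A `decomposition_model`.
#' @export
init_global <- function(single, ds, q_values = ds$q) {
  stopifnot(inherits(single, "single_fit"), inherits(ds, "secsaxs_dataset"))
  cols_q <- match_q(ds, q_values)
  sel <- ds$frames >= single$fit_limits[1] & ds$frames <= single$fit_limits[2]
  ts <- ds$frames[sel]
  basis <- shape_basis(single$kind, ts, single$shapes)
  cond <- kappa(basis, exact = TRUE)
  if (cond > 1e10) {
    warn(paste0("nearly collinear peak shapes (condition number ",
                format(cond, digits = 3), ")."))
  }
  N <- nrow(single$shapes)
  amplitudes <- matrix(vapply(cols_q, function(j) {
    solve_amplitudes(basis, ds$I[j, sel], ds$S[j, sel])
  }, numeric(N)), ncol = N, byrow = TRUE)
  new_decomposition_model(single$kind, select(single$shapes, -"a0"),
                          amplitudes, ds$q[cols_q], single$fit_limits,
                          single$common_distortion)
}

#' Global fit of shared peak shapes across chromatograms
#'
#' Joint weighted least squares over all selected chromatograms
#' simultaneously. Centers and widths are common to all chromatograms (one
#' value per family); distortions are in addition common to all families by
#' default. Per-q amplitudes remain free and non-negative, solved exactly
#' at every trial shape. Parameters can be frozen via `fix`.
#'
#' @param model A `decomposition_model` (from [init_global()]).
#' @param ds The `secsaxs_dataset` the model was initialized on.
#' @param fix Character vector of parameter groups to freeze: any of
#'   `"centers"`, `"widths"`, `"distortions"`.
#' @param maxiter Levenberg-Marquardt iteration cap.
#' @return The refined `decomposition_model`, with a [goodness_by_q()]
#'   report in `$fit_report` and the achieved weighted SSR in `$ssr`.
#' @export
global_fit <- function(model, ds, fix = character(0), maxiter = 100L) {
  stopifnot(inherits(model, "decomposition_model"),
            inherits(ds, "secsaxs_dataset"))
  N <- nrow(model$shapes)
  kind <- model$kind
  cd <- model$common_distortion
  cols_q <- match_q(ds, model$q)
  sel <- ds$frames >= model$fit_limits[1] & ds$frames <= model$fit_limits[2]
  ts <- ds$frames[sel]
  Y <- ds$I[cols_q, sel, drop = FALSE]
  S <- ds$S[cols_q, sel, drop = FALSE]
  theta0 <- pack_theta(model$shapes, kind, cd)
  bnd <- theta_bounds(N, kind, cd, range(ts))
  # freeze requested groups by pinning their bounds at the current value
  nd <- n_distortions(kind)
  n_dist <- if (nd == 0L) 0L else if (cd) nd else nd * N
  grp <- c(rep("centers", N), rep("widths", N), rep("distortions", n_dist))
  frozen <- grp %in% fix
  bnd$lower[frozen] <- theta0[frozen]
  bnd$upper[frozen] <- theta0[frozen]
  amp_for <- function(basis) {
    matrix(vapply(seq_len(nrow(Y)), function(r) {
      solve_amplitudes(basis, Y[r, ], S[r, ])
    }, numeric(N)), ncol = N, byrow = TRUE)
  }
  resid_fn <- function(theta) {
    shapes <- unpack_theta(theta, N, kind, cd)
    basis <- shape_basis(kind, ts, shapes)
    amp <- amp_for(basis)
    as.vector((Y - amp %*% t(basis)) / S)
  }
  fit <- minpack.lm::nls.lm(par = theta0, lower = bnd$lower,
                            upper = bnd$upper, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxiter))
  shapes <- unpack_theta(fit$par, N, kind, cd)
  basis <- shape_basis(kind, ts, shapes)
  out <- new_decomposition_model(kind, shapes, amp_for(basis), model$q,
                                 model$fit_limits, cd)
  out$ssr <- sum(resid_fn(fit$par)^2)
  out$converged <- fit$info %in% 1:4
  if (!out$converged) {
    warn(paste0("global fit did not fully converge (info = ", fit$info,
                "); returning best parameters found."))
  }
  out$fit_report <- goodness_by_q(out, ds)
  out
}

#' Extend amplitude fits to every chromatogram
#'
#' Amplitude-only non-negative linear fits for all q rows of the dataset,
#' using the shared shapes of a converged global fit. Chromatograms already
#' fitted keep their amplitudes (the solve is deterministic given the
#' shapes).
#'
#' @param model A `decomposition_model`.
#' @param ds The `secsaxs_dataset`.
#' @return The model with amplitudes for every q in `ds`.
#' @export
fit_all_amplitudes <- function(model, ds) {
  stopifnot(inherits(model, "decomposition_model"),
            inherits(ds, "secsaxs_dataset"))
  sel <- ds$frames >= model$fit_limits[1] & ds$frames <= model$fit_limits[2]
  ts <- ds$frames[sel]
  basis <- shape_basis(model$kind, ts, model$shapes)
  N <- nrow(model$shapes)
  amplitudes <- matrix(vapply(seq_len(length(ds$q)), function(j) {
    solve_amplitudes(basis, ds$I[j, sel], ds$S[j, sel])
  }, numeric(N)), ncol = N, byrow = TRUE)
  out <- new_decomposition_model(model$kind, model$shapes, amplitudes, ds$q,
                                 model$fit_limits, model$common_distortion)
  out$fit_report <- model$fit_report
  out
}

#' Per-q goodness of fit
#'
#' For every q in the model: the reduced chi-squared of data versus model
#' within the fit limits, and the longest-run P value of the residual sign
#' pattern (data versus fit compared point by point over the frames). The
#' three-class labels use the plain 0.05 / 0.01 cutoffs.
#'
#' @param model A `decomposition_model` with amplitudes.
#' @param ds The `secsaxs_dataset`.
#' @return A tibble: `q`, `chi2`, `p_value`, `class`.
#' @export
goodness_by_q <- function(model, ds) {
  stopifnot(inherits(model, "decomposition_model"),
            inherits(ds, "secsaxs_dataset"))
  cols_q <- match_q(ds, model$q)
  sel <- ds$frames >= model$fit_limits[1] & ds$frames <= model$fit_limits[2]
  ts <- ds$frames[sel]
  basis <- shape_basis(model$kind, ts, model$shapes)
  opts <- pairwise_options(q_max_cutoff = Inf, stride = 1L)
  rows <- lapply(seq_along(cols_q), function(r) {
    j <- cols_q[r]
    y <- ds$I[j, sel]; s <- ds$S[j, sel]
    yhat <- as.vector(basis %*% model$amplitudes[r, ])
    chi2 <- sum(((y - yhat) / s)^2) / max(length(y) - 1, 1)
    p <- cormap_pvalue(y, yhat, x = ts, opts = opts)
    tibble(q = ds$q[j], chi2 = chi2, p_value = p)
  })
  out <- bind_rows(rows)
  out$class <- classify_p(out$p_value, out$p_value < 0.01,
                          out$p_value < 0.05)
  out
}

#' Plot per-q goodness-of-fit indicators
#'
#' @param object A tibble from [goodness_by_q()] or a fitted
#'   `decomposition_model`.
#' @param ... Unused.
#' @return A ggplot of chi-squared and P value versus q, with the 0.05 and
#'   0.01 P-value cutoffs marked.
#' @export
plot_goodness_by_q <- function(object, ...) {
  rep <- if (inherits(object, "decomposition_model")) object$fit_report
    else object
  df <- tidyr::pivot_longer(rep, c("chi2", "p_value"),
                            names_to = "indicator", values_to = "value")
  cuts <- tibble(indicator = "p_value", value = c(0.05, 0.01))
  ggplot(df, aes(x = .data$q, y = .data$value)) +
    geom_point() +
    geom_hline(data = cuts, aes(yintercept = .data$value), linetype = 3) +
    facet_wrap(~indicator, scales = "free_y", ncol = 1) +
    labs(x = "q (1/A)", y = NULL) +
    theme_bw()
}

#' Back-generate per-species frames
#'
#' Reconstructs the scattering frames of one peak family: at every (q, t)
#' the intensity is the family's unit shape at t times that q's amplitude.
#' Experimental uncertainties are reassigned unchanged
#' (`fit_error_fraction = 0`); optionally a fraction of the local
#' data-versus-fit discrepancy is added in quadrature, apportioned by the
#' family's share of the total model intensity at that point:
#' `sigma = sqrt(sigma_orig^2 + (frac * |data - fit| * share)^2)`.
#'
#' @param model A `decomposition_model` with amplitudes for every q of
#'   `ds` (see [fit_all_amplitudes()]).
#' @param ds The `secsaxs_dataset`.
#' @param peak_index Family number.
#' @param frame_range Length-2 frame-ordinal range to reconstruct.
#' @param fit_error_fraction Fraction of the local fit discrepancy added to
#'   the uncertainties (no default is implied by the method; pass 0 for
#'   plain reassignment).
#' @return A `secsaxs_dataset` holding the species' frames.
#' @export
back_generate_frames <- function(model, ds, peak_index, frame_range,
                                 fit_error_fraction) {
  stopifnot(inherits(model, "decomposition_model"),
            inherits(ds, "secsaxs_dataset"))
  cols_q <- match_q(ds, model$q)
  if (length(cols_q) != length(ds$q)) {
    abort("model must cover every q of the dataset (run fit_all_amplitudes).")
  }
  sel <- which(ds$frames >= frame_range[1] & ds$frames <= frame_range[2])
  if (length(sel) == 0) abort("empty frame range.")
  ts <- ds$frames[sel]
  basis <- shape_basis(model$kind, ts, model$shapes)  # n_t x N
  amp <- model$amplitudes[order(cols_q), , drop = FALSE]
  total <- amp %*% t(basis)                 # n_q x n_t model intensity
  fam <- outer(amp[, peak_index], basis[, peak_index])  # n_q x n_t
  share <- ifelse(total > 0, fam / total, 0)
  discrepancy <- abs(ds$I[, sel, drop = FALSE] - total)
  sigma <- sqrt(ds$S[, sel, drop = FALSE]^2 +
                  (fit_error_fraction * discrepancy * share)^2)
  secsaxs_dataset(ds$q, fam, sigma, frames = ts,
                  meta = list(species = peak_index,
                              fit_error_fraction = fit_error_fraction))
}

#' Save a decomposition model to JSON
#'
#' Versioned, lossless round trip of kind, shapes, amplitudes and fit
#' limits.
#'
#' @param model A `decomposition_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "decomposition_model"))
  obj <- list(format = "secsaxs_decomposition", version = 1L,
              kind = model$kind,
              common_distortion = model$common_distortion,
              fit_limits = model$fit_limits,
              shapes = as.data.frame(model$shapes),
              q = model$q,
              amplitudes = model$amplitudes)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a decomposition model saved by [save_model()]
#'
#' @param path File path.
#' @return A `decomposition_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "secsaxs_decomposition")) {
    abort("not a decomposition model file.")
  }
  if (obj$version > 1L) abort(paste0("unsupported model version ", obj$version))
  if (!obj$kind %in% peak_kinds) abort(paste0("unknown kind tag: ", obj$kind))
  shapes <- as_tibble(obj$shapes)
  if (!"a4" %in% names(shapes)) shapes$a4 <- 0  # legacy single-distortion file
  amplitudes <- matrix(obj$amplitudes, nrow = length(obj$q))
  new_decomposition_model(obj$kind, shapes, amplitudes, obj$q,
                          obj$fit_limits, isTRUE(obj$common_distortion))
}
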