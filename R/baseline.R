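# Capillary-fouling detection and correction. Fouling deposits accumulate on
# the measurement cell in proportion to the sample scattering above the
# already-deposited material, leaving a steady residual signal I_BL(q) after
# elution ends. The integral baseline reconstructs the deposit history B(q,t)
# from I_BL(q) by iterating: total signal above the current baseline ->
# proportionality gamma -> cumulative deposits -> improved baseline.

#' Steady-state average intensity
#'
#' Per-q arithmetic mean of the intensity over the final steady-state frame
#' stretch `[t_s1, t_sm]`, which defines the fouling endpoint I_BL(q).
#'
#' @param ds A `secsaxs_dataset`.
#' @param t_s1,t_sm First and last frame ordinals of the steady-state region.
#' @return Numeric vector I_BL(q), one entry per q row.
#' @export
steady_state_average <- function(ds, t_s1, t_sm) {
  stopifnot(inherits(ds, "secsaxs_dataset"))
  j1 <- match(t_s1, ds$frames); j2 <- match(t_sm, ds$frames)
  if (is.na(j1) || is.na(j2) || j2 < j1) abort("region outside dataset.")
  if (j2 - j1 + 1 < 10) {
    warn("steady-state region shorter than 10 frames; I_BL will be noisy.")
  }
  rowMeans(ds$I[, j1:j2, drop = FALSE])
}

#' Buffer-frame similarity reference
#'
#' Summarises a buffer-only dataset by the mean and standard deviation of
#' the average red cluster size over all sliding windows of `window` frames,
#' computed with the same pairwise options used for the sample analysis.
#' This is the internal reference against which candidate steady-state
#' windows are judged.
#'
#' @param blanks A `secsaxs_dataset` of buffer-only frames.
#' @param window Window length in frames (default 20).
#' @param opts A [pairwise_options()] object.
#' @return A list of class `blank_reference` with `mean`, `sd`, `window`,
#'   `per_window` (tibble of start frame and average red cluster size) and
#'   the options used.
#' @export
blank_reference <- function(blanks, window = 20L, opts = pairwise_options()) {
  stopifnot(inherits(blanks, "secsaxs_dataset"))
  nt <- length(blanks$frames)
  if (nt < window) abort("buffer dataset shorter than one window.")
  starts <- seq_len(nt - window + 1L)
  acs <- vapply(starts, function(s) {
    m <- pairwise_pvalue_map(blanks$I[, s:(s + window - 1L), drop = FALSE],
                             x = blanks$q, opts = opts)
    red_cluster_stats(m)$average_red_cluster_size
  }, numeric(1))
  structure(list(mean = mean(acs), sd = sd(acs), window = window,
                 per_window = tibble(start = blanks$frames[starts],
                                     avg_red_cluster = acs),
                 opts = opts),
            class = "blank_reference")
}

#' Locate the final steady-state region
#'
#' Slides a window of `window` frames over `scan_range` and computes two
#' indicators per start frame: (1) the average red cluster size of the
#' window's pairwise P-value map, compared with the buffer reference, and
#' (2) the cumulative intensity (per-frame sum of I over q <= the cutoff)
#' averaged over the window, with its standard deviation. Windows whose
#' first indicator stays within the blanks' mean + 1 s.d. are candidates;
#' the chosen region is the latest consecutive run of candidate windows
#' (its flatness in indicator 2 is reported). A correction suggestion is
#' issued: "integral baseline" when the minimum windowed cumulative
#' intensity stays above zero (the signal never returns to a clean-buffer
#' level), otherwise "none/linear".
#'
#' @param ds A `secsaxs_dataset`.
#' @param blanks A [blank_reference()].
#' @param opts A [pairwise_options()] object (should match the reference's).
#' @param window Window length in frames (default 20, as in the reference).
#' @param scan_range Length-2 frame-ordinal range to scan (default: all).
#' @return A list of class `steady_state_region`: `t_s1`, `t_sm`,
#'   `suggestion`, `indicators` (tibble: start, avg_red_cluster,
#'   cum_intensity_mean, cum_intensity_sd, candidate) and `window`.
#' @export
find_best_region <- function(ds, blanks, opts = pairwise_options(),
                             window = blanks$window, scan_range = NULL) {
  stopifnot(inherits(ds, "secsaxs_dataset"), inherits(blanks, "blank_reference"))
  frames <- ds$frames
  if (is.null(scan_range)) scan_range <- range(frames)
  jr <- which(frames >= scan_range[1] & frames <= scan_range[2])
  if (length(jr) < window) abort("scan range shorter than one window.")
  qsel <- ds$q <= opts$q_max_cutoff
  cum_int <- colSums(ds$I[qsel, jr, drop = FALSE])
  starts <- seq_len(length(jr) - window + 1L)
  ind <- purrr::map(starts, function(s) {
    cols <- jr[s:(s + window - 1L)]
    m <- pairwise_pvalue_map(ds$I[, cols, drop = FALSE], x = ds$q, opts = opts)
    ci <- cum_int[s:(s + window - 1L)]
    tibble(start = frames[jr[s]],
           avg_red_cluster = red_cluster_stats(m)$average_red_cluster_size,
           cum_intensity_mean = mean(ci), cum_intensity_sd = sd(ci))
  })
  ind <- bind_rows(ind)
  ind$candidate <- ind$avg_red_cluster <= blanks$mean + blanks$sd
  if (!any(ind$candidate)) {
    abort("no candidate window: no stretch of frames matches the buffer reference.")
  }
  runs <- rle(ind$candidate)
  ends <- cumsum(runs$lengths)
  begins <- ends - runs$lengths + 1L
  cand_runs <- which(runs$values)
  best <- cand_runs[length(cand_runs)]  # latest run of candidate windows
  i1 <- begins[best]; i2 <- ends[best]
  t_s1 <- ind$start[i1]
  t_sm <- frames[jr[starts[i2] + window - 1L]]
  suggestion <- if (min(ind$cum_intensity_mean) > 0) "integral baseline"
    else "none/linear"
  structure(list(t_s1 = t_s1, t_sm = t_sm, suggestion = suggestion,
                 indicators = ind, window = window,
                 flatness = sd(ind$cum_intensity_mean[i1:i2])),
            class = "steady_state_region")
}

#' @export
print.steady_state_region <- function(x, ...) {
  cat("<steady_state_region> frames ", x$t_s1, "..", x$t_sm,
      " (window ", x$window, ")\n  suggestion: ", x$suggestion, "\n", sep = "")
  invisible(x)
}

#' Plot steady-state search indicators
#'
#' @param object A `steady_state_region`.
#' @param ... Unused.
#' @return A ggplot with both indicators versus window start frame.
#' @export
autoplot.steady_state_region <- function(object, ...) {
  df <- tidyr::pivot_longer(object$indicators,
                            c("avg_red_cluster", "cum_intensity_mean"),
                            names_to = "indicator", values_to = "value")
  ggplot(df, aes(x = .data$start, y = .data$value, color = .data$candidate)) +
    geom_point() +
    facet_wrap(~indicator, scales = "free_y", ncol = 1) +
    geom_vline(xintercept = c(object$t_s1, object$t_sm), linetype = 2) +
    labs(x = "window start frame", y = NULL) +
    theme_bw()
}

# normalized Gaussian kernel on (2k+1) points; sd chosen so the support
# covers +/- 2 sd
gaussian_kernel <- function(points) {
  k <- (points - 1L) / 2L
  s <- max(k / 2, 0.5)
  w <- dnorm(seq(-k, k), sd = s)
  w / sum(w)
}

#' Gaussian smoothing of a chromatogram
#'
#' Convolves the intensity with a normalized Gaussian kernel of the given
#' odd support (7 points by default); near the edges the kernel is
#' renormalized over the available points so constants are preserved
#' everywhere. Sigmas are left untouched. Smoothing is computational
#' scaffolding for the integral-baseline iteration only; the subtraction
#' itself is always applied to the raw data.
#'
#' @param intensity Numeric vector (one chromatogram).
#' @param points Odd kernel support >= 3.
#' @return Smoothed numeric vector of the same length.
#' @export
gaussian_smooth <- function(intensity, points = 7L) {
  points <- as.integer(points)
  if (points < 3L || points %% 2L == 0L) abort("`points` must be odd and >= 3.")
  n <- length(intensity)
  if (points > n) abort("kernel support exceeds series length.")
  w <- gaussian_kernel(points)
  k <- (points - 1L) %/% 2L
  padded <- c(rep(NA_real_, k), intensity, rep(NA_real_, k))
  vapply(seq_len(n), function(i) {
    seg <- padded[i:(i + 2L * k)]
    ok <- !is.na(seg)
    sum(seg[ok] * w[ok]) / sum(w[ok])
  }, numeric(1))
}

#' Iterative integral baseline for one chromatogram
#'
#' Reconstructs the fouling baseline B(t) for a single q value. Starting
#' from B = 0, each iteration computes the total intensity above the
#' current baseline over the elution region, S_i = sum(I(t_{k-1}) -
#' B_i(t_{k-1})), sets gamma_i = I_BL / S_i, and accumulates deposits
#' B_{i+1}(t_k) = sum_{j<=k} gamma_i (I(t_{j-1}) - B_i(t_{j-1})). B(t_0) is
#' pinned to zero (no deposit before any exposure) and the iteration stops
#' when successive baselines agree within `epsilon` (default 0, meaning run
#' to the cap unless the baselines repeat exactly) or after `max_iter`
#' iterations. After the end of the elution region the baseline continues
#' to accumulate with the same rule, so it plateaus at I_BL over the
#' steady-state stretch.
#'
#' If the integral S_i is not positive the correction would add signal
#' rather than subtract it; the chromatogram is then marked skipped ("0s")
#' and a zero baseline returned.
#'
#' @param intensity Chromatogram intensities (ideally pre-smoothed with
#'   [gaussian_smooth()]).
#' @param I_BL Steady-state average for this q (scalar).
#' @param region_end Index (into `intensity`) of the last elution frame over
#'   which deposits accumulate, normally the position of t_s1.
#' @param epsilon Convergence threshold on `max |B_{i+1} - B_i|` (default 0).
#' @param max_iter Iteration cap (default 5).
#' @return A list: `B` (baseline vector, same length), `gamma`, `iterations`,
#'   `converged`, `skipped`.
#' @export
integral_baseline <- function(intensity, I_BL, region_end,
                              epsilon = 0, max_iter = 5L) {
  n <- length(intensity)
  if (region_end < 2 || region_end > n) abort("invalid elution region.")
  if (I_BL <= 0) {
    return(list(B = numeric(n), gamma = 0, iterations = 0L,
                converged = TRUE, skipped = FALSE))
  }
  B <- numeric(n)
  gamma <- 0
  iterations <- 0L
  converged <- FALSE
  reg <- seq_len(region_end - 1L)  # t_{k-1} indices feeding deposits
  for (i in seq_len(max_iter)) {
    above <- intensity - B
    S <- sum(above[reg])
    if (S <= 0) {
      return(list(B = numeric(n), gamma = NA_real_, iterations = iterations,
                  converged = FALSE, skipped = TRUE))
    }
    gamma <- I_BL / S
    # deposits D(t_k) = gamma * (I - B)(t_{k-1}); continue past the elution
    # region so the baseline holds its plateau against residual signal
    D <- c(0, gamma * above[seq_len(n - 1L)])
    B_new <- cumsum(D)
    iterations <- i
    delta <- max(abs(B_new - B))
    B <- B_new
    if (delta <= epsilon) { converged <- TRUE; break }
  }
  list(B = B, gamma = gamma, iterations = iterations,
       converged = converged, skipped = FALSE)
}

#' Apply the integral baseline correction to a dataset
#'
#' Computes the per-q integral baseline from the smoothed chromatograms and
#' subtracts it from the original (unsmoothed) data. Chromatograms hitting
#' the negative-integral guard pass through unchanged and are flagged "0s".
#' Sigmas are unchanged.
#'
#' @param ds A `secsaxs_dataset`.
#' @param region A `steady_state_region` (or a list with `t_s1`, `t_sm`).
#' @param epsilon,max_iter Passed to [integral_baseline()].
#' @param smooth_points Gaussian smoothing support for the baseline
#'   computation (default 7); `0` disables smoothing.
#' @return A list of class `baseline_result`: `corrected` (dataset),
#'   `I_BL` (per-q steady-state average), `B` (n_q x n_t baseline matrix),
#'   `gamma` (per-q), `iterations` (per-q), `skipped` (per-q logical flags),
#'   `region`.
#' @export
apply_integral_baseline <- function(ds, region, epsilon = 0, max_iter = 5L,
                                    smooth_points = 7L) {
  stopifnot(inherits(ds, "secsaxs_dataset"))
  I_BL <- steady_state_average(ds, region$t_s1, region$t_sm)
  j_s1 <- match(region$t_s1, ds$frames)
  nq <- length(ds$q)
  B <- matrix(0, nq, length(ds$frames))
  gamma <- numeric(nq)
  iterations <- integer(nq)
  skipped <- logical(nq)
  for (i in seq_len(nq)) {
    y <- ds$I[i, ]
    if (smooth_points >= 3) y <- gaussian_smooth(y, smooth_points)
    res <- integral_baseline(y, I_BL[i], region_end = j_s1,
                             epsilon = epsilon, max_iter = max_iter)
    B[i, ] <- res$B
    gamma[i] <- if (res$skipped) NA_real_ else res$gamma
    iterations[i] <- res$iterations
    skipped[i] <- res$skipped
  }
  corrected <- secsaxs_dataset(ds$q, ds$I - B, ds$S, frames = ds$frames,
                               time = ds$time,
                               meta = c(ds$meta, list(baseline = "integral")))
  if (any(skipped)) {
    warn(paste0(sum(skipped), " chromatogram(s) skipped by the ",
                "negative-integral guard (flagged '0s')."))
  }
  structure(list(corrected = corrected, I_BL = I_BL, B = B, gamma = gamma,
                 iterations = iterations, skipped = skipped, region = region,
                 epsilon = epsilon),
            class = "baseline_result")
}

#' Tidy a baseline result
#'
#' @param x A `baseline_result`.
#' @param ... Unused.
#' @return A tibble with one row per q: `q`, `I_BL`, `gamma`, `iterations`,
#'   `skipped` (the "0s" flag).
#' @export
tidy.baseline_result <- function(x, ...) {
  tibble(q = x$corrected$q, I_BL = x$I_BL, gamma = x$gamma,
         iterations = x$iterations, skipped = x$skipped)
}

#' Linear baseline correction
#'
#' Subtracts the straight line through the mean (t, I) points of two
#' disjoint anchor windows. Appropriate for simple drifting, not for
#' capillary fouling.
#'
#' @param chrom A tibble with columns `frame` and `intensity` (as returned
#'   by [chromatogram()]).
#' @param anchor_start,anchor_end Length-2 frame-ordinal ranges of the two
#'   anchor windows.
#' @return The chromatogram tibble with `intensity` replaced by the
#'   line-subtracted values (other columns untouched).
#' @export
linear_baseline <- function(chrom, anchor_start, anchor_end) {
  a <- chrom$frame >= anchor_start[1] & chrom$frame <= anchor_start[2]
  b <- chrom$frame >= anchor_end[1] & chrom$frame <= anchor_end[2]
  if (!any(a) || !any(b)) abort("empty anchor window.")
  t1 <- mean(chrom$frame[a]); y1 <- mean(chrom$intensity[a])
  t2 <- mean(chrom$frame[b]); y2 <- mean(chrom$intensity[b])
  if (t1 == t2) abort("identical anchor means in t.")
  slope <- (y2 - y1) / (t2 - t1)
  chrom$intensity <- chrom$intensity - (y1 + slope * (chrom$frame - t1))
  chrom
}
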