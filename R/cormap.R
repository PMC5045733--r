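# Longest same-sign run ("correlation map") P values for pairwise curve
# comparison, Holm-Bonferroni adjustment, P-value maps and red-cluster
# statistics. The null model is n independent fair signs; the P value is the
# probability that the longest run of equal signs is at least the observed
# length.

#' Options for pairwise curve comparisons
#'
#' @param q_max_cutoff Upper abscissa limit for all comparisons, in inverse
#'   Angstrom (default 0.05); use `Inf` to compare full curves (e.g. when
#'   the abscissa is the frame index).
#' @param stride Integer subsampling step applied after the cutoff: 1 keeps
#'   every point, 2 every other point (decorrelates adjacent detector
#'   pixels).
#' @param adjust `"none"` or `"holm_bonferroni"`.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return A list of class `pairwise_options`.
#' @export
pairwise_options <- function(q_max_cutoff = 0.05, stride = 1L,
                             adjust = c("none", "holm_bonferroni"),
                             alpha = 0.05) {
  adjust <- match.arg(adjust)
  stride <- as.integer(stride)
  if (stride < 1L) abort("stride must be >= 1.")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1).")
  structure(list(q_max_cutoff = q_max_cutoff, stride = stride,
                 adjust = adjust, alpha = alpha),
            class = "pairwise_options")
}

#' Longest run of constant sign
#'
#' Length of the longest maximal stretch of consecutive strictly positive or
#' strictly negative entries. Exact zeros terminate runs and belong to none,
#' so an all-zero vector scores 0.
#'
#' @param delta Numeric vector of differences (finite).
#' @return Integer run length.
#' @export
#' @examples
#' longest_same_sign_run(c(1, 1, -1, 1))  # 2
longest_same_sign_run <- function(delta) {
  if (length(delta) == 0) abort("empty vector.")
  if (any(!is.finite(delta))) abort("non-finite values in `delta`.")
  s <- sign(delta)
  r <- rle(s)
  len <- r$lengths[r$values != 0]
  if (length(len) == 0) return(0L)
  as.integer(max(len))
}

#' Exact longest-run P value under the fair-sign null
#'
#' Probability that the longest run of equal signs among `n` independent
#' fair signs is at least `C`. Computed from the exact run-length recursion
#' (compositions of n into parts of size < C), carried in probability scale
#' so it is stable for large n.
#'
#' @param n Number of points compared (>= 1).
#' @param C Observed longest run; `C = 0` (no signed run at all) gives 1.
#' @return P value in `[0, 1]`.
#' @export
#' @examples
#' run_pvalue(10, 10)  # 2^(1-10)
run_pvalue <- function(n, C) {
  n <- as.integer(n)
  C <- as.integer(C)
  if (n < 1) abort("n must be >= 1.")
  if (C > n) abort("C cannot exceed n.")
  if (C <= 1L) return(1)
  m <- C - 1L  # allowed maximal run length under the complement event
  # r[k+1] = (# sign sequences of length k with all runs <= m) / 2^(k-1)
  r <- numeric(n + 1L)
  r[1L] <- 2  # k = 0 convention: one empty composition, scaled by 2^(0-1)
  for (k in seq_len(n)) {
    j <- seq_len(min(m, k))
    r[k + 1L] <- sum(r[k + 1L - j] / 2^j)
  }
  p <- 1 - r[n + 1L]
  min(max(p, 0), 1)
}

#' Longest-run P value for a pair of curves
#'
#' Restricts both curves to `x <= q_max_cutoff`, subsamples by `stride`,
#' and scores the sign pattern of their difference against the fair-sign
#' null. The null length is the number of points actually compared (after
#' cutoff and stride), not the raw grid length.
#'
#' @param a,b Numeric vectors on a common abscissa grid.
#' @param x Abscissa grid (default: index), used for the cutoff.
#' @param opts A [pairwise_options()] object.
#' @return P value.
#' @export
cormap_pvalue <- function(a, b, x = seq_along(a), opts = pairwise_options()) {
  if (length(a) != length(b) || length(a) != length(x)) {
    abort("`a`, `b` and `x` must have equal length.")
  }
  keep <- which(x <= opts$q_max_cutoff)
  keep <- keep[seq(1L, length(keep), by = opts$stride)]
  if (length(keep) < 2) abort("fewer than 2 points after cutoff/stride.")
  delta <- a[keep] - b[keep]
  run_pvalue(length(keep), longest_same_sign_run(delta))
}

# three-class labels from P values; thresholds are either the plain 0.05 /
# 0.01 cutoffs or Holm-Bonferroni step thresholds at those two levels
classify_p <- function(p, red, yellow) {
  ifelse(red, "red", ifelse(yellow, "yellow", "green"))
}

#' Holm-Bonferroni stepwise adjustment
#'
#' Sorts the P values ascending and rejects while `p_(i) <= alpha/(m-i+1)`,
#' stopping at the first failure. Decisions agree with
#' `p.adjust(p, "holm") <= alpha`.
#'
#' @param pvals Numeric vector of P values in `[0, 1]`.
#' @param alpha Family-wise significance level.
#' @return A tibble with one row per input P value (original order):
#'   `p`, `rank`, `threshold` (the step threshold applied to it), `reject`.
#' @export
holm_bonferroni <- function(pvals, alpha = 0.05) {
  m <- length(pvals)
  if (m < 1) abort("need at least one P value.")
  if (any(pvals < 0 | pvals > 1)) abort("P values must lie in [0, 1].")
  ord <- order(pvals)
  thr_sorted <- alpha / (m - seq_len(m) + 1)
  ok <- pvals[ord] <= thr_sorted
  first_fail <- which(!ok)[1]
  reject_sorted <- if (is.na(first_fail)) rep(TRUE, m) else
    seq_len(m) < first_fail
  out <- tibble(p = pvals, rank = NA_integer_, threshold = NA_real_,
                reject = NA)
  out$rank[ord] <- seq_len(m)
  out$threshold[ord] <- thr_sorted
  out$reject[ord] <- reject_sorted
  out
}

#' Pairwise longest-run P-value map
#'
#' Scores all n(n-1)/2 curve pairs and assigns the three-class color code:
#' without adjustment, green for P >= 0.05, yellow for 0.01 <= P < 0.05 and
#' red for P < 0.01; with `adjust = "holm_bonferroni"`, red means rejected
#' by the stepwise procedure at level 0.01 and yellow rejected at 0.05 but
#' not at 0.01.
#'
#' @param curves Numeric matrix (one curve per column) or list of equal
#'   length numeric vectors, all on the grid `x`.
#' @param x Common abscissa grid (default: point index).
#' @param opts A [pairwise_options()] object.
#' @return An object of class `pvalue_map`: list with the symmetric `P`
#'   matrix (diagonal 1), the `classes` character matrix, `m` (number of
#'   pairs), `n_curves` and the options used.
#' @export
pairwise_pvalue_map <- function(curves, x = NULL, opts = pairwise_options()) {
  if (is.list(curves) && !is.data.frame(curves)) {
    curves <- do.call(cbind, curves)
  }
  curves <- as.matrix(curves)
  n <- ncol(curves)
  if (n < 2) abort("need at least 2 curves.")
  if (is.null(x)) x <- seq_len(nrow(curves))
  P <- matrix(1, n, n)
  pairs <- which(upper.tri(P), arr.ind = TRUE)
  pv <- vapply(seq_len(nrow(pairs)), function(k) {
    cormap_pvalue(curves[, pairs[k, 1]], curves[, pairs[k, 2]], x, opts)
  }, numeric(1))
  P[pairs] <- pv
  P[pairs[, c(2, 1), drop = FALSE]] <- pv
  if (opts$adjust == "holm_bonferroni") {
    red_rej <- holm_bonferroni(pv, alpha = 0.01)$reject
    yel_rej <- holm_bonferroni(pv, alpha = 0.05)$reject
    cls_pairs <- classify_p(pv, red_rej, yel_rej)
  } else {
    cls_pairs <- classify_p(pv, pv < 0.01, pv < 0.05)
  }
  classes <- matrix("green", n, n)
  classes[pairs] <- cls_pairs
  classes[pairs[, c(2, 1), drop = FALSE]] <- cls_pairs
  diag(classes) <- NA_character_
  structure(list(n_curves = n, P = P, classes = classes,
                 m = n * (n - 1) / 2, opts = opts),
            class = "pvalue_map")
}

#' @export
print.pvalue_map <- function(x, ...) {
  st <- red_cluster_stats(x)
  cat("<pvalue_map> ", x$n_curves, " curves, ", x$m, " pairs (",
      x$opts$adjust, ")\n", sep = "")
  cat(sprintf("  red %.2f%%  yellow %.2f%%  green %.2f%%  avg red cluster %.2f\n",
              st$percent_red, st$percent_yellow, st$percent_green,
              st$average_red_cluster_size))
  invisible(x)
}

#' Tidy a P-value map
#'
#' @param x A `pvalue_map`.
#' @param ... Unused.
#' @return A tibble with one row per unordered pair: `i`, `j`, `p`, `class`.
#' @export
tidy.pvalue_map <- function(x, ...) {
  pairs <- which(upper.tri(x$P), arr.ind = TRUE)
  tibble(i = pairs[, 1], j = pairs[, 2], p = x$P[pairs],
         class = x$classes[pairs])
}

# 4-connected components over a logical matrix, iterative flood fill
label_components4 <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      cell <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[cell] != 0L || !mask[cell]) next
      lab[cell] <- cur
      i <- (cell - 1L) %% n + 1L
      j <- (cell - 1L) %/% n + 1L
      nb <- c(if (i > 1) cell - 1L, if (i < n) cell + 1L,
              if (j > 1) cell - n, if (j < m) cell + n)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      stack <- c(stack, nb)
    }
  }
  lab
}

#' Red-cluster statistics of a P-value map
#'
#' Clusters are maximal groups of horizontally and/or vertically adjacent
#' red cells of the full (mirrored) square matrix, the diagonal excluded.
#' Class percentages are computed over the n(n-1)/2 unordered pairs.
#'
#' @param map A `pvalue_map`.
#' @return A list of class `cluster_stats`: `cluster_sizes`,
#'   `average_red_cluster_size` (0 when there are no red cells),
#'   `percent_red`, `percent_yellow`, `percent_green`, and `flag_red_gt_1pct`
#'   (screening flag: more than 1% red pairs).
#' @export
red_cluster_stats <- function(map) {
  stopifnot(inherits(map, "pvalue_map"))
  cls <- map$classes
  mask <- !is.na(cls) & cls == "red"
  lab <- label_components4(mask)
  sizes <- if (max(lab) == 0L) integer(0) else as.integer(table(lab[lab > 0]))
  pairs <- cls[upper.tri(cls)]
  pr <- 100 * mean(pairs == "red")
  py <- 100 * mean(pairs == "yellow")
  pg <- 100 * mean(pairs == "green")
  structure(list(
    cluster_sizes = sizes,
    average_red_cluster_size = if (length(sizes)) mean(sizes) else 0,
    percent_red = pr, percent_yellow = py, percent_green = pg,
    flag_red_gt_1pct = pr > 1
  ), class = "cluster_stats")
}

#' Plot a P-value map
#'
#' @param object A `pvalue_map`.
#' @param ... Unused.
#' @return A ggplot object: the three-class square matrix.
#' @export
autoplot.pvalue_map <- function(object, ...) {
  n <- object$n_curves
  df <- tibble(
    i = rep(seq_len(n), times = n),
    j = rep(seq_len(n), each = n),
    class = as.vector(object$classes)
  )
  df <- df[!is.na(df$class), ]
  ggplot(df, aes(x = .data$i, y = .data$j, fill = .data$class)) +
    geom_tile() +
    scale_fill_manual(values = c(green = "#2ca25f", yellow = "#ffd92f",
                                 red = "#de2d26")) +
    labs(x = "curve index", y = "curve index", fill = "P class") +
    theme_bw()
}
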