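# Data model for SEC-SAXS series: a shared q grid, ordered frames, and the
# intensity / sigma matrices that pivot between the frame view I_t(q) and the
# chromatogram view I_q(t).

#' Construct a SEC-SAXS dataset
#'
#' The central container of the package: an `n_q x n_t` intensity matrix `I`
#' on a common momentum-transfer grid `q` (in inverse Angstrom), with a
#' matching matrix `S` of per-point standard deviations and strictly
#' increasing integer frame ordinals.
#'
#' @param q Numeric vector, strictly increasing momentum-transfer grid
#'   (inverse Angstrom).
#' @param I Numeric matrix, `length(q)` rows by `length(frames)` columns of
#'   scattering intensities (one column per time frame).
#' @param S Numeric matrix of the same shape holding the standard deviation
#'   of every intensity point; all entries must be non-negative.
#' @param frames Integer vector of frame ordinals, strictly increasing.
#'   Defaults to `1:ncol(I)`.
#' @param time Optional numeric vector of frame times in seconds.
#' @param meta Free-form named list of provenance information.
#'
#' @return An object of class `secsaxs_dataset`.
#' @export
#' @examples
#' ds <- secsaxs_dataset(q = c(0.01, 0.02), I = matrix(1:6, 2), S = matrix(1, 2, 3))
#' dim(ds)
secsaxs_dataset <- function(q, I, S, frames = seq_len(ncol(I)), time = NULL,
                            meta = list()) {
  q <- as.numeric(q)
  I <- as.matrix(I)
  S <- as.matrix(S)
  frames <- as.integer(frames)
  if (length(q) != nrow(I)) {
    abort("`q` must have one entry per row of `I`.")
  }
  if (!all(dim(I) == dim(S))) {
    abort("`I` and `S` must have identical dimensions.")
  }
  if (length(frames) != ncol(I)) {
    abort("`frames` must have one entry per column of `I`.")
  }
  if (any(diff(q) <= 0)) {
    abort("non-monotone q: the grid must be strictly increasing.")
  }
  if (any(diff(frames) <= 0)) {
    abort("frame indices must be strictly increasing.")
  }
  if (any(S < 0, na.rm = TRUE)) {
    abort("sigma values must be non-negative.")
  }
  if (!is.null(time) && length(time) != length(frames)) {
    abort("`time` must have one entry per frame.")
  }
  structure(
    list(q = q, frames = frames, I = I, S = S, time = time, meta = meta),
    class = "secsaxs_dataset"
  )
}

#' @export
dim.secsaxs_dataset <- function(x) dim(x$I)

#' @export
print.secsaxs_dataset <- function(x, ...) {
  cat("<secsaxs_dataset> ", length(x$q), " q points x ", length(x$frames),
      " frames\n", sep = "")
  cat("  q: [", format(min(x$q)), ", ", format(max(x$q)), "] A^-1\n", sep = "")
  cat("  frames: ", x$frames[1], "..", x$frames[length(x$frames)], "\n", sep = "")
  if (length(x$meta)) {
    cat("  meta: ", paste(names(x$meta), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy view of a dataset
#'
#' Returns the long (q, frame, intensity, sigma) representation: one row per
#' measured point. This is a pure reshaping; no values are altered.
#'
#' @param x A `secsaxs_dataset`.
#' @param ... Unused.
#' @return A tibble with columns `q`, `frame`, `intensity`, `sigma`.
#' @export
as_tibble.secsaxs_dataset <- function(x, ...) {
  tibble(
    q = rep(x$q, times = length(x$frames)),
    frame = rep(x$frames, each = length(x$q)),
    intensity = as.vector(x$I),
    sigma = as.vector(x$S)
  )
}

#' Extract one frame as a scattering curve
#'
#' @param ds A `secsaxs_dataset`.
#' @param frame Frame ordinal (as stored in `ds$frames`).
#' @return A tibble with columns `q`, `intensity`, `sigma`.
#' @export
get_frame <- function(ds, frame) {
  stopifnot(inherits(ds, "secsaxs_dataset"))
  j <- match(frame, ds$frames)
  if (is.na(j)) abort(paste0("frame ", frame, " not present in dataset."))
  tibble(q = ds$q, intensity = ds$I[, j], sigma = ds$S[, j])
}

#' Transpose a frame series into per-q chromatograms
#'
#' Converts the ensemble of time frames I_t(q) into the I_q(t) view: one
#' chromatogram per q grid point. Values are reindexed, never interpolated,
#' so transposing twice restores the original matrices bit for bit.
#'
#' @param ds A `secsaxs_dataset`.
#' @return A tibble with columns `q`, `frame`, `intensity`, `sigma`, ordered
#'   by `q` then `frame` (one group of rows per chromatogram).
#' @export
chromatograms <- function(ds) {
  stopifnot(inherits(ds, "secsaxs_dataset"))
  tibble(
    q = rep(ds$q, each = length(ds$frames)),
    frame = rep(ds$frames, times = length(ds$q)),
    intensity = as.vector(t(ds$I)),
    sigma = as.vector(t(ds$S))
  )
}

#' Extract a single chromatogram
#'
#' @param ds A `secsaxs_dataset`.
#' @param q_value The q grid value (matched to the nearest grid point within
#'   relative tolerance `tol`).
#' @param tol Relative matching tolerance.
#' @return A tibble with columns `frame`, `intensity`, `sigma`; the matched
#'   grid value is stored in attribute `q_value`.
#' @export
chromatogram <- function(ds, q_value, tol = 1e-6) {
  stopifnot(inherits(ds, "secsaxs_dataset"))
  i <- which.min(abs(ds$q - q_value))
  if (abs(ds$q[i] - q_value) > tol * max(q_value, ds$q[i])) {
    abort(paste0("no q grid point near ", q_value))
  }
  out <- tibble(frame = ds$frames, intensity = ds$I[i, ], sigma = ds$S[i, ])
  attr(out, "q_value") <- ds$q[i]
  out
}

#' Rebuild a dataset from its chromatogram (or tidy) representation
#'
#' Inverse of [chromatograms()] / [as_tibble.secsaxs_dataset()].
#'
#' @param tbl A tibble with columns `q`, `frame`, `intensity`, `sigma`
#'   covering a complete q-by-frame grid.
#' @param meta Passed to [secsaxs_dataset()].
#' @return A `secsaxs_dataset`.
#' @export
as_dataset <- function(tbl, meta = list()) {
  q <- sort(unique(tbl$q))
  frames <- sort(unique(tbl$frame))
  idx <- cbind(match(tbl$q, q), match(tbl$frame, frames))
  I <- matrix(NA_real_, length(q), length(frames))
  S <- matrix(NA_real_, length(q), length(frames))
  I[idx] <- tbl$intensity
  S[idx] <- tbl$sigma
  if (anyNA(I)) abort("tibble does not cover a complete q x frame grid.")
  secsaxs_dataset(q, I, S, frames = frames, meta = meta)
}

# parse the trailing integer in a filename, NA when absent
frame_ordinal_from_name <- function(path) {
  base <- tools::file_path_sans_ext(basename(path))
  m <- regmatches(base, regexpr("[0-9]+$", base))
  if (length(m) == 0) NA_integer_ else as.integer(m)
}

#' Read a series of 3-column SAXS frames
#'
#' Loads whitespace-delimited ASCII frames (columns q, intensity and
#' optionally sigma; `#`-prefixed comment lines ignored) into one dataset.
#' All files must share the q grid of the first file to within relative
#' tolerance `q_tol`. Frames are ordered by the trailing integer in each
#' filename unless `order = "given"`.
#'
#' Files without a sigma column are rejected unless a fill rule is supplied:
#' with `sigma_fill = list(k = 1, floor = 0)` missing sigmas become
#' `k * sqrt(pmax(intensity, floor))`, a counting-statistics-style stand-in
#' for beamline-provided uncertainties.
#'
#' @param paths Character vector of file paths.
#' @param sigma_fill `NULL` (reject 2-column files) or a list with elements
#'   `k` and `floor`.
#' @param q_tol Relative q-grid equality tolerance (default `1e-8`).
#' @param order `"filename"` (trailing-integer ordering, the default) or
#'   `"given"`.
#' @return A `secsaxs_dataset`; `meta$paths` records the source files in
#'   load order.
#' @export
load_frames <- function(paths, sigma_fill = NULL, q_tol = 1e-8,
                        order = c("filename", "given")) {
  order <- match.arg(order)
  if (length(paths) < 1) abort("no input files.")
  if (order == "filename") {
    ord <- frame_ordinal_from_name(paths)
    if (!anyNA(ord)) paths <- paths[base::order(ord)]
  }
  frames <- lapply(paths, read_saxs_frame, sigma_fill = sigma_fill)
  q0 <- frames[[1]]$q
  for (i in seq_along(frames)) {
    qi <- frames[[i]]$q
    if (length(qi) != length(q0) ||
        any(abs(qi - q0) > q_tol * pmax(abs(q0), 1e-30))) {
      abort(paste0("inconsistent q grids: ", paths[i],
                   " differs from ", paths[1]))
    }
  }
  secsaxs_dataset(
    q = q0,
    I = vapply(frames, function(f) f$intensity, numeric(length(q0))),
    S = vapply(frames, function(f) f$sigma, numeric(length(q0))),
    meta = list(paths = paths)
  )
}

#' Read one SAXS frame file
#'
#' @inheritParams load_frames
#' @param path File path.
#' @return A tibble with columns `q`, `intensity`, `sigma`.
#' @export
read_saxs_frame <- function(path, sigma_fill = NULL) {
  tab <- tryCatch(
    read.table(path, comment.char = "#", header = FALSE,
               colClasses = "numeric"),
    error = function(e) abort(paste0("unreadable file ", path, ": ",
                                     conditionMessage(e)))
  )
  if (ncol(tab) < 2) abort(paste0(path, ": fewer than 2 numeric columns."))
  q <- tab[[1]]
  if (any(diff(q) <= 0)) abort(paste0(path, ": non-monotone q."))
  intensity <- tab[[2]]
  if (ncol(tab) >= 3) {
    sigma <- tab[[3]]
  } else if (!is.null(sigma_fill)) {
    sigma <- sigma_fill$k * sqrt(pmax(intensity, sigma_fill$floor %||% 0))
  } else {
    abort(paste0(path, ": no sigma column (supply `sigma_fill` to opt in)."))
  }
  tibble(q = q, intensity = intensity, sigma = sigma)
}

#' Write a dataset back to per-frame ASCII files
#'
#' One 3-column file per frame, named `prefix_NNNN.dat`, full double
#' precision so that [load_frames()] reproduces the dataset exactly.
#'
#' @param ds A `secsaxs_dataset`.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Invisibly, the written paths.
#' @export
write_frames <- function(ds, dir, prefix = "frame") {
  stopifnot(inherits(ds, "secsaxs_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%05d.dat", prefix, ds$frames))
  for (j in seq_along(paths)) {
    tab <- cbind(ds$q, ds$I[, j], ds$S[, j])
    lines <- apply(format(tab, digits = 17, trim = TRUE, scientific = TRUE),
                   1, paste, collapse = " ")
    writeLines(c("# q intensity sigma", lines), paths[j])
  }
  invisible(paths)
}

#' Drop chromatograms that contain only noise
#'
#' Removes q rows whose mean signal-to-noise ratio (mean over frames of
#' intensity / sigma) falls below `snr_threshold`. The supporting trimming
#' rule used by the original GUI is not published; this mean-SNR criterion
#' is this package's own documented substitute.
#'
#' @param ds A `secsaxs_dataset` with strictly positive sigmas.
#' @param snr_threshold Minimum acceptable mean SNR (default 1.5).
#' @return The trimmed dataset. The dropped q values and their SNRs are
#'   attached as a tibble in attribute `"trim_report"`; surviving rows keep
#'   their original order.
#' @export
trim_noise_chromatograms <- function(ds, snr_threshold = 1.5) {
  stopifnot(inherits(ds, "secsaxs_dataset"))
  if (any(ds$S <= 0)) abort("trimming requires strictly positive sigma.")
  snr <- rowMeans(ds$I / ds$S)
  keep <- snr >= snr_threshold
  if (!any(keep)) abort("no usable chromatograms: all rows fall below the SNR threshold.")
  out <- secsaxs_dataset(ds$q[keep], ds$I[keep, , drop = FALSE],
                         ds$S[keep, , drop = FALSE], frames = ds$frames,
                         time = ds$time, meta = ds$meta)
  attr(out, "trim_report") <- tibble(q = ds$q[!keep], mean_snr = snr[!keep])
  out
}

#' Export a table to CSV at full precision
#'
#' RFC-4180-style CSV with a header row; numeric columns are written with
#' shortest-round-trip precision so that [read_csv_table()] reproduces the
#' values exactly.
#'
#' @param table A data frame or tibble (columns of equal length).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_csv <- function(table, path) {
  table <- as.data.frame(table)
  num <- vapply(table, is.numeric, logical(1))
  table[num] <- lapply(table[num], function(x) {
    vapply(x, function(v) format(v, digits = 17, scientific = NA), character(1))
  })
  write.table(table, path, sep = ",", row.names = FALSE, quote = TRUE,
              qmethod = "double")
  invisible(path)
}

#' Re-import a CSV written by [export_csv()]
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_csv_table <- function(path) {
  as_tibble(read.table(path, sep = ",", header = TRUE,
                       stringsAsFactors = FALSE))
}
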