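# Shared fixtures, all built in code.

# small deterministic dataset: nq x nt, intensities i*10 + j
tiny_dataset <- function(nq = 4, nt = 3) {
  I <- outer(seq_len(nq) * 10, seq_len(nt), `+`)
  secsaxs_dataset(q = seq(0.01, by = 0.01, length.out = nq), I = I,
                  S = matrix(1, nq, nt))
}

# forward-simulate fouling on a clean signal: deposits at t_k proportional
# to the clean signal at t_{k-1}; returns observed = signal + baseline
forward_foul <- function(signal, gamma) {
  n <- length(signal)
  B <- numeric(n)
  for (k in 2:n) B[k] <- B[k - 1] + gamma * signal[k - 1]
  list(observed = signal + B, baseline = B)
}

# write a 3-column frame file, returns path
write_frame_file <- function(q, I, S = NULL, dir = tempdir(),
                             name = "frame_00001.dat") {
  path <- file.path(dir, name)
  tab <- if (is.null(S)) cbind(q, I) else cbind(q, I, S)
  write.table(tab, path, row.names = FALSE, col.names = FALSE)
  path
}

# exhaustive fair-sign null: distribution of the longest equal-sign run
# among all 2^n sequences, via vectorized bit tricks (independent of the
# package's recursion)
enumerate_longest_runs <- function(n) {
  xs <- 0:(2^n - 1)
  if (n == 1) return(rep(1L, 2))
  # y marks positions where adjacent bits differ; equal-bit runs of x are
  # zero-runs of y. Longest equal run = longest 1-run of the complement + 1.
  y <- bitwXor(xs, bitwShiftR(xs, 1L))
  mask <- 2^(n - 1) - 1
  w <- bitwAnd(bitwNot(y), mask)
  k <- integer(length(xs))
  run <- w
  iter <- 0L
  while (any(run != 0)) {
    iter <- iter + 1L
    k[run != 0] <- iter
    run <- bitwAnd(run, bitwShiftR(run, 1L))
  }
  k + 1L
}

# single-species synthetic layout used by several modules
single_species_spec <- function(seed = 7, gamma = 0, noise_frac = 0.01,
                                n_frames = 200L,
                                q = seq(0.005, 0.15, length.out = 60)) {
  synthetic_spec(
    q = q, n_frames = n_frames,
    species = list(synthetic_species(
      30, 100, peak_model("EMG_GMG", 300, 90, 8, 6, 5))),
    gamma = gamma, noise_frac = noise_frac, seed = seed)
}
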