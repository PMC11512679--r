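# Small builders shared across the suite. Everything is generated in code;
# no fixture files.

tiny_coch <- function(n_chords = 400L, seed = 1L, contrast = "low",
                      n_trials = 2L) {
  generate_drc(drc_spec(n_chords, contrast, n_trials = n_trials, seed = seed))
}

# trial x bin Poisson counts around a fixed rate vector
poisson_counts <- function(rate, n_trials, seed = 1L) {
  set.seed(seed)
  matrix(rpois(n_trials * length(rate), rep(rate, each = n_trials)),
         nrow = n_trials)
}

# destroy stimulus locking while keeping single-trial statistics: permute
# time bins independently within each trial
shuffle_within_trials <- function(counts, seed = 1L) {
  set.seed(seed)
  t(apply(counts, 1L, sample))
}

# latency-aligned correlation between a fitted STRF kernel and the
# generating kernel of a simulated IC unit
kernel_recovery_r <- function(model, unit_kernel, latency_bins) {
  kf <- ln_kernel(model)[, ncol(ln_kernel(model)):1]   # cols h = 0,1,...
  kt <- effective_strf_kernel(unit_kernel, latency_bins,
                              n_history = ncol(kf))
  cor(as.vector(kf), as.vector(kt))
}
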