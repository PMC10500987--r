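# synthetic frame builders shared across test files

# frames whose (shifted) gap (eps2 + dalpha) - eps1 is a constant c in every
# window: eps1 arbitrary, eps2 = eps1 + c
const_gap_frames <- function(schedule, c_gap, n = 40, seed = 1) {
  set.seed(seed)
  dplyr::bind_rows(lapply(seq_along(schedule), function(m) {
    e1 <- rnorm(n)
    tibble::tibble(window = m, lambda = schedule[m], step = seq_len(n),
                   eps1 = e1, eps2 = e1 + c_gap)
  }))
}

# frames with window-wise Gaussian gaps
gauss_gap_frames <- function(schedule, mean, sd, n, seed = 1) {
  set.seed(seed)
  dplyr::bind_rows(lapply(seq_along(schedule), function(m) {
    gap <- rnorm(n, mean, sd)
    tibble::tibble(window = m, lambda = schedule[m], step = seq_len(n),
                   eps1 = 0, eps2 = gap)
  }))
}

# small sampled toy dataset reused by analysis/calibration tests
toy_frames <- function(n_windows = 21, n_steps = 20000, seed = 101,
                       delta_alpha = 0, model = default_toy_model()) {
  run_fep_schedule(model, lambda_schedule(n_windows), delta_alpha,
                   sampler_config(n_steps = n_steps,
                                  burn_in = max(1000, n_steps / 10),
                                  seed = seed))
}

# build an evb_profile directly from bin values (for extraction tests)
manual_profile <- function(dg, xs = seq_along(dg), valid = TRUE,
                           temperature = 300) {
  prof <- tibble::tibble(bin = seq_along(dg), xs = xs, dg = dg,
                         count = 1000L,
                         valid = rep_len(valid, length(dg)))
  out <- tibble::new_tibble(prof, class = "evb_profile")
  attr(out, "temperature") <- temperature
  attr(out, "normalization") <- "manual"
  out
}
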