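# Shared fixtures: small, fast synthetic configurations.

tiny_cfg <- function(n_az = 60, n_stimuli = 20, seed = 1L, ...) {
  synth_config(n_az = n_az, n_stimuli = n_stimuli, seed = seed, ...)
}

# A noise- and nuisance-free configuration for constructed-stack tests.
clean_cfg <- function(n_az = 10, n_stimuli = 5, seed = 1L, ...) {
  synth_config(n_az = n_az, n_stimuli = n_stimuli, seed = seed,
               noise_sd = 0, baseline_structure = 0,
               drift_px_per_frame = 0, bleach_tau_s = Inf, ...)
}

# One AZ exactly on a pixel centre, silent population, for closed-form
# flash tests.
one_az_cfg <- function(...) {
  cfg <- clean_cfg(n_az = 1, ...)
  cfg$field_size_um <- c(5.52, 5.52)   # 40 x 40 px at 0.138
  cfg
}

one_az_table <- function(cfg) {
  # pixel (20, 20) centre: (20 - 0.5) * 0.138
  az <- data.frame(az_id = 1L, x_um = 19.5 * cfg$pixel_size_um,
                   y_um = 19.5 * cfg$pixel_size_um)
  az$true_class <- factor("active", c("silent", "spont_only", "active"))
  az$true_pr <- 1
  az
}

# Build a pr_map data.frame by hand.
make_prmap <- function(pr_hat, n_stimuli = 100, spont_count = NULL) {
  n <- length(pr_hat)
  spont_count <- spont_count %||% rep(1L, n)
  out <- data.frame(az_id = seq_len(n),
                    n_evoked = as.integer(round(pr_hat * n_stimuli)),
                    n_stimuli = n_stimuli, pr_hat = pr_hat,
                    spont_count = spont_count,
                    spont_rate_hz = spont_count / 300)
  class(out) <- c("pr_map", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
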