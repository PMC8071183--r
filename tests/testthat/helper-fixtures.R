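# Shared fixtures: quiet cascade parameter sets and small simulation helpers.

quiet_params <- function(...) {
  cascade_params(noise_sd = 0, ...)
}

# Reference full-agonist kinetics used across tests (dopamine at WT).
da_wt <- function() ligand_kinetics("dopamine", k_on = 9.70e7, k_off = 0.197)

# Pure monoexponential decay/rise samples on a 156 Hz grid.
pure_decay <- function(tau, amplitude = 1, offset = 0, duration = 8 * tau,
                       noise_sd = 0, seed = 1, sample_rate = 156) {
  t <- seq(0, duration, by = 1 / sample_rate)
  y <- amplitude * exp(-t / tau) + offset
  if (noise_sd > 0) {
    y <- y + withr::with_seed(seed, rnorm(length(t), sd = noise_sd))
  }
  tibble::tibble(time = t, current = -y)
}

as_trace <- function(df, sample_rate = 156) {
  out <- tibble::as_tibble(df)
  class(out) <- unique(c("girk_trace", class(out)))
  attr(out, "params") <- cascade_params(sample_rate = sample_rate)
  out
}

# Memoized heavy computation shared between acceptance blocks.
.recovery_cache <- new.env(parent = emptyenv())

table1_recovery <- function(n_seeds = 20, seed = 42) {
  key <- paste0("r", n_seeds, "_", seed)
  if (is.null(.recovery_cache[[key]])) {
    .recovery_cache[[key]] <- run_study_pipeline(
      n_seeds = n_seeds, seed = seed, run_staircase = FALSE
    )
  }
  .recovery_cache[[key]]
}
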