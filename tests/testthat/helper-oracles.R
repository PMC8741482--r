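# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Two-sided permutation test on the difference of means.
perm_t_p <- function(a, b, n_perm = 4000, seed = 1) {
  obs <- abs(mean(a) - mean(b))
  pooled <- c(a, b)
  na <- length(a)
  withr::with_seed(seed, {
    stats <- replicate(n_perm, {
      idx <- sample(length(pooled), na)
      abs(mean(pooled[idx]) - mean(pooled[-idx]))
    })
  })
  (sum(stats >= obs - 1e-12) + 1) / (n_perm + 1)
}

# Bootstrap sd of a ratio of means.
boot_ratio_sd <- function(treated, vehicle, n_boot = 4000, seed = 1) {
  withr::with_seed(seed, {
    ratios <- replicate(n_boot, {
      mean(sample(treated, replace = TRUE)) /
        mean(sample(vehicle, replace = TRUE))
    })
  })
  sd(ratios)
}

# Condition-summary row builder for rescue-screen tests.
cond_row <- function(label, condition, values) {
  tibble::tibble(label = label, condition = condition,
                 mean = mean(values),
                 sd = if (length(values) >= 2) sd(values) else NA_real_,
                 n = length(values), values = list(values))
}

# Small simulated batch: control + WT + mutant event tables sharing a seed
# family; returns per-replicate event lists for two_a_replicates().
sim_batch <- function(p_pm, n_reps = 3, n_events = 5000, seed = 1) {
  list(
    mut = lapply(seq_len(n_reps), function(i) {
      simulate_events(cyto_sim_config(n_events = n_events, p_pm = p_pm),
                      seed = seed + 10 * i)
    }),
    wt = lapply(seq_len(n_reps), function(i) {
      simulate_events(cyto_sim_config(n_events = n_events, p_pm = 1),
                      seed = seed + 10 * i + 5)
    }),
    ctrl = simulate_events(
      cyto_sim_config(n_events = n_events, frac_transfected = 0),
      seed = seed + 999)
  )
}
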