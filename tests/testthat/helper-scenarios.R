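# shared builders for the demographic and regime fixtures used across tests

five_scenarios <- function(n0 = 1000) standard_scenarios(n0)

yule_params <- function(t_i = 100, total_time = 500, max_lineages = 64) {
  # isolation completes RI long before any contact could matter
  regime_parameters(t_i = t_i, t_s = 1e7, t_r = 1,
                    timing_mode = "exponential",
                    total_time = total_time, max_lineages = max_lineages)
}

fuse_only <- c(reinforce = 0, extinct_one = 0, extinct_both = 0)

# study conditions of the mutation-rate sweep (see the methods vignette)
sweep_conditions <- function() {
  list(
    base = regime_parameters(t_i = 3000, t_s = 12000, t_r = 1,
                             timing_mode = "exponential",
                             contact_outcomes = fuse_only,
                             total_time = 15000, max_lineages = 256),
    epsilon = 0.05,
    u_values = 10^seq(-3, -2, length.out = 5),
    n_histories = 500L
  )
}

# pooled scaled internode waiting times from Yule histories: with k lineages
# extant, the wait to the next isolating event is Exp(k / t_i), so
# k * wait / t_i should be standard exponential
scaled_yule_waits <- function(t_i, n_target, master_seed) {
  waits <- numeric()
  seeds <- derive_seeds(master_seed, 1000L)
  for (s in seeds) {
    h <- simulate_history(yule_params(t_i = t_i), seed = s)
    iso <- h$events[h$events$type == "isolation", ]
    if (!nrow(iso)) next
    times <- c(0, iso$time)
    w <- diff(times)
    k <- seq_along(w)          # lineage count during each waiting interval
    waits <- c(waits, w * k / t_i)
    if (length(waits) >= n_target) break
  }
  waits[seq_len(n_target)]
}
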