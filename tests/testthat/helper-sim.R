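# Shared fixture builders. Everything is generated in code; tests that need
# randomness seed it explicitly so the suite is reproducible.

# A small noiseless trace setup: params, amplicon spec, processed reference.
make_noiseless_setup <- function(n_cpg = 5L, methylation = 0.4, ...) {
  p <- trace_sim_params(n_cpg_sites = n_cpg, methylation = methylation,
                        noise_sd = 0, ...)
  spec <- sim_amplicon_spec(p)
  ref <- simulate_reference_trace(p)
  list(params = p, spec = spec, ref = ref,
       frame = process_reference(ref, spec))
}

# Hand-rolled product-limit survival at each distinct event time, the
# independent oracle for km_estimate.
oracle_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(tt))
  for (j in seq_along(tt)) {
    n_j <- sum(time >= tt[j])
    d_j <- sum(time == tt[j] & event == 1)
    s <- s * (1 - d_j / n_j)
    out[j] <- s
  }
  list(time = tt, surv = out)
}

# Breslow log partial likelihood for a single covariate on untied data;
# independent of the package's Newton-Raphson path, used for grid searches.
oracle_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# A small survival cohort with a marker; moderate censoring.
make_toy_cohort <- function(n = 60, beta = 1, seed = 11, cens_rate = 0.02) {
  set.seed(seed)
  x <- runif(n)
  t_event <- rexp(n, rate = 0.05 * exp(beta * x))
  t_cens <- rexp(n, rate = cens_rate)
  data.frame(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens), x = x)
}
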