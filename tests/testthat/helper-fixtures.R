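# Shared fixtures and independent oracles, built in code at test time.

# Short synthetic recordings for module tests (cheap: 60 s).
short_synth <- function(scenario = "scenario1", seed = 1L, duration_s = 60) {
  generate_aecg(scenario_preset(scenario, duration_s = duration_s,
                                seed = seed))
}

# Exhaustive k-medoids oracle: global optimum total cost over all medoid
# triples (squared-Euclidean assignment), independent of the package's
# clustering path.
brute_force_kmedoids_cost <- function(values, k = 3) {
  best <- Inf
  for (combo in utils::combn(length(values), k, simplify = FALSE)) {
    med <- values[combo]
    cost <- sum(apply(vapply(med, function(m) (values - m)^2,
                             numeric(length(values))), 1, min))
    if (cost < best) best <- cost
  }
  best
}
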