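# Shared small synthetic fixtures (cheap to regenerate per file).

small_sim <- function(seed = 11, informative = c(2, 5), effect = 2.5) {
  generate_trialset(
    n_trials = 60, n_channels = 6, n_samples = 11,
    informative_channels = informative, effect_size = effect,
    noise_correlation = 0.3, seed = seed
  )
}

# A weight store built by hand from explicit per-model weight vectors.
# `weights` is a list of channels x samples matrices (one per repeat).
manual_store <- function(weights, participant_id = "P01") {
  models <- lapply(weights, function(w) {
    lay <- slrco::feature_layout(nrow(w), ncol(w))
    structure(
      list(
        mu = c(as.vector(t(w)), 0), # channel-major features + bias
        alpha = rep(1, length(w) + 1),
        sigma_diag = rep(0.1, length(w) + 1),
        active_set = which(c(as.vector(t(w)), 1) != 0),
        layout = lay, n_iter = 1L, converged = TRUE,
        has_bias = TRUE, bias_index = length(w) + 1L,
        standardization = list(
          centre = rep(0, length(w)),
          scale = rep(1, length(w))
        ),
        n_features = length(w), n_trials = 10L
      ),
      class = "slr_model"
    )
  })
  slrco::build_weight_store(models,
    n_repeats = length(weights), n_periods = 1L,
    participant_id = participant_id
  )
}
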