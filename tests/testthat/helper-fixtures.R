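# Shared fixtures, built in code at test time.

# a quiet default profile for deterministic kinematic checks
noiseless_profile <- function(seed = 1, ...) {
  participant_profile(gyro_bias = 0, accel_noise_sd = 0, gyro_noise_sd = 0,
                      mounting_misalignment = 0, seed = seed, ...)
}

# small cached cohort shared across test files (generation is seeded,
# so caching only saves time, not determinism)
.fixture_env <- new.env()

small_cohort <- function(n_controls = 3, n_impaired = 0, seed = 7) {
  key <- paste("coh", n_controls, n_impaired, seed, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_cohort(n_controls, n_impaired, seed)
  }
  .fixture_env[[key]]
}

# a fast pipeline config for tests
fast_config <- function(...) {
  onset_config(nn = nn_spec(25, max_iter = 300), n_per_class = 300, ...)
}

# a trained neural-network bundle (3 training participants) plus a held-out
# probe, shared between the streaming and acceptance tests
trained_bundle_fixture <- function() {
  if (is.null(.fixture_env$stream_bundle)) {
    coh <- small_cohort(4, 0, seed = 7)
    cfg <- onset_config(nn = nn_spec(25, max_iter = 400), n_per_class = 500)
    .fixture_env$stream_bundle <- list(
      bundle = fit_onset_model(coh[1:3], "neural_net", cfg),
      probe = coh[[4]])
  }
  .fixture_env$stream_bundle
}

# brute-force per-class metric tallies from raw label pairs (independent of
# the confusion-matrix path)
brute_metrics <- function(y_true, y_pred, classes) {
  vapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    tn <- sum(y_true != cl & y_pred != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    sens <- if (tp + fn == 0) 0 else tp / (tp + fn)
    spec <- if (tn + fp == 0) 0 else tn / (tn + fp)
    acc <- (tp + tn) / length(y_true)
    f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
    c(accuracy = acc, precision = prec, sensitivity = sens,
      specificity = spec, f1 = f1)
  }, numeric(5))
}
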