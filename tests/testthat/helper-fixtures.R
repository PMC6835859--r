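# Shared fixtures. Gain normalisation of the published detector classes is
# deterministic but takes a few seconds, so the normalised classes are
# computed once per test run and reused.

.fixture_env <- new.env(parent = emptyenv())

normalized_class <- function(which = 1L) {
  key <- paste0("cls", which)
  if (is.null(.fixture_env[[key]])) {
    raw <- if (which == 1L) rd_class(1.07, 1.0, 0.022) else rd_class(3.42, 2.5, 0.022)
    .fixture_env[[key]] <- rd_normalize_gain(raw)
  }
  .fixture_env[[key]]
}

# Full-size published configuration with pre-normalised gains (identical to
# rd_config() defaults after engine-side normalisation).
published_cfg <- function(...) {
  rd_config(classes = list(normalized_class(1L), normalized_class(2L)), ...)
}

# Reduced two-class configuration for fast population tests: same published
# tuning parameters (so cached gains apply), fewer detectors, shorter retina.
small_cfg <- function(...) {
  cls1 <- normalized_class(1L); cls1$count <- 8L
  cls2 <- normalized_class(2L); cls2$count <- 8L
  rd_config(classes = list(cls1, cls2), retina_extent_deg = 60, ...)
}

# Single-class miniature configuration for fitting tests.
tiny_cfg <- function(...) {
  cls1 <- normalized_class(1L); cls1$count <- 6L
  rd_config(classes = list(cls1), retina_extent_deg = 30,
            trial_duration_s = 0.6, ...)
}

# Synthetic trial CSV fixture on disk.
write_synth_csv <- function(path, elements = c(1, 4), n_trials = 8, seed = 3) {
  trials <- synth_behavior(elements, lapply(elements, function(el) {
    transition_steps(5.36 * el^0.462, n_steps = 4)
  }), n_trials, seed = seed)
  write_trials(trials, path)
  trials
}
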