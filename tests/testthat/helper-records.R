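# Shared fixtures: short synthetic recordings built in code, cached per
# session so several test files can reuse the same record cheaply.

.fixture_env <- new.env(parent = emptyenv())

test_record <- function(group = "PFA_T-", seed = 7, post_s = 200,
                        noise_sd = 0, ...) {
  key <- paste(group, seed, post_s, noise_sd, ...)
  if (is.null(.fixture_env[[key]])) {
    cfg <- generator_config(duration_post_s = post_s,
                            noise_sd_mV = noise_sd, ...)
    .fixture_env[[key]] <- generate_lesion_recording(cfg, group, seed = seed)
  }
  .fixture_env[[key]]
}

test_features <- function(group = "PFA_T-", seed = 7, post_s = 200,
                          noise_sd = 0) {
  key <- paste("feat", group, seed, post_s, noise_sd)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <-
      build_feature_series(test_record(group, seed, post_s, noise_sd))
  }
  .fixture_env[[key]]
}

# match detected peaks to truth within a tolerance (samples); returns
# sensitivity and positive predictive value
match_peaks <- function(detected, truth, tol) {
  if (length(detected) == 0) return(c(sens = 0, ppv = NA_real_))
  hit_truth <- vapply(truth, function(r) any(abs(detected - r) <= tol),
                      logical(1))
  hit_det <- vapply(detected, function(d) any(abs(truth - d) <= tol),
                    logical(1))
  c(sens = mean(hit_truth), ppv = mean(hit_det))
}
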