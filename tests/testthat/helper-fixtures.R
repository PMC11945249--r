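# Shared fixtures. Cohorts are generated once per test run and memoized;
# everything is built in code (no stored data files).

.fixture_env <- new.env(parent = emptyenv())

default_cohort <- function(seed = 1) {
  key <- paste0("cohort_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_cohort(gradient_config(), seed = seed)
  .fixture_env[[key]]
}

big_cohort <- function(seed = 1, n = 5000) {
  key <- paste0("big_", seed, "_", n)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_cohort(gradient_config(), seed = seed,
                                           n_sites = n)
  .fixture_env[[key]]
}

balanced_activities <- function(sample_id = "bal") {
  data.frame(sample_id = sample_id, bg = 2, cbh = 1, nag = 1, lap = 2, ap = 3,
             stringsAsFactors = FALSE)
}

expect_ev_error <- function(expr, class) expect_error(expr, class = class)
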