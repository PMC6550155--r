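# Simulated cohorts shared across test files, built once per test run.
# Seeds are fixed study constants, not tuning knobs.

.cohort_cache <- new.env(parent = emptyenv())

# study-scale cohort at the reference population sizes (242 TD / 56 D),
# full 300-s recordings; features extracted once
study_cohort <- function() {
  if (is.null(.cohort_cache$study)) {
    coh <- generate_cohort(cohort_spec(seed = 42))
    fc <- extract_cohort(coh$recordings)
    .cohort_cache$study <- list(coh = coh, fc = fc)
  }
  .cohort_cache$study
}

# balanced 40 + 40 cohort for direction-recovery checks
balanced_cohort <- function() {
  if (is.null(.cohort_cache$balanced)) {
    coh <- generate_cohort(cohort_spec(n_td = 40, n_d = 40, seed = 101))
    fc <- extract_cohort(coh$recordings)
    .cohort_cache$balanced <- list(coh = coh, fc = fc)
  }
  .cohort_cache$balanced
}

# small quick cohort for protocol plumbing tests (short recordings)
small_cohort <- function() {
  if (is.null(.cohort_cache$small)) {
    prof <- default_profiles(duration = 60)
    coh <- generate_cohort(cohort_spec(n_td = 10, n_d = 8,
                                       td_profile = prof$td,
                                       d_profile = prof$d, seed = 9))
    fc <- extract_cohort(coh$recordings)
    .cohort_cache$small <- list(coh = coh, fc = fc)
  }
  .cohort_cache$small
}
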