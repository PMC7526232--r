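# The default study-shaped cohort is expensive to score, so it is built once
# and shared across test files (test-acceptance.R runs first and fills the
# cache).
.cohort_cache <- new.env(parent = emptyenv())

default_pipeline <- function() {
  if (is.null(.cohort_cache$res)) {
    .cohort_cache$res <- suppressMessages(run_pipeline(seed = 1))
  }
  .cohort_cache$res
}

# A small cohort configuration for structural/IO tests: 6 recordings of 5 s.
tiny_config <- function(...) {
  cohort_config(
    group_sizes = c(normal = 1, wheeze_only = 1, crackles_pm_wheeze = 1,
                    cf_clear = 0),
    quadrants = "left_upper",
    exclusions_per_device = 0,
    duration_s = 5,
    ...
  )
}
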