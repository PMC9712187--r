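# In-code fixtures shared across test files.

# two-stratum exposure table
tiny_exposure <- function() {
  data.frame(sex = c("male", "female"), age_group = "45-49",
             mean_pct = c(18, 16), sd_pct = c(8.1, 7.2),
             se_mean_pct = c(0.9, 0.8), population = c(5e6, 5.2e6),
             stringsAsFactors = FALSE)
}

# matching event table, all outcomes and metrics
tiny_events <- function(exposure = tiny_exposure()) {
  g <- expand.grid(i = seq_len(nrow(exposure)), outcome = c("CHD", "stroke"),
                   metric = c("deaths", "incident_cases", "dalys"),
                   stringsAsFactors = FALSE)
  base <- c(deaths = 1000, incident_cases = 4000, dalys = 25000)
  v <- base[g$metric] * ifelse(g$outcome == "stroke", 0.7, 1) *
    ifelse(exposure$sex[g$i] == "male", 1.2, 1)
  data.frame(sex = exposure$sex[g$i], age_group = exposure$age_group[g$i],
             outcome = g$outcome, metric = g$metric, value = unname(v),
             ui_low = unname(0.8 * v), ui_high = unname(1.2 * v),
             stringsAsFactors = FALSE)
}

# default synthetic bundle, generated once per test run (oracle is costly)
the_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_study(synthetic_config())
    cache
  }
})

chd_curve <- function() build_rr_curve(rr_spec("CHD", 1.29, 1.12, 1.48))
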