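# Shared fixtures: reduced-scale simulation configs for unit tests and a
# deterministic toy summary set.

small_config <- function(...) {
  simulation_config(m = 2000L, ...)
}

null_config <- function(m = 2000L, alpha1 = 0.05) {
  simulation_config(m = m, alpha1 = alpha1,
                    effect_model = effect_size_model(
                      list(list(kind = "point", weight = 1))))
}

# A handful of summary rows with known values.
toy_summaries <- function() {
  data.frame(snp_id = paste0("rs", 1:4),
             mu_hat = c(0.30, -0.25, 0.45, 0.10),
             se = c(0.06, 0.05, 0.08, 0.05),
             stringsAsFactors = FALSE)
}
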