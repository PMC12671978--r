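# Small, fast scenarios for unit tests; full-scale runs live in the
# acceptance tests.
small_confounder <- function(...) {
  scenario_preset("confounder", n = 2000L, iterations = 20L, seed = 421L, ...)
}

small_instrument <- function(...) {
  scenario_preset("instrument", n = 2000L, iterations = 20L, seed = 422L, ...)
}
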