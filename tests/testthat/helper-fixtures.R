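# Shared fixtures, built in code.

# Small config for fast cohort draws.
small_config <- function(seed = 1L, ...) {
  generator_config(n_hc = 28L, n_csa = 14L, n_ra = 82L, seed = seed, ...)
}

# Brute-force AUC: mean over all event/nonevent pairs, ties counted 1/2.
auc_by_enumeration <- function(score, outcome) {
  ev <- score[outcome]; ne <- score[!outcome]
  mean(outer(ev, ne, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Printed healthy-reference cut points used throughout the scoring tests.
printed_ref <- function() reference_quartiles(618.83, 734.55, 822.36)
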