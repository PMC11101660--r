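# shared generators for property-style tests

random_pair <- function() {
  gene_disease_pair(
    disease_id = "d", gene_id = "g",
    carrier_prevalence = runif(1, 1e-4, 0.02),
    penetrance = runif(1, 0.01, 0.99),
    precision = sample(c(10, 100, 1000, 10000), 1),
    test_disutility = sample(c(0, -runif(1, 0, 1e-4)), 1)
  )
}

random_disutilities <- function() {
  disutility_spec(runif(1, 0.1, 10), runif(1, 0.1, 10))
}

# four outcome utilities consistent with the stated ordering assumptions
random_outcome_utilities <- function() {
  c_gneg_dneg <- runif(1, 1, 10)
  c_gpos_dpos <- runif(1, 1, 10)
  outcome_utilities(
    c_gpos_dpos = c_gpos_dpos,
    c_gneg_dneg = c_gneg_dneg,
    c_gpos_dneg = c_gneg_dneg - runif(1, 0.01, 0.9),
    c_gneg_dpos = c_gpos_dpos - runif(1, 0.01, 0.9)
  )
}
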