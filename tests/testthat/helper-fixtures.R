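# Shared fixtures, generated in code.

# German-type inventory population at the published BEECH moments.
beech_population <- function(n = 4000, seed = 101) {
  generate_population(population_spec("BEECH", n, 35, 15, 25, 7,
                                      seed = seed))
}

# Small fixed design whose predictions stay far from zero (DBH 25-60 cm),
# so recovery replicates on a population of exactly n trees always use the
# same design matrix.
fixed_design_population <- function(n = 50, seed = 5) {
  set.seed(seed)
  data.frame(species = "BEECH", dbh_cm = runif(n, 25, 60),
             ht_m = runif(n, 18, 32))
}

# A simple single-coefficient linear equation AGB = b1 * DBH.
single_coef_equation <- function(b1 = 2) {
  biomass_equation("toy_linear", "linear-in-basis", b1, basis = "dbh")
}

expect_symmetric_psd <- function(M, tol = 1e-8) {
  expect_equal(M, t(M), tolerance = tol)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -tol * max(abs(ev)))
}
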