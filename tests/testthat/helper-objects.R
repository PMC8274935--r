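# Shared fixtures: the generator truth preset, lidocaine drug parameters,
# and small utilities used across test files.

truth <- default_truth()
lido20 <- drug_params(conc = uM(20))
lido5 <- drug_params(conc = uM(5))
drug_free <- drug_params(conc = 0)

v_grid <- seq(-120, 40, by = 5)

expect_within <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
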