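# Tiny analytic instances used across tests; all solved by hand.

# One input, one output: B uses twice A's input for the same output.
toy_ab <- function() {
  transform_undesirable(
    dmu_data(cbind(x = c(1, 2)), cbind(y = c(1, 1)), dmu_ids = c("A", "B")))
}

# A(1,1), B(2,4), C(4,6): B is the CRS-best ratio; A scales up (IRS),
# C scales down (DRS).
toy_abc <- function() {
  transform_undesirable(
    dmu_data(cbind(x = c(1, 2, 4)), cbind(y = c(1, 4, 6)),
             dmu_ids = c("A", "B", "C")))
}

# Two inputs, one output: B matches A on input 1 but wastes one unit of
# input 2 -> radially efficient yet mix-inefficient.
toy_mix <- function() {
  transform_undesirable(
    dmu_data(cbind(x1 = c(1, 1), x2 = c(1, 2)), cbind(y = c(1, 1)),
             dmu_ids = c("A", "B")))
}
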