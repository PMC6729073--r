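test_that("hand-solved radial toys reproduce", {
  # a single DMU is its own frontier
  one <- transform_undesirable(dmu_data(cbind(x = 2), cbind(y = 3)))
  s1 <- solve_radial(one, 1, "crs")
  expect_equal(s1$theta, 1)
  expect_true(s1$fully_efficient)
  expect_equal(unname(s1$input_slacks), 0)

  # B needs only half its input for A's output
  ab <- toy_ab()
  expect_equal(solve_radial(ab, "B", "crs")$theta, 0.5, tolerance = 1e-9)
  expect_equal(solve_radial(ab, "A", "crs")$theta, 1)

  # radially efficient but mix-inefficient: theta = 1 with residual slack
  mix <- toy_mix()
  sB <- solve_radial(mix, "B", "crs")
  expect_equal(sB$theta, 1)
  expect_equal(unname(sB$input_slacks), c(0, 1), tolerance = 1e-9)
  expect_false(sB$fully_efficient)
  expect_true(solve_radial(mix, "A", "crs")$fully_efficient)
})

test_that("TE decomposes into PTE x SE on the three-DMU instance", {
  abc <- toy_abc()
  ccr <- solve_radial(abc, "C", "crs")
  bcc <- solve_radial(abc, "C", "vrs")
  dec <- decompose_efficiency(ccr, bcc)
  expect_equal(unname(dec), c(0.75, 1, 0.75), tolerance = 1e-9)
  expect_equal(unname(dec["te"]), unname(dec["pte"] * dec["se"]))
  # mismatched DMUs are refused
  expect_error(decompose_efficiency(solve_radial(abc, "A", "crs"), bcc),
               "different DMUs")
  expect_error(decompose_efficiency(bcc, ccr), "CRS solution")
})

test_that("returns to scale are classified from the sum-lambda interval", {
  abc <- toy_abc()
  a <- classify_rts(abc, "A")
  expect_identical(a$label, "IRS")
  expect_equal(unname(a$sum_lambda_bounds[["max"]]), 0.25, tolerance = 1e-7)
  c_ <- classify_rts(abc, "C")
  expect_identical(c_$label, "DRS")
  expect_equal(unname(c_$sum_lambda_bounds[["min"]]), 1.5, tolerance = 1e-7)
  expect_identical(classify_rts(abc, "B")$label, "CRS")
})

test_that("any CCR-efficient DMU with zero slacks is classified CRS", {
  set.seed(31)
  for (i in 1:5) {
    ds <- transform_undesirable(random_dmu_instance())
    for (o in seq_len(nrow(ds$X))) {
      s <- solve_radial(ds, o, "crs")
      if (s$fully_efficient) {
        expect_identical(classify_rts(ds, o, theta = s$theta)$label, "CRS")
      }
    }
  }
})

test_that("envelopment bound theta_CRS <= theta_VRS <= 1 holds everywhere", {
  set.seed(32)
  for (i in 1:8) {
    ds <- transform_undesirable(random_dmu_instance())
    th <- vapply(seq_len(nrow(ds$X)), function(o) {
      c(solve_radial(ds, o, "crs")$theta, solve_radial(ds, o, "vrs")$theta)
    }, numeric(2))
    expect_true(all(th[1, ] <= th[2, ] + 1e-6))
    expect_true(all(th[2, ] <= 1 + 1e-6))
    # the VRS frontier is non-empty
    expect_true(any(th[2, ] >= 1 - 1e-6))
  }
})

test_that("radial scores are invariant to column rescaling", {
  set.seed(33)
  ds <- transform_undesirable(random_dmu_instance(n = 6, m = 2, s = 2))
  scaled <- ds
  scaled$X[, 1] <- scaled$X[, 1] * 1000
  scaled$Y[, 2] <- scaled$Y[, 2] * 0.004
  for (o in 1:6) {
    for (rts in c("crs", "vrs")) {
      expect_equal(solve_radial(ds, o, rts)$theta,
                   solve_radial(scaled, o, rts)$theta, tolerance = 1e-6)
    }
  }
})

test_that("BCC input-oriented scores are invariant to output translation", {
  set.seed(34)
  ds <- transform_undesirable(random_dmu_instance(n = 6, m = 2, s = 2))
  shifted <- ds
  shifted$Y[, 1] <- shifted$Y[, 1] + 50
  for (o in 1:6) {
    expect_equal(solve_radial(ds, o, "vrs")$theta,
                 solve_radial(shifted, o, "vrs")$theta, tolerance = 1e-6)
  }
})

test_that("reference sets of inefficient DMUs contain only efficient peers", {
  set.seed(35)
  for (i in 1:5) {
    ds <- transform_undesirable(random_dmu_instance())
    eff <- vapply(seq_len(nrow(ds$X)),
                  function(o) solve_radial(ds, o, "crs")$fully_efficient,
                  logical(1))
    names(eff) <- ds$dmu_ids
    for (o in seq_len(nrow(ds$X))) {
      s <- solve_radial(ds, o, "crs")
      if (!s$fully_efficient) {
        expect_true(all(eff[setdiff(s$reference_set, s$dmu)]))
      }
    }
  }
})

test_that("solves demand transformed undesirable outputs and valid indices", {
  raw <- dmu_data(cbind(x = c(1, 2)), cbind(y = c(1, 1), bad = c(3, 1)),
                  output_direction = c("desirable", "undesirable"))
  expect_error(solve_radial(raw, 1, "crs"), "transform_undesirable")
  ab <- toy_ab()
  expect_error(solve_radial(ab, 5, "crs"), "out of range")
  expect_error(solve_radial(ab, "Z", "crs"), "unknown DMU")
})
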