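test_that("coefficient vectors are validated per mode", {
  expect_s3_class(coefficient_vector(c(1, 0, 0), c(0, 1, 0), "binary"),
                  "coefficient_vector")
  expect_error(coefficient_vector(c(1, 0.5), c(0, 0), "binary"), "binary")
  expect_error(coefficient_vector(1, 1, "binary"), "binary")   # (1,1) invalid
  expect_error(coefficient_vector(0.5, 1.2, "fuzzy"), "\\[0, 1\\]")
  expect_error(coefficient_vector(c(1, 0), 0, "binary"), "length")
})

test_that("the integrated position score matches hand arithmetic", {
  cf <- coefficient_vector(c(0.8, 0.2), c(0.1, 0.3), "fuzzy")
  expect_equal(position_score_tp(c(2, 1), cf), 1.3 / 2.3, tolerance = 1e-12)
  ones <- coefficient_vector(c(1, 1), c(0, 0), "binary")
  expect_identical(position_score_tp(c(5, 3), ones), 1)
  sym <- coefficient_vector(c(0.4, 0.7), c(0.4, 0.7), "fuzzy")
  expect_identical(position_score_tp(c(2, 9), sym), 0)
  # unmeasured-everywhere (all-zero coefficients): no information -> 0
  zero <- coefficient_vector(c(0, 0), c(0, 0), "binary")
  expect_identical(position_score_tp(c(2, 9), zero), 0)
  expect_error(position_score_tp(c(1, 2, 3), ones), "length")
  expect_error(position_score_tp(c(-1, 2), ones), "nonnegative")
})

test_that("aggregation is the sine of the mean arcsine", {
  expect_equal(aggregate_t(c(0, 1)), sin(pi / 4), tolerance = 1e-12)
  expect_equal(aggregate_t(rep(0.37, 5)), 0.37, tolerance = 1e-12)
  expect_identical(aggregate_t(0.9), 0.9)
  expect_error(aggregate_t(numeric(0)), "empty")
  expect_error(aggregate_t(c(0.2, 1.5)), "\\[-1, 1\\]")
  # tiny float excursions beyond 1 are clipped, not fatal
  expect_equal(aggregate_t(1 + 1e-12), 1, tolerance = 1e-9)
})

test_that("the a-priori score matches hand arithmetic", {
  expect_equal(prior_t0(coefficient_vector(c(0.8, 0.2), c(0.1, 0.3), "fuzzy")),
               0.6 / 1.4, tolerance = 1e-12)
  expect_identical(prior_t0(coefficient_vector(c(1, 1), c(0, 0), "binary")), 1)
  expect_identical(prior_t0(coefficient_vector(c(0.3, 0.6), c(0.3, 0.6),
                                               "fuzzy")), 0)
  expect_identical(prior_t0(coefficient_vector(c(0, 0), c(0, 0), "binary")), 0)
})

test_that("the final estimate contrasts t with t0", {
  expect_equal(estimate_B(0.5, 0.2), 0.3 / 0.9, tolerance = 1e-12)
  expect_identical(estimate_B(1, 0), 1)
  expect_identical(estimate_B(0.3, 0.3), 0)
  expect_identical(estimate_B(1, 1), 0)     # equal extremes: undetermined
  expect_identical(estimate_B(-1, -1), 0)
  expect_identical(estimate_B(1, -1 + 1e-15), 1)  # singular limit
  expect_error(estimate_B(1.5, 0), "\\[-1, 1\\]")
})

test_that("B stays within [-1, 1] across random valid configurations", {
  set.seed(1234)
  for (rep in 1:500) {
    N <- sample(1:8, 1); m <- sample(1:12, 1)
    cf <- coefficient_vector(runif(N), runif(N), "fuzzy")
    tp <- vapply(seq_len(m), function(p)
      position_score_tp(runif(N, 0, 10), cf), numeric(1))
    B <- estimate_B(aggregate_t(tp), prior_t0(cf))
    expect_true(B >= -1 - 1e-12 && B <= 1 + 1e-12)
  }
})

test_that("swapping ability and inability coefficients negates everything", {
  set.seed(77)
  N <- 6; m <- 9
  a <- runif(N); b <- runif(N)
  S <- matrix(runif(N * m, 0, 5), m, N)
  cf <- coefficient_vector(a, b, "fuzzy")
  cfr <- coefficient_vector(b, a, "fuzzy")
  tp <- apply(S, 1, position_score_tp, coeffs = cf)
  tpr <- apply(S, 1, position_score_tp, coeffs = cfr)
  expect_equal(tpr, -tp, tolerance = 1e-12)
  expect_equal(aggregate_t(tpr), -aggregate_t(tp), tolerance = 1e-12)
  expect_equal(prior_t0(cfr), -prior_t0(cf), tolerance = 1e-12)
  expect_equal(estimate_B(aggregate_t(tpr), prior_t0(cfr)),
               -estimate_B(aggregate_t(tp), prior_t0(cf)), tolerance = 1e-12)
})

test_that("position scores are invariant to a common scaling of S", {
  set.seed(88)
  cf <- coefficient_vector(runif(4), runif(4), "fuzzy")
  s <- runif(4, 0, 3)
  expect_equal(position_score_tp(s * 17.3, cf), position_score_tp(s, cf),
               tolerance = 1e-12)
})

test_that("predict_pair wires scores and coefficients together", {
  ds <- toy_dataset()
  # binary mode: an unseen protein similar to T3/T4 should favor their ligands
  q <- "GSHMLEDPVDAFWEIQQLRRTVGELEARLKVSEQ"
  pr <- predict_pair(q, "L1", ds, mode = "binary", frame = 7)
  expect_s3_class(pr, "pcm_prediction")
  expect_identical(pr$m, nchar(q))
  expect_identical(pr$N, 4L)
  expect_true(abs(pr$B) <= 1)
  expect_true(all(abs(pr$tp) <= 1))
  # t derives from tp, B from (t, t0) exactly as the equation layer says
  expect_equal(pr$t, aggregate_t(pr$tp), tolerance = 1e-12)
  expect_equal(pr$B, estimate_B(pr$t, pr$t0), tolerance = 1e-12)
  expect_error(predict_pair(q, "nope", ds, mode = "binary"), "ligand id")
})

test_that("identical training sequences force t = t0 and B = 0", {
  ds <- toy_dataset()
  same <- ds
  same$proteins[] <- ds$proteins[[1]]
  pr <- predict_pair("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQA", "L1", same,
                     mode = "binary", frame = 7)
  expect_equal(pr$t, pr$t0, tolerance = 1e-12)
  expect_equal(pr$B, 0, tolerance = 1e-12)
})

test_that("fuzzy mode with coefficients forced to 0/1 equals binary mode", {
  ds <- toy_dataset()
  q <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQT"
  for (lig in names(ds$ligands)) {
    bin <- predict_pair(q, lig, ds, mode = "binary", frame = 7)
    a <- bin$coefficients$a; b <- bin$coefficients$b
    S <- positional_score_matrix(q, ds$proteins, 7)
    cf <- coefficient_vector(a, b, "fuzzy")
    tp <- apply(S, 1, position_score_tp, coeffs = cf)
    B <- estimate_B(aggregate_t(tp), prior_t0(cf))
    expect_identical(B, bin$B)
  }
})
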