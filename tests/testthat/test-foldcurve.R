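test_that("the saddle-node toy has a cusp-free fold line in (p, d)", {
  ## xdot = p - 2 d x^2 folds at x = 0 for every d; the normal-form
  ## coefficient w'B(v,v) = -4d never vanishes, so no cusp exists
  net <- reaction_network("X", list(
    reaction(character(), "X", "p", 1),
    reaction(c("X", "X"), character(), "d", 1)))
  br <- continue_equilibria(net, c(p = 1, d = 1), "p", c(-0.5, 2), x0 = 0.7)
  expect_length(br$folds, 1L)
  fc <- continue_fold_curve(net, c(p = 1, d = 1), c("d", "p"),
                            br$folds[[1]],
                            range = list(a = c(0.2, 5), b = c(-1, 2)),
                            start_param = "b")
  expect_length(fc$cusps, 0L)
  ## the fold line is p = 0 at every traced d
  expect_lt(max(abs(fc$params[, "p"])), 1e-6)
  expect_true(all(is.finite(fc$bcoef)))
  expect_true(all(abs(fc$bcoef) > 1e-8))
})

test_that("GAL fold curve in (k7, k5) passes through the nominal folds and
          locates the low-parameter cusp", {
  gal <- gal_fix()
  br <- gal_k5_branch()
  f_lo <- br$folds[[which.min(vapply(br$folds, `[[`, 0, "param"))]]
  fc <- continue_fold_curve(gal$network, gal$parameters, c("k7", "k5"),
                            f_lo, range = list(a = c(0.5, 40),
                                               b = c(0.5, 60)),
                            step_control = list(h0 = 0.02, hmin = 1e-8,
                                                hmax = 0.5,
                                                max_steps = 1200L))
  expect_gte(length(fc$cusps), 1L)
  cp <- fc$cusps[[which.min(vapply(fc$cusps, `[[`, 0, "param_a"))]]
  ## this model's cusp; the published value is (4.363, 3.835)
  expect_equal(cp$param_a, 4.360, tolerance = 2e-3)
  expect_equal(cp$param_b, 3.834, tolerance = 2e-3)
  ## the curve passes through both one-parameter folds at nominal k7
  k7_nom <- unname(gal$parameters["k7"])
  near_nom <- abs(fc$params[, "k7"] - k7_nom) < 0.2
  expect_true(any(abs(fc$params[near_nom, "k5"] - 12.4841) < 0.2))
  ## every curve point is a genuine fold: f = 0 and J v = 0
  idx <- with_seed(9L, sample(nrow(fc$params), 10))
  for (i in idx) {
    pl <- gal$parameters
    pl["k7"] <- fc$params[i, "k7"]; pl["k5"] <- fc$params[i, "k5"]
    x <- fc$states[i, ]
    expect_lt(max(abs(rhs(gal$network, x, pl))),
              1e-6 * max(1, max(abs(x))))
    sv <- svd(jacobian_x(gal$network, x, pl))$d
    expect_lt(sv[9], 1e-6 * sv[1])
  }
})

test_that("bistable region in the (k7, k5) plane matches multistart counts
          inside and outside the cusp-bounded wedge", {
  gal <- gal_fix()
  ms <- multistart_spec(n_random = 120, guesses = gal$reference_states,
                        seed = 23L)
  count_stable <- function(k7, k5) {
    pl <- gal$parameters; pl["k7"] <- k7; pl["k5"] <- k5
    sum(vapply(find_equilibria(gal$network, pl, ms), `[[`, TRUE,
               "stable"))
  }
  ## derive test points from the computed fold curve itself: at a given
  ## k7, the two fold k5 values bound the bistable wedge
  br <- gal_k5_branch()
  f_lo <- br$folds[[which.min(vapply(br$folds, `[[`, 0, "param"))]]
  fc <- continue_fold_curve(gal$network, gal$parameters, c("k7", "k5"),
                            f_lo, range = list(a = c(0.5, 40),
                                               b = c(0.5, 60)),
                            step_control = list(h0 = 0.02, hmin = 1e-8,
                                                hmax = 0.2,
                                                max_steps = 1500L))
  for (k7q in c(12, 20)) {
    near <- abs(fc$params[, "k7"] - k7q) < 2
    expect_gte(sum(near), 2L)
    k5f <- range(fc$params[near, "k5"])
    expect_gt(k5f[2] - k5f[1], 1)    # both fold branches sampled here
    expect_gte(count_stable(k7q, mean(k5f)), 2L)        # inside wedge
    expect_equal(count_stable(k7q, 0.5 * k5f[1]), 1L)   # below lower fold
    expect_equal(count_stable(k7q, 2.0 * k5f[2]), 1L)   # above upper fold
  }
  expect_equal(count_stable(3, 3.8), 1L)    # below the cusp: monostable
})
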