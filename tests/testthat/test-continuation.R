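test_that("the saddle-node toy folds exactly at p = 0", {
  ## xdot = p - x^2 (zero-order production, quadratic degradation at rate
  ## 0.5 removing two molecules per event)
  net <- reaction_network("X", list(
    reaction(character(), "X", "p", 1),
    reaction(c("X", "X"), character(), "d", 0.5)))
  br <- continue_equilibria(net, c(p = 1, d = 0.5), "p", c(-0.5, 2),
                            x0 = 1)
  expect_length(br$folds, 1L)
  expect_equal(br$folds[[1]]$param, 0, tolerance = 1e-8)
  expect_equal(br$folds[[1]]$state, 0, tolerance = 1e-6)
  expect_null(bistable_interval(br))      # single fold: no interval
})

test_that("linear systems produce fold-free branches", {
  bd <- toy_models()$birth_death
  br <- continue_equilibria(bd$network, bd$parameters, "k", c(0.5, 3),
                            x0 = 1.5)
  expect_length(br$folds, 0L)
  expect_null(bistable_interval(br))
  ## branch points are equilibria: x = k / mu along the whole branch
  expect_lt(max(abs(br$states[, 1] - br$param)), 1e-6)
  expect_true(all(br$stable))
})

test_that("GAL k5 branch is S-shaped with two folds delimiting
          bistability", {
  br <- gal_k5_branch()
  expect_length(br$folds, 2L)
  iv <- bistable_interval(br)
  ## fold locations from the Moore-Spence refinement of this model; the
  ## published figure reports [12.57, 26.62]
  expect_equal(iv[1], 12.4841, tolerance = 1e-3)
  expect_equal(iv[2], 26.3372, tolerance = 1e-3)
  ## every branch point satisfies the steady-state equations
  gal <- gal_fix()
  idx <- with_seed(8L, sample(length(br$param), 25))
  for (i in idx) {
    pl <- gal$parameters; pl["k5"] <- br$param[i]
    r <- max(abs(rhs(gal$network, br$states[i, ], pl)))
    expect_lt(r, 1e-6 * max(1, max(abs(br$states[i, ]))))
  }
  ## stability flips exactly at the folds: the branch, ordered by
  ## arclength, is stable-unstable-stable
  runs <- rle(br$stable)$values
  expect_equal(runs, c(TRUE, FALSE, TRUE))
  ## fold states carry a genuine simple zero eigenvalue
  for (f in br$folds) {
    pl <- gal$parameters; pl["k5"] <- f$param
    ev <- sort(abs(eigen(jacobian_x(gal$network, f$state, pl),
                         only.values = TRUE)$values))
    expect_lt(ev[1], 1e-6)
    expect_gt(ev[2], 1e-6)
  }
})

test_that("branch export round-trips through CSV with fold flags", {
  br <- gal_k5_branch()
  path <- tempfile(fileext = ".csv")
  tab <- branch_table(br, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), length(br$param))
  expect_equal(back$k5, br$param, tolerance = 1e-12)
  expect_equal(sum(back$near_fold), 2L)
  expect_setequal(unique(back$stability), c("stable", "unstable"))
})

test_that("bistability region test: inside vs outside the k5 interval", {
  gal <- gal_fix()
  iv <- bistable_interval(gal_k5_branch())
  ms <- multistart_spec(n_random = 120, guesses = gal$reference_states,
                        seed = 17L)
  inside <- with_seed(21L, runif(3, iv[1] + 0.5, iv[2] - 0.5))
  outside <- c(iv[1] - 2, iv[2] + 2, iv[2] + 15)
  for (k5 in inside) {
    pl <- gal$parameters; pl["k5"] <- k5
    eqs <- find_equilibria(gal$network, pl, ms)
    expect_gte(sum(vapply(eqs, `[[`, TRUE, "stable")), 2L)
  }
  for (k5 in outside) {
    pl <- gal$parameters; pl["k5"] <- k5
    eqs <- find_equilibria(gal$network, pl, ms)
    expect_equal(sum(vapply(eqs, `[[`, TRUE, "stable")), 1L)
  }
})
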