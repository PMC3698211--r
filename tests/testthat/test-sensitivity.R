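test_that("sensitivities start at zero and obey the steady-state closed
          form of the birth-death process", {
  bd <- toy_models()$birth_death
  tr <- sensitivity_integrate(bd$network, bd$parameters, x0 = 1.5,
                              horizon = 30)
  expect_equal(as.numeric(tr$raw[, , 1]), c(0, 0))     # S(0) = 0 exactly
  Tn <- length(tr$time)
  ## x* = k / mu: normalized sensitivity +1 to k, -1 to mu
  expect_equal(unname(tr$normalized[1, "k", Tn]), 1, tolerance = 1e-4)
  expect_equal(unname(tr$normalized[1, "mu", Tn]), -1, tolerance = 1e-4)
})

test_that("sensitivity trajectories satisfy the forward equations and
          match finite differences for the GAL model", {
  gal <- gal_fix()
  net <- gal$network; p <- gal$parameters
  eq <- gal_eq("low")
  st <- gal_sens("low")
  Tn <- length(st$time)
  ## three seeded (i, j) spot checks against central differences with a
  ## 1e-4 relative parameter step
  pairs <- with_seed(13L, cbind(sample(9, 3, TRUE), sample(23, 3, TRUE)))
  for (r in 1:3) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    h <- 1e-4 * p[j]
    pp <- p; pp[j] <- pp[j] + h
    pm <- p; pm[j] <- pm[j] - h
    xp <- simulate_network(net, pp, eq$state, 20, rtol = 1e-9,
                           atol = 1e-11, keep = "last")$state
    xm <- simulate_network(net, pm, eq$state, 20, rtol = 1e-9,
                           atol = 1e-11, keep = "last")$state
    fd <- (xp[2, i] - xm[2, i]) / (2 * h)
    expect_lt(abs(st$raw[i, j, Tn] - fd) / max(1e-8, abs(fd)), 1e-3)
  }
  ## the run is tagged with the nominal parameters it is local to
  expect_identical(unname(st$parameters), unname(as.numeric(p)))
})

test_that("normalization masks concentrations below the floor", {
  t1 <- toy_models()$toy1d
  tr <- sensitivity_integrate(t1$network, t1$parameters, x0 = 0.5,
                              horizon = 25)
  Tn <- length(tr$time)
  ## x(t) -> 0, so late normalized entries are masked
  expect_true(all(is.na(tr$normalized[, , Tn])))
  expect_true(all(is.finite(tr$raw[, , Tn])))
})

test_that("ranking is deterministic with alphabetical tie-breaks", {
  fake <- structure(list(
    time = c(0, 1, 2),
    normalized = array(0, c(1, 3, 3),
                       dimnames = list("X", c("b", "a", "c"), NULL)),
    raw = array(0, c(1, 3, 3),
                dimnames = list("X", c("b", "a", "c"), NULL))),
    class = "sensitivity_trajectory")
  rk <- rank_parameters(fake)
  expect_equal(rk$parameter, c("a", "b", "c"))    # all-zero: alphabetical
  expect_equal(rk$score, rep(0, 3))
  fake$normalized[1, "c", ] <- c(0, 2, 2)
  rk <- rank_parameters(fake)
  expect_equal(rk$parameter[1], "c")
  expect_equal(rk$score[1], 3)                    # trapezoid of |s| over t
})

test_that("sensitivity_table exports the long format losslessly", {
  bd <- toy_models()$birth_death
  tr <- sensitivity_integrate(bd$network, bd$parameters, x0 = 0.2,
                              horizon = 2)
  tab <- sensitivity_table(tr)
  expect_equal(nrow(tab), 1 * 2 * length(tr$time))
  expect_setequal(unique(tab$parameter), c("k", "mu"))
  expect_equal(tab$raw[tab$parameter == "k" &
                         tab$time == max(tr$time)],
               tr$raw[1, "k", length(tr$time)])
})
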