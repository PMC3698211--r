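test_that("GAL multistart finds two stable states matching the published
          values plus an intermediate saddle", {
  eqs <- gal_equilibria()
  expect_length(eqs, 3L)
  stable <- Filter(function(e) e$stable, eqs)
  unstable <- Filter(function(e) !e$stable && !e$marginal, eqs)
  expect_length(stable, 2L)
  expect_length(unstable, 1L)
  gal <- gal_fix()
  states <- vapply(stable, `[[`, numeric(9), "state")
  low <- states[, which.min(states[9, ])]
  high <- states[, which.max(states[9, ])]
  expect_lt(max(abs(low - gal$reference_states[, "low"]) /
                  pmax(abs(gal$reference_states[, "low"]), 1e-6)), 1e-3)
  expect_lt(max(abs(high - gal$reference_states[, "high"]) /
                  pmax(abs(gal$reference_states[, "high"]), 1e-6)), 1e-3)
  ## the saddle is intermediate in the reporter coordinate (G1) with
  ## exactly one unstable mode (not componentwise between: e.g. its G80
  ## exceeds both stable values)
  saddle <- unstable[[1]]
  expect_equal(sum(Re(saddle$eigenvalues) > 1e-8), 1L)
  expect_gt(saddle$state[9], low[9])
  expect_lt(saddle$state[9], high[9])
})

test_that("Newton from the printed 4-decimal states converges in a few
          iterations", {
  gal <- gal_fix()
  for (w in c("low", "high")) {
    r <- newton_equilibrium(gal$network, gal$parameters,
                            gal$reference_states[, w])
    expect_true(r$converged)
    expect_lte(r$iterations, 5L)
    ## printed values carry 4-decimal rounding; refinement moves them by
    ## up to ~2e-4 relative
    expect_lt(max(abs(r$state - gal$reference_states[, w]) /
                    pmax(abs(r$state), 1)), 5e-4)
  }
})

test_that("closed-form toy equilibria are recovered exactly", {
  spec_small <- multistart_spec(n_random = 60, log_range = c(1e-2, 10),
                                seed = 5L)
  bd <- toy_models()$birth_death
  eqs <- find_equilibria(bd$network, bd$parameters, spec_small)
  expect_length(eqs, 1L)
  expect_true(eqs[[1]]$stable)
  expect_equal(eqs[[1]]$state, 1.5, tolerance = 1e-9)  # k / mu

  t1 <- toy_models()$toy1d
  eqs <- find_equilibria(t1$network, t1$parameters, spec_small)
  states <- sort(vapply(eqs, `[[`, 0, "state"))
  expect_equal(states, c(0, 1), tolerance = 1e-8)
  expect_true(eqs[[which.min(states)]]$stable)
  expect_false(eqs[[which.max(states)]]$stable)
})

test_that("toy2d multistart matches the closed-form equilibrium set", {
  t2 <- toy_models()$toy2d
  eqs <- find_equilibria(t2$network, t2$parameters,
                         multistart_spec(n_random = 150,
                                         log_range = c(1e-3, 3),
                                         guesses = t2$known_equilibria,
                                         seed = 7L))
  found <- vapply(eqs, `[[`, numeric(2), "state")
  expect_equal(ncol(found), 4L)
  for (j in seq_len(ncol(t2$known_equilibria))) {
    d <- apply(found, 2, function(x)
      max(abs(x - t2$known_equilibria[, j])))
    expect_lt(min(d), 1e-7)
  }
  stable <- vapply(eqs, `[[`, TRUE, "stable")
  expect_equal(sum(stable), 2L)   # the two exclusion states
})

test_that("equilibria_table round-trips stability labels and residuals", {
  eqs <- gal_equilibria()
  gal <- gal_fix()
  csv <- tempfile(fileext = ".csv"); json <- tempfile(fileext = ".json")
  tab <- equilibria_table(eqs, gal$network, csv = csv, json = json)
  expect_equal(nrow(tab), 3L)
  expect_setequal(tab$stability, c("stable", "stable", "unstable"))
  back <- utils::read.csv(csv)
  expect_equal(back$G3, tab$G3, tolerance = 1e-12)
  payload <- jsonlite::fromJSON(json)
  expect_length(payload$state, 3L)
})

test_that("multistart sampling is deterministic under the seed and leaves
          the global RNG untouched", {
  spec <- multistart_spec(n_random = 10, seed = 99L)
  set.seed(1); before <- runif(1)
  a <- bistacert:::multistart_points(spec, 3L)
  set.seed(1); expect_equal(runif(1), before)
  b <- bistacert:::multistart_points(spec, 3L)
  expect_identical(a, b)
})
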