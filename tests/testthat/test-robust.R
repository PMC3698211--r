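bd_pbox <- function() {
  bd <- toy_models()$birth_death
  parameter_box(bd$parameters, c("k", "mu"),
                intervals = rbind(c(1, 1), c(2, 2)))
}

test_that("birth-death exclusion verdicts match the exact equilibrium
          interval [0.5, 2]", {
  bd <- toy_models()$birth_death
  pb <- bd_pbox()
  expect_equal(exclusion_certificate(bd$network, axis_box(3, 4),
                                     pb)$verdict, "certified-empty")
  expect_equal(exclusion_certificate(bd$network, axis_box(2.05, 2.5),
                                     pb)$verdict, "certified-empty")
  expect_equal(exclusion_certificate(bd$network, axis_box(0.1, 0.45),
                                     pb)$verdict, "certified-empty")
  ## boxes meeting the equilibrium set must never be excluded
  expect_equal(exclusion_certificate(bd$network, axis_box(0.5, 2),
                                     pb)$verdict, "unknown")
  expect_equal(exclusion_certificate(bd$network, axis_box(1.4, 1.6),
                                     pb)$verdict, "unknown")
})

test_that("certified-empty witnesses re-check rigorously", {
  bd <- toy_models()$birth_death
  ce <- exclusion_certificate(bd$network, axis_box(3, 4), bd_pbox())
  expect_false(is.null(ce$witness))
  expect_gt(ce$witness$h, 0)
  expect_true(all(ce$witness$y >= 0))
  ## independent re-evaluation of the Farkas value from the stored witness
  rel <- bistacert:::build_relaxation(bd$network, ce$state_box,
                                      ce$param_box)
  expect_equal(bistacert:::witness_value(rel, ce$witness$y,
                                         ce$witness$mu),
               ce$witness$h, tolerance = 1e-9)
})

test_that("box shrinkage converges to the exact robust interval within a
          slab width", {
  bd <- toy_models()$birth_death
  sh <- shrink_robust_box(bd$network, axis_box(0.1, 10), bd_pbox())
  ## exact robust equilibrium set is [k_min/mu_max, k_max/mu_min] = [0.5, 2]
  slab <- 0.1 * (sh$box$upper - sh$box$lower)
  expect_lte(sh$box$lower, 0.5)
  expect_gte(sh$box$lower, 0.5 - slab)
  expect_gte(sh$box$upper, 2)
  expect_lte(sh$box$upper, 2 + slab)
  expect_true(any(sh$log$cut))
})

test_that("zero slab fraction is a degenerate no-op schedule", {
  bd <- toy_models()$birth_death
  sh <- shrink_robust_box(bd$network, axis_box(0.1, 10), bd_pbox(),
                          slab_fraction = 0)
  expect_equal(sh$box$lower, 0.1)
  expect_equal(sh$box$upper, 10)
  expect_equal(sh$rounds, 0L)
})

test_that("enlarging the parameter box can only enlarge the shrunken box", {
  bd <- toy_models()$birth_death
  shrunk_for <- function(delta) {
    pb <- parameter_box(bd$parameters, c("k", "mu"), delta)
    shrink_robust_box(bd$network, axis_box(0.1, 10), pb)$box
  }
  b_small <- shrunk_for(5)
  b_big <- shrunk_for(40)
  expect_lte(b_big$lower, b_small$lower + 1e-12)
  expect_gte(b_big$upper, b_small$upper - 1e-12)
})

test_that("GAL exclusion certificates respect soundness", {
  gal <- gal_fix()
  net <- gal$network; p <- gal$parameters
  theta <- c("k1", "k2", "k5", "k7", "k8", "k9", "mu13", "mu16", "mu17")
  eq <- gal_eq("low")$state
  ## a tight box around a verified equilibrium is never certified empty
  ce <- exclusion_certificate(net,
                              axis_box(eq * 0.99, eq * 1.01,
                                       species = net$species_names),
                              parameter_box(p, theta, 0))
  expect_equal(ce$verdict, "unknown")
  ## a far-away box with dominant degradation is certified empty
  ce2 <- exclusion_certificate(net, axis_box(rep(5000, 9), rep(6000, 9)),
                               parameter_box(p, theta, 2))
  expect_equal(ce2$verdict, "certified-empty")
})

test_that("point-parameter shrinkage around the low GAL state keeps the
          equilibrium inside", {
  gal <- gal_fix()
  net <- gal$network
  eq <- gal_eq("low")$state
  pb <- parameter_box(gal$parameters)
  init <- axis_box(eq * 0.5, eq * 2, species = net$species_names)
  sh <- shrink_robust_box(net, init, pb, max_rounds = 6L)
  expect_true(all(sh$box$lower <= eq & eq <= sh$box$upper))
  expect_true(any(sh$box$lower > init$lower | sh$box$upper < init$upper))
})

test_that("printed initial boxes contain their published equilibria and
          match the documented values", {
  S <- printed_initial_boxes()
  gal <- gal_fix()
  expect_equal(S$S10$lower[5], 0.175)     # G80 interval
  expect_equal(S$S10$upper[5], 12.001)
  expect_equal(S$S20$lower[4], 2.236)     # G4 interval
  expect_equal(S$S20$upper[4], 123.599)
  expect_true(bistacert:::box_contains(S$S10,
                                       gal$reference_states[, "low"]))
  expect_true(bistacert:::box_contains(S$S20,
                                       gal$reference_states[, "high"]))
  ## and they equal the printed DA boxes under the rho = 4 scaling rule
  D <- printed_da_boxes()
  expect_equal(S$S10$upper, D$D1$upper * 4, tolerance = 2e-3)
  expect_equal(S$S10$lower[c(1, 2, 5, 6, 7)],
               D$D1$lower[c(1, 2, 5, 6, 7)] / 4, tolerance = 2e-3)
})

test_that("robust bistability at point parameters returns disjoint boxes
          containing the nominal equilibria", {
  gal <- gal_fix()
  D <- printed_da_boxes()
  r <- robust_bistability(gal$network, gal$parameters, D$D1, D$D2,
                          delta = 0.001, max_rounds = 3L, n_draws = 5L)
  expect_equal(r$status, "ok")
  expect_true(r$disjoint)
  expect_true(all(r$soundness))
  expect_true(bistacert:::box_contains(r$S1, gal_eq("low")$state))
  expect_true(bistacert:::box_contains(r$S2, gal_eq("high")$state))
})
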