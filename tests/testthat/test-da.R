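## Certification tests are anchored to the closed-form feasibility region
## of the 1-species toy xdot = -x + x^2 about the stable equilibrium 0:
## for a shifted box [l, u] (l < 0 < u < 1) the three certificate
## conditions reduce to gamma > u, M >= gamma^2 / min(l^2, u^2) and
## M <= 1 / max(l^2, u^2), so a box is certifiable iff
## max(u, |l|)^2 < min over admissible gamma... concretely: symmetric
## boxes [-u, u] are certifiable for every u < 1 (any gamma in (u, 1)),
## while [-0.5, 0.9] is NOT (needs gamma > 0.9 and 4 gamma^2 <= 1/0.81).

toy1d_quad <- function() {
  t1 <- toy_models()$toy1d
  quadratic_decomposition(t1$network, t1$parameters, 0)
}

test_that("toy1d certification matches the closed-form feasibility set", {
  qs <- toy1d_quad()
  ## certifiable: symmetric boxes below the unstable equilibrium
  for (u in c(0.5, 0.8, 0.9)) {
    cert <- certify_box(qs, axis_box(-u, u, "shifted"))
    expect_s3_class(cert, "da_certificate")
    expect_gt(cert$gamma, u)            # the analytic requirement
    m <- as.numeric(cert$M)
    expect_gte(m * u^2, cert$gamma^2 - 1e-7)
    expect_lte(m * u^2, 1 + 1e-9)
  }
  ## not certifiable: asymmetric box (far face forces M too large) and
  ## any box crossing the unstable equilibrium at 1
  for (bounds in list(c(-0.5, 0.9), c(-0.5, 1.1), c(-0.2, 1.0001))) {
    cert <- certify_box(qs, axis_box(bounds[1], bounds[2], "shifted"))
    expect_false(inherits(cert, "da_certificate"))
    expect_equal(cert$status, "not-certified")
  }
})

test_that("certificates re-verify and survive shrinking", {
  qs <- toy1d_quad()
  cert <- certify_box(qs, axis_box(-0.7, 0.7, "shifted"))
  chk <- check_certificate(qs, cert$box, cert$gamma, cert$M, margin = 0)
  expect_true(chk$valid)
  expect_gt(chk$margins$lyapunov, 0)
  expect_gt(chk$margins$M_pd, 0)
  ## monotonicity: scaling a certified box toward the origin stays certified
  for (rho in c(0.9, 0.5, 0.1)) {
    smaller <- scale_box(cert$box, rho)
    expect_s3_class(certify_box(qs, smaller), "da_certificate")
  }
})

test_that("linear systems certify boxes and grow to the cap", {
  lin <- toy_models()$linear2d
  qs <- quadratic_decomposition(lin$network, lin$parameters, c(0, 0))
  cert <- certify_box(qs, axis_box(c(-2, -2), c(2, 2), "shifted"))
  expect_s3_class(cert, "da_certificate")
  ## globally stable linear system: growth is limited only by the step cap
  gr <- grow_box(qs, axis_box(c(-1, -1), c(1, 1), "shifted"),
                 nonneg_floor = FALSE, max_steps = 8L)
  expect_equal(gr$accepted_steps, 8L)
  expect_true(all(gr$box$upper >= c(1, 1)))
  expect_s3_class(gr$certificate, "da_certificate")
})

test_that("toy1d growth never crosses the basin boundary at 1", {
  qs <- toy1d_quad()
  gr <- grow_box(qs, axis_box(-0.1, 0.1, "shifted"), nonneg_floor = FALSE,
                 max_steps = 60L)
  expect_lt(gr$box$upper, 1)
  expect_gte(gr$box$upper, 0.8)   # conservative but not vacuous
  expect_true(all(gr$frozen) || gr$accepted_steps == 60L)
  ## monotone: grown box contains the seed
  expect_lte(gr$box$lower, -0.1)
  expect_gte(gr$box$upper, 0.1)
})

test_that("certify_box rejects non-Hurwitz linearizations", {
  t1 <- toy_models()$toy1d
  qs <- quadratic_decomposition(t1$network, t1$parameters, 1)  # unstable eq
  expect_error(certify_box(qs, axis_box(-0.1, 0.1, "shifted")),
               "Hurwitz")
})

test_that("a small GAL box about the low state certifies, re-verifies at
          all 512 vertices, and passes simulation spot checks", {
  gal <- gal_fix()
  eq <- gal_eq("low")
  qs <- quadratic_decomposition(gal$network, gal$parameters, eq)
  hw <- 0.01 * pmax(eq$state, 0.5)
  box <- axis_box(-hw, hw, "shifted", species = gal$network$species_names)
  cert <- certify_box(qs, box, gamma_grid = c(0.2287, 0.187, 0.1452))
  expect_s3_class(cert, "da_certificate")
  chk <- check_certificate(qs, box, cert$gamma, cert$M)
  expect_true(chk$valid)
  ## simulation soundness on a reduced sample (the full 512 + 50 sweep runs
  ## in the acceptance suite)
  vb <- verify_box_by_simulation(gal$network, gal$parameters,
                                 from_shifted(box, eq), eq,
                                 n_interior = 6, seed = 2L, horizon = 150,
                                 include_vertices = FALSE)
  expect_equal(vb$fraction, 1.0)
})
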