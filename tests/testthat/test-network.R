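test_that("packaged GAL model has the documented shape", {
  gal <- gal_fix()
  net <- gal$network
  expect_s3_class(net, "reaction_network")
  expect_equal(net$n_species, 9L)
  expect_equal(net$n_reactions, 23L)
  expect_equal(dim(stoichiometry(net)), c(9L, 23L))
  expect_length(gal$parameters, 23L)
  expect_equal(unname(gal$gex), 1000)
  ## representative rate constants and all-unit degradations
  expect_equal(unname(gal$parameters["k5"]), 22.0604)
  expect_equal(unname(gal$parameters["k8"]), 181.4157)
  expect_equal(unname(gal$parameters["kr19"]), 222.0536)
  mus <- grep("^mu", names(gal$parameters), value = TRUE)
  expect_length(mus, 9L)
  expect_true(all(gal$parameters[mus] == 1.0))
})

test_that("gal_model() serves an immutable nominal copy", {
  a <- gal_model()
  a$parameters["k1"] <- 99
  b <- gal_model()
  expect_equal(unname(b$parameters["k1"]), 0.1814)
})

test_that("rhs matches the printed steady states at 4-decimal rounding", {
  gal <- gal_fix()
  ## printed values are rounded to 4 decimals; residuals are bounded by the
  ## rounding amplified through the bimolecular products
  r_low <- rhs(gal$network, gal$reference_states[, "low"], gal$parameters)
  r_high <- rhs(gal$network, gal$reference_states[, "high"], gal$parameters)
  expect_lt(max(abs(r_low)), 0.02)
  expect_lt(max(abs(r_high)), 2.5)
})

test_that("rhs at the origin keeps only zero-order production", {
  gal <- gal_fix()
  f0 <- rhs(gal$network, rep(0, 9), gal$parameters)
  expect_equal(f0[4], unname(gal$parameters["k5"]))  # basal G4 expression
  expect_equal(f0[-4], rep(0, 8))
})

test_that("rhs is homogeneous of degree one for first-order networks", {
  lin <- toy_models()$linear2d
  x <- c(0.7, 1.9)
  expect_equal(rhs(lin$network, 2 * x, lin$parameters),
               2 * rhs(lin$network, x, lin$parameters))
  ## and its Jacobian is constant in x
  expect_equal(jacobian_x(lin$network, x, lin$parameters),
               jacobian_x(lin$network, 10 * x, lin$parameters))
})

test_that("analytic Jacobians agree with central differences", {
  gal <- gal_fix()
  net <- gal$network; p <- gal$parameters
  x <- gal$reference_states[, "low"]
  Jx <- jacobian_x(net, x, p)
  Jx_fd <- fd_jacobian(function(z) rhs(net, z, p), x)
  expect_lt(max(abs(Jx - Jx_fd)) / max(abs(Jx)), 1e-6)
  Jp <- jacobian_p(net, x, p)
  Jp_fd <- fd_jacobian(function(q) rhs(net, x, q), as.numeric(p))
  expect_lt(max(abs(Jp - Jp_fd)) / max(abs(Jp)), 1e-6)
})

test_that("rhs is stoichiometry times the rate vector", {
  gal <- gal_fix()
  net <- gal$network
  set.seed(11)
  for (i in 1:5) {
    x <- 10^runif(9, -2, 3)
    expect_equal(rhs(net, x, gal$parameters),
                 as.numeric(stoichiometry(net) %*%
                              rate_vector(net, x, gal$parameters)))
  }
})

test_that("reaction validation rejects malformed inputs", {
  expect_error(reaction(c("A", "B", "C"), "D", "k", 1), "molecularity")
  expect_error(reaction("A", "B", "k", 0), "positive")
  expect_error(reaction("A", "B", "k", -2), "positive")
  expect_error(reaction_network("A", list(reaction("A", "Z", "k", 1))),
               "unknown species")
})

test_that("parser handles the minimal zero-order network", {
  mod <- parse_model(c("species:", "  - X",
                       "parameters:", "  k: 2.5",
                       "reactions:", "  - 0 -> X @ k"))
  expect_equal(stoichiometry(mod$network), matrix(1, 1, 1,
               dimnames = list("X", "k")))
  expect_equal(rate_vector(mod$network, 3.0), c(k = 2.5))
})

test_that("parser errors on molecularity > 2 and undeclared names", {
  expect_error(parse_model(c("species:", "  - A", "  - B", "  - C",
                             "  - D", "parameters:", "  k: 1",
                             "reactions:", "  - A + B + C -> D @ k")),
               "molecularity")
  expect_error(parse_model(c("species:", "  - A", "parameters:", "  k: 1",
                             "reactions:", "  - A -> 0 @ kq")),
               "undeclared rate constant")
})

test_that("model write/parse round trip is bit-exact on parameters", {
  gal <- gal_fix()
  path <- tempfile(fileext = ".txt")
  write_model(gal$network, path)
  mod2 <- parse_model(path)
  expect_identical(mod2$parameters, gal$parameters)
  expect_identical(stoichiometry(mod2$network), stoichiometry(gal$network))
  x <- gal$reference_states[, "high"]
  expect_identical(rhs(mod2$network, x, mod2$parameters),
                   rhs(gal$network, x, gal$parameters))
})
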