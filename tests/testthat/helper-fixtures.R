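## Shared fixtures. Everything here is cheap; expensive GAL artifacts are
## built lazily and memoised so independent test files can share them.

the_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(the_cache[[key]])) the_cache[[key]] <- force(expr)
  the_cache[[key]]
}

gal_fix <- function() memo("gal", gal_model())

## Newton-refined stable equilibria of the GAL model
gal_eq <- function(which = c("low", "high")) {
  which <- match.arg(which)
  memo(paste0("eq_", which), {
    gal <- gal_fix()
    r <- newton_equilibrium(gal$network, gal$parameters,
                            gal$reference_states[, which])
    stopifnot(r$converged)
    classify_eq(gal$network, gal$parameters, r)
  })
}

classify_eq <- function(net, p, r) {
  ev <- eigen(jacobian_x(net, r$state, p), only.values = TRUE)$values
  structure(list(state = r$state, residual_norm = r$residual_norm,
                 eigenvalues = ev, stable = all(Re(ev) < -1e-8),
                 marginal = any(abs(Re(ev)) <= 1e-8)),
            class = "equilibrium")
}

## full GAL equilibrium list (3 equilibria), reduced multistart for speed
gal_equilibria <- function() memo("eq_all", {
  gal <- gal_fix()
  find_equilibria(gal$network, gal$parameters,
                  multistart_spec(n_random = 250,
                                  guesses = gal$reference_states,
                                  seed = 42L))
})

## the k5 continuation branch (used by several test files)
gal_k5_branch <- function() memo("k5_branch", {
  gal <- gal_fix()
  continue_equilibria(gal$network, gal$parameters, "k5", c(1, 50),
                      x0 = gal_eq("low")$state)
})

## GAL forward-sensitivity runs (shared by the module and acceptance tests)
gal_sens <- function(which = c("low", "high")) {
  which <- match.arg(which)
  memo(paste0("sens_", which), {
    gal <- gal_fix()
    sensitivity_integrate(gal$network, gal$parameters,
                          gal_eq(which)$state, horizon = 20)
  })
}

## finite-difference Jacobian oracle
fd_jacobian <- function(f, x, h_rel = 1e-6) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    h <- h_rel * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}
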