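## Equilibrium location and classification by damped multistart Newton.

#' Multistart specification for equilibrium search
#'
#' Deterministic, seeded description of the Newton start points used by
#' [find_equilibria()]: a log-uniform random subsample over a concentration
#' range, plus optional user guesses, each accompanied by a seeded subset of
#' the corners of the box `guess * (1 +/- guess_perturb)`.
#'
#' @param n_random number of log-uniform random start points.
#' @param log_range positive concentration range (uM) sampled per species.
#' @param guesses optional matrix of start guesses (one column per guess).
#' @param guess_perturb relative half-width of the corner perturbations.
#' @param n_guess_corners corners sampled per guess.
#' @param seed integer seed controlling all sampling.
#' @return object of class `"multistart_spec"`.
#' @export
multistart_spec <- function(n_random = 500, log_range = c(1e-2, 1e4),
                            guesses = NULL, guess_perturb = 0.5,
                            n_guess_corners = 32, seed = 1L) {
  stopifnot(length(log_range) == 2L, all(log_range > 0),
            log_range[1] < log_range[2])
  structure(list(n_random = n_random, log_range = log_range,
                 guesses = guesses, guess_perturb = guess_perturb,
                 n_guess_corners = n_guess_corners, seed = as.integer(seed)),
            class = "multistart_spec")
}

## evaluate a seeded expression without disturbing the global RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

multistart_points <- function(spec, n_species) {
  pts <- with_seed(spec$seed, {
    lo <- log10(spec$log_range[1]); hi <- log10(spec$log_range[2])
    rand <- matrix(10^stats::runif(spec$n_random * n_species, lo, hi),
                   nrow = n_species)
    extra <- NULL
    if (!is.null(spec$guesses)) {
      g <- as.matrix(spec$guesses)
      stopifnot(nrow(g) == n_species)
      corners <- lapply(seq_len(ncol(g)), function(j) {
        signs <- matrix(sample(c(-1, 1), spec$n_guess_corners * n_species,
                               replace = TRUE), nrow = n_species)
        g[, j] * (1 + spec$guess_perturb * signs)
      })
      extra <- cbind(g, do.call(cbind, corners))
    }
    cbind(rand, extra)
  })
  pts
}

#' Damped Newton iteration for a steady state
#'
#' Solves `rhs(network, x, p) = 0` from a single start by Newton's method
#' with backtracking on the max-norm of the residual.
#'
#' @inheritParams rate_vector
#' @param x0 start state.
#' @param tol convergence tolerance on the scaled residual
#'   `max(abs(f)) <= tol * max(1, max(abs(x)))`.
#' @param max_iter iteration cap.
#' @return list with `state`, `residual_norm`, `converged`, `iterations`; or
#'   `converged = FALSE` when the iteration fails.
#' @export
newton_equilibrium <- function(network, p, x0, tol = 1e-10, max_iter = 60L) {
  x <- as.numeric(x0)
  for (it in seq_len(max_iter)) {
    f <- rhs(network, x, p)
    fn <- max(abs(f))
    if (!is.finite(fn))
      return(list(state = x, residual_norm = Inf, converged = FALSE,
                  iterations = it))
    if (fn <= tol * max(1, max(abs(x))))
      return(list(state = x, residual_norm = fn, converged = TRUE,
                  iterations = it - 1L))
    J <- jacobian_x(network, x, p)
    dx <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(dx))
      return(list(state = x, residual_norm = fn, converged = FALSE,
                  iterations = it))
    t <- 1
    repeat {
      fn_new <- max(abs(rhs(network, x + t * dx, p)))
      if (is.finite(fn_new) && fn_new <= (1 - 0.25 * t) * fn) break
      t <- t / 2
      if (t < 1e-10) break
    }
    x <- x + t * dx
  }
  f <- rhs(network, x, p)
  fn <- max(abs(f))
  list(state = x, residual_norm = fn,
       converged = fn <= tol * max(1, max(abs(x))), iterations = max_iter)
}

classify_equilibrium <- function(network, p, state, residual_norm,
                                 marginal_tol = 1e-8) {
  ev <- eigen(jacobian_x(network, state, p), only.values = TRUE)$values
  re <- Re(ev)
  structure(list(state = state, residual_norm = residual_norm,
                 eigenvalues = ev,
                 stable = all(re < -marginal_tol),
                 marginal = any(abs(re) <= marginal_tol),
                 n_unstable = sum(re > marginal_tol)),
            class = "equilibrium")
}

#' @export
print.equilibrium <- function(x, ...) {
  lab <- if (x$marginal) "marginal" else if (x$stable) "stable" else
    paste0("unstable (", x$n_unstable, " unstable direction",
           if (x$n_unstable > 1) "s", ")")
  cat("Equilibrium (", lab, "), residual ", format(x$residual_norm), "\n",
      sep = "")
  print(round(x$state, 4))
  invisible(x)
}

#' Find all nonnegative equilibria by seeded multistart Newton
#'
#' Runs [newton_equilibrium()] from every start point of a
#' [multistart_spec()], discards non-convergent or negative solutions, and
#' merges duplicates closer than `merge_tol` in relative distance. Each
#' surviving equilibrium is classified by the spectrum of the state Jacobian
#' (eigenvalue real parts within `1e-8` of zero are labelled marginal and not
#' counted as stable).
#'
#' @inheritParams rate_vector
#' @param multistart a [multistart_spec()].
#' @param tol Newton residual tolerance.
#' @param merge_tol relative merge distance for duplicate solutions.
#' @return list of `"equilibrium"` objects, sorted by the first state
#'   coordinate.
#' @examples
#' toy <- toy_models()$toy1d
#' eqs <- find_equilibria(toy$network, toy$parameters,
#'                        multistart_spec(n_random = 50, log_range = c(1e-2, 10)))
#' vapply(eqs, function(e) e$state, 0)
#' @export
find_equilibria <- function(network, p = nominal_parameters(network),
                            multistart = multistart_spec(),
                            tol = 1e-10, merge_tol = 1e-6) {
  starts <- multistart_points(multistart, network$n_species)
  sols <- list()
  for (j in seq_len(ncol(starts))) {
    res <- newton_equilibrium(network, p, starts[, j], tol = tol)
    if (!res$converged) next
    x <- res$state
    if (any(x < -1e-8 * max(1, max(abs(x))))) next      # negative branch
    x[x < 0] <- 0
    dup <- FALSE
    for (s in sols) {
      if (max(abs(s - x)) <= merge_tol * max(1, max(abs(s)))) { dup <- TRUE; break }
    }
    if (!dup) sols[[length(sols) + 1L]] <- x
  }
  sols <- sols[order(vapply(sols, `[`, 0, 1L))]
  lapply(sols, function(x)
    classify_equilibrium(network, p, x, max(abs(rhs(network, x, p)))))
}

#' Write an equilibrium list to CSV / JSON
#'
#' @param equilibria list returned by [find_equilibria()].
#' @param network the network (for species names).
#' @param csv,json optional output paths.
#' @return data frame with one row per equilibrium (invisibly).
#' @export
equilibria_table <- function(equilibria, network, csv = NULL, json = NULL) {
  tab <- do.call(rbind, lapply(equilibria, function(e) {
    row <- as.data.frame(as.list(stats::setNames(e$state,
                                                 network$species_names)))
    row$residual_norm <- e$residual_norm
    row$stability <- if (e$marginal) "marginal" else
      if (e$stable) "stable" else "unstable"
    row
  }))
  if (!is.null(csv)) utils::write.csv(tab, csv, row.names = FALSE)
  if (!is.null(json)) {
    payload <- lapply(equilibria, function(e)
      list(state = e$state, residual_norm = e$residual_norm,
           stable = e$stable, marginal = e$marginal,
           eigenvalues_re = Re(e$eigenvalues),
           eigenvalues_im = Im(e$eigenvalues)))
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = I(17))
  }
  invisible(tab)
}
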