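## One-parameter equilibrium continuation (pseudo-arclength with secant
## predictor and Newton corrector), fold (limit point) detection by sign
## change of det(J) along the branch, and Moore-Spence refinement of the
## detected folds. States and the continuation parameter are scaled by their
## nominal magnitudes so the arclength step control is meaningful across
## coordinates spanning several orders of magnitude.

#' Continue an equilibrium branch in one parameter
#'
#' @inheritParams rate_vector
#' @param param name of the continuation parameter (a rate-constant name).
#' @param range numeric length-2 parameter range to sweep.
#' @param x0 starting equilibrium at the nominal value of `param` (located
#'   automatically from `p` via Newton when `NULL` fails to be supplied).
#' @param step_control list with `h0`, `hmin`, `hmax` (scaled arclength
#'   steps) and `max_steps`.
#' @param tol corrector residual tolerance (scaled).
#' @return object of class `"branch"`: list with `param` (values),
#'   `states` (one row per point), `stable` (labels), `det_sign`, `folds`
#'   (list of refined fold points with `param`, `state`, `null_vector`).
#' @export
continue_equilibria <- function(network, p = nominal_parameters(network),
                                param, range, x0,
                                step_control = list(h0 = 0.01, hmin = 1e-6,
                                                    hmax = 0.5,
                                                    max_steps = 3000L),
                                tol = 1e-9) {
  jp <- match(param, names(network$rate_values))
  if (is.na(jp)) stop("unknown parameter '", param, "'")
  p <- as.numeric(p)
  lam0 <- p[jp]
  stopifnot(range[1] < range[2], lam0 >= range[1], lam0 <= range[2])
  ## refine the starting equilibrium
  st <- newton_equilibrium(network, p, x0)
  if (!st$converged) stop("failed to locate the starting equilibrium")
  sx <- pmax(1, abs(st$state))
  sl <- max(1, abs(lam0))

  pt_list <- list()
  add_point <- function(x, lam) {
    pl <- p; pl[jp] <- lam
    J <- jacobian_x(network, x, pl)
    ev <- eigen(J, only.values = TRUE)$values
    dt <- det(J / max(abs(J)))      # normalized for overflow safety
    pt_list[[length(pt_list) + 1L]] <<- list(
      x = x, lam = lam, stable = all(Re(ev) < -1e-8), det_sign = sign(dt))
  }

  ## corrector: scaled Newton on [f; tangent' (u - upred)] = 0
  correct <- function(x, lam, tvec, uref, h) {
    for (it in 1:25) {
      pl <- p; pl[jp] <- lam
      f <- rhs(network, x, pl)
      u <- c(x / sx, lam / sl)
      g <- sum(tvec * (u - uref)) - h
      res <- max(abs(f)) / max(1, max(abs(x))) ; if (max(abs(c(res, g))) < tol)
        return(list(x = x, lam = lam, ok = TRUE, iters = it))
      J <- jacobian_x(network, x, pl)
      fp <- jacobian_p(network, x, pl)[, jp]
      Jt <- cbind(sweep(J, 2, sx, `*`), fp * sl)
      Amat <- rbind(Jt, tvec)
      du <- tryCatch(solve(Amat, -c(f, g)), error = function(e) NULL)
      if (is.null(du)) return(list(ok = FALSE))
      x <- x + du[seq_along(x)] * sx
      lam <- lam + du[length(du)] * sl
      if (!all(is.finite(x))) return(list(ok = FALSE))
    }
    list(ok = FALSE)
  }

  sweep_dir <- function(dir) {
    x <- st$state; lam <- lam0
    ## initial tangent: null direction of [J, f_p] oriented along dir
    pl <- p; pl[jp] <- lam
    J <- jacobian_x(network, x, pl)
    fp <- jacobian_p(network, x, pl)[, jp]
    dxdl <- tryCatch(solve(J, -fp), error = function(e) NULL)
    tvec <- if (is.null(dxdl)) c(numeric(length(x)), dir) else {
      v <- c(dxdl * 1 / sx * sl, 1)        # d(x/sx)/d(lam/sl), d(lam/sl)
      dir * v / sqrt(sum(v^2))
    }
    h <- step_control$h0
    pts <- 0L
    add_point(x, lam)
    n_here <- 1L
    while (pts < step_control$max_steps) {
      uref <- c(x / sx, lam / sl)
      xp <- x + tvec[seq_along(x)] * sx * h
      lp <- lam + tvec[length(tvec)] * sl * h
      co <- correct(xp, lp, tvec, uref, h)
      if (!co$ok) {
        h <- h / 2
        if (h < step_control$hmin) break
        next
      }
      unew <- c(co$x / sx, co$lam / sl)
      tnew <- unew - uref
      nt <- sqrt(sum(tnew^2))
      if (nt < 1e-14) break
      ## stop at the sweep boundary without recording overshoot points
      ## (large adaptive steps can jump far past the requested range)
      if (co$lam < range[1] - 1e-9 || co$lam > range[2] + 1e-9) break
      tvec <- tnew / nt
      x <- co$x; lam <- co$lam
      add_point(x, lam)
      pts <- pts + 1L; n_here <- n_here + 1L
      ## record the first negative-state point (needed to bracket folds on
      ## the nonnegative boundary), then stop the sweep
      if (any(x < -1e-6 * max(1, max(abs(x))))) break
      if (co$iters <= 4 && h < step_control$hmax) h <- min(step_control$hmax, h * 1.4)
    }
    n_here
  }

  n_fwd <- sweep_dir(+1)
  fwd <- pt_list
  pt_list <- list()
  sweep_dir(-1)
  bwd <- pt_list
  ## assemble in increasing arclength order: reversed backward sweep, then
  ## forward sweep (both include the start; drop one copy)
  all_pts <- c(rev(bwd), fwd[-1])
  lam_v <- vapply(all_pts, `[[`, 0, "lam")
  states <- do.call(rbind, lapply(all_pts, `[[`, "x"))
  stable <- vapply(all_pts, `[[`, TRUE, "stable")
  dsign <- vapply(all_pts, `[[`, 0, "det_sign")

  ## folds: sign change of det(J) between consecutive points
  folds <- list()
  for (i in seq_len(length(all_pts) - 1L)) {
    if (dsign[i] * dsign[i + 1L] < 0) {
      fold <- refine_fold(network, p, jp, states[i, ], lam_v[i],
                          states[i + 1L, ], lam_v[i + 1L])
      if (!is.null(fold)) folds[[length(folds) + 1L]] <- fold
    }
  }
  ## deduplicate folds (sweeps can overlap)
  if (length(folds) > 1) {
    keep <- !duplicated(round(vapply(folds, `[[`, 0, "param"), 6))
    folds <- folds[keep]
  }
  structure(list(param_name = param, param = lam_v, states = states,
                 stable = stable, det_sign = dsign, folds = folds,
                 species = network$species_names),
            class = "branch")
}

#' @export
print.branch <- function(x, ...) {
  cat("Equilibrium branch in '", x$param_name, "': ", length(x$param),
      " points, ", length(x$folds), " fold(s)\n", sep = "")
  for (f in x$folds)
    cat(sprintf("  fold at %s = %.6g\n", x$param_name, f$param))
  invisible(x)
}

## Moore-Spence system {f = 0, J v = 0, c'v = 1} refined by Newton from a
## bracketing pair of branch points.
refine_fold <- function(network, p, jp, x1, lam1, x2, lam2, tol = 1e-10) {
  n <- length(x1)
  x <- (x1 + x2) / 2
  lam <- (lam1 + lam2) / 2
  pl <- p; pl[jp] <- lam
  J <- jacobian_x(network, x, pl)
  sv <- svd(J)
  v <- sv$v[, n]
  cvec <- v
  for (it in 1:40) {
    pl <- p; pl[jp] <- lam
    f <- rhs(network, x, pl)
    J <- jacobian_x(network, x, pl)
    g <- as.numeric(J %*% v)
    res <- c(f, g, sum(cvec * v) - 1)
    if (max(abs(res)) < tol * max(1, max(abs(x)))) {
      return(list(param = unname(lam), state = unname(x),
                  null_vector = unname(v / sqrt(sum(v^2)))))
    }
    fp <- jacobian_p(network, x, pl)[, jp]
    Hv <- hessian_apply(hessian_tensor(network, pl), v)
    dJv_dlam <- network$N[, jp] * sum(monomial_gradients(network, x)[jp, ] * v)
    Amat <- rbind(
      cbind(J, matrix(0, n, n), fp),
      cbind(Hv, J, dJv_dlam),
      c(numeric(n), cvec, 0))
    du <- tryCatch(solve(Amat, -res), error = function(e) NULL)
    if (is.null(du)) return(NULL)
    x <- x + du[1:n]; v <- v + du[n + 1:n]; lam <- lam + du[2 * n + 1]
  }
  NULL
}

#' Export a branch as a flat table
#'
#' One row per branch point: parameter value, full state, stability label
#' and a fold flag (set on the points bracketing each detected fold).
#'
#' @param branch a [continue_equilibria()] result.
#' @param path optional CSV path.
#' @return data frame (invisibly when written to a file).
#' @export
branch_table <- function(branch, path = NULL) {
  tab <- data.frame(branch$param, branch$states,
                    stability = ifelse(branch$stable, "stable", "unstable"))
  names(tab)[1] <- branch$param_name
  names(tab)[2:(1 + ncol(branch$states))] <-
    if (!is.null(branch$species)) branch$species else
      paste0("x", seq_len(ncol(branch$states)))
  tab$near_fold <- FALSE
  for (f in branch$folds) {
    i <- which.min(abs(branch$param - f$param))
    tab$near_fold[i] <- TRUE
  }
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Bistable parameter interval from a branch
#'
#' The interval between the two folds of an S-shaped branch; `NULL` unless
#' exactly two folds are present.
#'
#' @param branch a [continue_equilibria()] result.
#' @return numeric `c(lower, upper)` or `NULL`.
#' @export
bistable_interval <- function(branch) {
  if (length(branch$folds) != 2L) return(NULL)
  sort(vapply(branch$folds, `[[`, 0, "param"))
}
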