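## Two-parameter continuation of fold (limit point) curves and cusp
## detection. The augmented Moore-Spence system
##   f(x, p_a, p_b) = 0,  J(x, p) v = 0,  c'v = 1
## defines a one-dimensional curve in (x, v, p_a, p_b); it is traced by
## pseudo-arclength continuation. Along the curve the fold normal-form
## coefficient b = w' B(v, v) (w the left null vector of J, B the constant
## second-derivative tensor) changes sign exactly at cusp points, which are
## then refined by bisection along the curve.

#' Continue a fold curve in two parameters
#'
#' @inheritParams rate_vector
#' @param params character vector of the two parameter names `(name_a,
#'   name_b)`.
#' @param start a fold point from [continue_equilibria()] (fields `param`,
#'   `state`, `null_vector`), located at the nominal value of `name_a` and
#'   with `start$param` the value of `name_b`... more precisely the fold is
#'   taken at `p` with `params[2]` replaced by `start$param` when
#'   `start_param` is `"b"` (the default, matching folds detected in the
#'   second parameter).
#' @param range list with elements `a` and `b`, each a length-2 numeric
#'   range; the curve is truncated outside.
#' @param start_param which of the two parameters the starting fold was
#'   detected in (`"b"` default).
#' @param step_control list with `h0`, `hmin`, `hmax`, `max_steps`.
#' @param tol corrector tolerance.
#' @return object of class `"fold_curve"`: list with `params` (matrix of
#'   `(p_a, p_b)` values), `states`, `bcoef` (normal-form coefficient),
#'   `cusps` (list with `param_a`, `param_b`, `state`), `status`.
#' @export
continue_fold_curve <- function(network, p = nominal_parameters(network),
                                params, start, range,
                                start_param = "b",
                                step_control = list(h0 = 0.02, hmin = 1e-8,
                                                    hmax = 1, max_steps = 4000L),
                                tol = 1e-9) {
  ja <- match(params[1], names(network$rate_values))
  jb <- match(params[2], names(network$rate_values))
  if (anyNA(c(ja, jb))) stop("unknown parameter name(s)")
  n <- network$n_species
  p <- as.numeric(p)
  if (start_param == "b") p[jb] <- start$param else p[ja] <- start$param
  x <- start$state
  v <- start$null_vector
  cvec <- v / sum(v * v)                  # so that c'v = 1 at the start
  sx <- pmax(1, abs(x))
  sa <- max(1e-3, abs(p[ja])); sb <- max(1e-3, abs(p[jb]))

  pack <- function(x, v, pa, pb) c(x / sx, v, pa / sa, pb / sb)
  unpack <- function(u) list(x = u[seq_len(n)] * sx, v = u[n + seq_len(n)],
                             pa = u[2 * n + 1] * sa, pb = u[2 * n + 2] * sb)

  resid <- function(z) {
    pl <- p; pl[ja] <- z$pa; pl[jb] <- z$pb
    J <- jacobian_x(network, z$x, pl)
    c(rhs(network, z$x, pl), as.numeric(J %*% z$v), sum(cvec * z$v) - 1)
  }
  jac_aug <- function(z) {
    pl <- p; pl[ja] <- z$pa; pl[jb] <- z$pb
    J <- jacobian_x(network, z$x, pl)
    fp <- jacobian_p(network, z$x, pl)
    G <- monomial_gradients(network, z$x)
    Hv <- hessian_apply(hessian_tensor(network, pl), z$v)
    dJv_da <- network$N[, ja] * sum(G[ja, ] * z$v)
    dJv_db <- network$N[, jb] * sum(G[jb, ] * z$v)
    rbind(cbind(sweep(J, 2, sx, `*`), matrix(0, n, n), fp[, ja] * sa,
                fp[, jb] * sb),
          cbind(sweep(Hv, 2, sx, `*`), J, dJv_da * sa, dJv_db * sb),
          c(numeric(n), cvec, 0, 0))
  }
  bcoef_at <- function(z, w_prev = NULL) {
    pl <- p; pl[ja] <- z$pa; pl[jb] <- z$pb
    J <- jacobian_x(network, z$x, pl)
    sv <- svd(J)
    w <- sv$u[, n]
    if (!is.null(w_prev) && sum(w * w_prev) < 0) w <- -w
    H <- hessian_tensor(network, pl)
    list(b = sum(w * vapply(H, function(Hi) sum(z$v * (Hi %*% z$v)), 0)),
         w = w, sigma2 = if (n > 1) sv$d[n - 1] else Inf)
  }

  correct <- function(u_pred, tvec, uref, h) {
    u <- u_pred
    for (it in 1:30) {
      z <- unpack(u)
      r <- c(resid(z), sum(tvec * (u - uref)) - h)
      if (max(abs(r)) < tol * max(1, max(abs(z$x)))) {
        return(list(u = u, ok = TRUE, iters = it))
      }
      A <- rbind(jac_aug(z), tvec)
      du <- tryCatch(solve(A, -r), error = function(e) NULL)
      if (is.null(du) || !all(is.finite(du))) return(list(ok = FALSE))
      u <- u + du
    }
    list(ok = FALSE)
  }

  ## polish the starting fold in the augmented system (p_a, p_b fixed)
  u <- pack(x, v, p[ja], p[jb])
  zz <- unpack(u)
  st0 <- correct(u, c(numeric(2 * n), 1, 0), u, 0)     # freeze p_a
  if (st0$ok) u <- st0$u

  ## initial tangent: null vector of the augmented Jacobian
  z <- unpack(u)
  A <- jac_aug(z)
  tvec <- qr.Q(qr(t(A)), complete = TRUE)[, 2 * n + 2]
  tvec <- tvec / sqrt(sum(tvec^2))

  run_dir <- function(dir0) {
    u_cur <- u
    tcur <- dir0 * tvec
    h <- step_control$h0
    z <- unpack(u_cur)
    bb <- bcoef_at(z)
    out <- list(list(u = u_cur, b = bb$b))
    w_prev <- bb$w
    status <- "range-exit"
    steps <- 0L
    while (steps < step_control$max_steps) {
      co <- correct(u_cur + h * tcur, tcur, u_cur, h)
      if (!co$ok) {
        h <- h / 2
        if (h < step_control$hmin) { status <- "step-underflow"; break }
        next
      }
      tnew <- co$u - u_cur
      tnew <- tnew / sqrt(sum(tnew^2))
      u_cur <- co$u
      tcur <- tnew
      z <- unpack(u_cur)
      ## renormalize v and the c vector to keep c'v = 1 well conditioned
      nv <- sqrt(sum(z$v^2))
      z$v <- z$v / nv
      cvec <<- z$v
      u_cur <- pack(z$x, z$v, z$pa, z$pb)
      bb <- bcoef_at(z, w_prev)
      w_prev <- bb$w
      out[[length(out) + 1L]] <- list(u = u_cur, b = bb$b)
      steps <- steps + 1L
      if (co$iters <= 4) h <- min(step_control$hmax, h * 1.4)
      if (bb$sigma2 < 1e-6) { status <- "fold-character-lost"; break }
      if (z$pa < range$a[1] || z$pa > range$a[2] ||
          z$pb < range$b[1] || z$pb > range$b[2]) break
      if (any(z$x < -1e-6 * max(1, max(abs(z$x))))) { status <- "negative-state"; break }
    }
    list(points = out, status = status)
  }

  cvec0 <- cvec
  d1 <- run_dir(+1)
  cvec <- cvec0
  d2 <- run_dir(-1)
  pts <- c(rev(d2$points), d1$points[-1])

  param_mat <- t(vapply(pts, function(q) {
    z <- unpack(q$u); c(z$pa, z$pb)
  }, numeric(2)))
  colnames(param_mat) <- params
  states <- t(vapply(pts, function(q) unpack(q$u)$x, numeric(n)))
  bcoef <- vapply(pts, `[[`, 0, "b")

  ## cusps: sign changes of b, refined by bisection along the curve; the
  ## refinement must drive |b| several orders below the bracket values
  ## (rejects sign flips across discontinuous jumps of the traversal)
  cusps <- list()
  for (i in seq_len(length(pts) - 1L)) {
    if (is.finite(bcoef[i]) && is.finite(bcoef[i + 1L]) &&
        bcoef[i] * bcoef[i + 1L] < 0) {
      cp <- refine_cusp(pts[[i]]$u, pts[[i + 1L]]$u, unpack, pack, resid,
                        jac_aug, bcoef_at, tol)
      if (!is.null(cp)) cusps[[length(cusps) + 1L]] <- cp
    }
  }
  if (length(cusps) > 1L) {
    key <- vapply(cusps, function(cp)
      paste(signif(cp$param_a, 3), signif(cp$param_b, 3)), "")
    cusps <- cusps[!duplicated(key)]
  }
  structure(list(params = param_mat, states = states, bcoef = bcoef,
                 cusps = cusps, status = c(d2$status, d1$status),
                 param_names = params),
            class = "fold_curve")
}

refine_cusp <- function(u1, u2, unpack, pack, resid, jac_aug, bcoef_at,
                        tol) {
  tvec <- (u2 - u1); tvec <- tvec / sqrt(sum(tvec^2))
  corr <- function(u_pred, uref) {
    u <- u_pred
    for (it in 1:30) {
      z <- unpack(u)
      r <- c(resid(z), sum(tvec * (u - uref)))
      if (max(abs(r)) < tol * max(1, max(abs(z$x)))) return(u)
      A <- rbind(jac_aug(z), tvec)
      du <- tryCatch(solve(A, -r), error = function(e) NULL)
      if (is.null(du) || !all(is.finite(du))) return(NULL)
      u <- u + du
    }
    NULL
  }
  b_at <- function(u) bcoef_at(unpack(u))$b
  b1 <- b_at(u1); b2 <- b_at(u2)
  bscale <- max(abs(b1), abs(b2))
  lo <- u1; hi <- u2
  ## bisect until the bracketing b values themselves collapse: along a
  ## genuine cusp b is continuous through 0, whereas a discontinuous jump
  ## of the traversal leaves a persistent gap (spurious crossing, rejected)
  converged <- FALSE
  for (iter in 1:60) {
    if (abs(b1 - b2) <= 1e-3 * bscale) { converged <- TRUE; break }
    mid <- corr((lo + hi) / 2, (lo + hi) / 2)
    if (is.null(mid)) break
    bm <- b_at(mid)
    if (!is.finite(bm)) break
    if (sign(bm) == sign(b1)) { lo <- mid; b1 <- bm } else { hi <- mid; b2 <- bm }
  }
  if (!converged) return(NULL)
  z <- unpack((lo + hi) / 2)
  list(param_a = unname(z$pa), param_b = unname(z$pb), state = unname(z$x))
}

#' @export
print.fold_curve <- function(x, ...) {
  cat("Fold curve in (", paste(x$param_names, collapse = ", "), "): ",
      nrow(x$params), " points, ", length(x$cusps), " cusp(s); status: ",
      paste(x$status, collapse = " / "), "\n", sep = "")
  for (cp in x$cusps)
    cat(sprintf("  cusp at (%s, %s) = (%.6g, %.6g)\n", x$param_names[1],
                x$param_names[2], cp$param_a, cp$param_b))
  invisible(x)
}
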