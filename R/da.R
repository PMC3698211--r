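## Box-in-domain-of-attraction certification for quadratic systems.
##
## A shifted box S (origin = equilibrium, strictly interior) is certified to
## lie in the domain of attraction when there exist gamma in (0,1) and a
## symmetric positive-definite matrix M such that
##   (a)  M  >=  gamma^2 a_k a_k'          for all 2n face normals a_k,
##   (b)  v' M v <= 1                      at every vertex v of S,
##   (c)  gamma (A'M + MA) + M D(v) + D(v)' M  < 0   at every vertex,
## where D(z) has rows z'F_i. Condition (a) is the Schur complement of the
## published (n+1)-block form; (b) puts S inside the unit-level ellipsoid of
## M; (c) makes the Lyapunov derivative negative on the blown-up box S/gamma
## which contains the ellipsoid, so the ellipsoid is invariant and
## attracting. The scalar c of the underlying theorem is absorbed into
## M = P/c, which makes all three conditions jointly linear in M at fixed
## gamma.

#' Certify that a shifted box lies in a domain of attraction
#'
#' Solves, for each `gamma` in `gamma_grid` (largest first), the LMI
#' feasibility system described above; the first feasible `gamma` wins. The
#' box is certified only if an independently recomputed eigenvalue check of
#' all three condition families passes at every one of the `2^n` vertices.
#'
#' @param quad a [quadratic_decomposition()] of the network about the target
#'   equilibrium (its `A` must be Hurwitz).
#' @param box a shifted-frame [axis_box()].
#' @param gamma_grid values in (0,1); default 24 uniform points in
#'   (0.02, 0.98), tried in descending order.
#' @param margin required strict margin on condition (c).
#' @param max_vertex_rounds constraint-generation rounds (vertex subsets are
#'   grown until the full vertex set verifies).
#' @param verbose print per-gamma progress.
#' @return an object of class `"da_certificate"` (fields `gamma`, `M`,
#'   `box`, `margins`, `status = "certified"`), or a list with
#'   `status = "not-certified"` and the per-gamma solver report.
#' @export
certify_box <- function(quad, box, gamma_grid = default_gamma_grid(),
                        margin = 1e-7, max_vertex_rounds = 12L,
                        verbose = FALSE) {
  stopifnot(inherits(quad, "quadratic_system"), inherits(box, "axis_box"),
            box$frame == "shifted")
  n <- nrow(quad$A)
  ev <- eigen(quad$A, only.values = TRUE)$values
  if (any(Re(ev) >= 0))
    stop("A is not Hurwitz; the equilibrium must be asymptotically stable")

  ## diagonal rescaling for conditioning: coordinates divided by the
  ## equilibrium magnitude (floored at 1)
  s <- pmax(1, abs(quad$origin_state))
  As <- diag(1 / s) %*% quad$A %*% diag(s)
  Fs <- lapply(seq_len(n), function(i)
    diag(s) %*% quad$F[[i]] %*% diag(s) / s[i])
  quad_s <- structure(list(A = As, F = Fs, origin_state = quad$origin_state,
                           species = quad$species),
                      class = "quadratic_system")
  box_s <- axis_box(box$lower / s, box$upper / s, "shifted",
                    species = box$species)

  verts <- box_vertices(box_s)
  nvert <- ncol(verts)
  Amat <- face_normals(box_s)
  report <- list()
  for (gamma in gamma_grid) {
    fit <- certify_box_gamma(quad_s, box_s, verts, Amat, gamma,
                             margin = margin,
                             max_vertex_rounds = max_vertex_rounds)
    report[[sprintf("gamma=%.4f", gamma)]] <- fit$status
    if (verbose)
      message(sprintf("  gamma = %.4f: %s (t = %.3g)", gamma, fit$status,
                      fit$t))
    if (fit$status == "certified") {
      ## map certificate back to the unscaled shifted frame and re-verify
      M <- diag(1 / s) %*% fit$M %*% diag(1 / s)
      chk <- check_certificate(quad, box, gamma, M, margin = 0)
      if (chk$valid) {
        return(structure(list(gamma = gamma, M = M, box = box,
                              origin_state = quad$origin_state,
                              margins = chk$margins, status = "certified",
                              solver = list(t = fit$t,
                                            iterations = fit$iterations)),
                         class = "da_certificate"))
      }
      report[[sprintf("gamma=%.4f", gamma)]] <- "failed-reverification"
    }
  }
  list(status = "not-certified", report = report,
       n_vertices = nvert, gamma_grid = gamma_grid)
}

#' Default gamma grid for [certify_box()]
#'
#' 24 uniformly spaced values in (0.02, 0.98), descending.
#' @return numeric vector.
#' @export
default_gamma_grid <- function() rev(seq(0.02, 0.98, length.out = 24))

## single-gamma LMI solve with vertex constraint generation
certify_box_gamma <- function(quad, box, verts, Amat, gamma, margin,
                              max_vertex_rounds) {
  n <- nrow(quad$A)
  nvert <- ncol(verts)
  idx <- vech_index(n)
  nv <- nrow(idx)

  ## scalar (7b) rows as linear constraints in vech(M): v'Mv <= 1
  quad_row <- function(v) {
    w <- ifelse(idx[, 1] == idx[, 2], 1, 2)
    w * v[idx[, 1]] * v[idx[, 2]]
  }

  ## initial vertex working set
  active <- if (nvert <= 64) seq_len(nvert) else
    unique(c(1L, nvert, with_seed(20240509L, sample(nvert, 48L))))

  ## Lyapunov start: A'P + PA = -I, normalized under (7b)
  P <- lyapunov_solve(quad$A)
  qmax <- max(apply(verts, 2, function(v) sum(v * (P %*% v))))
  P <- P / (2 * qmax)
  m0 <- mat_to_vech(P, idx)

  face_blocks <- lapply(seq_len(ncol(Amat)), function(k)
    list(type = "var", Q = gamma^2 * tcrossprod(Amat[, k])))

  fit <- NULL
  for (round in seq_len(max_vertex_rounds)) {
    lyap_blocks <- lapply(active, function(j) {
      C <- gamma * quad$A + quad_D(quad, verts[, j])
      list(type = "lyap", C = C, Q = margin * diag(n))
    })
    lin <- list(Amat = t(matrix(vapply(active, function(j)
                  quad_row(verts[, j]), numeric(nv)), nrow = nv)),
                b = rep(1, length(active)))
    fit <- lmi_phase1(c(face_blocks, lyap_blocks), n, m0, lin = lin,
                      t_stop = -1e-9)
    if (!fit$feasible)
      return(list(status = "infeasible-or-unconverged", t = fit$t,
                  iterations = fit$iterations, M = NULL))
    m0 <- fit$m
    ## full-vertex screening of (7b) and (7c)
    M <- fit$M
    qb <- apply(verts, 2, function(v) sum(v * (M %*% v)))
    sym_part <- gamma * (t(quad$A) %*% M + M %*% quad$A)
    lam <- vapply(seq_len(nvert), function(j) {
      D <- quad_D(quad, verts[, j])
      max(eigen(sym_part + M %*% D + t(D) %*% M, symmetric = TRUE,
                only.values = TRUE)$values)
    }, 0)
    viol <- unique(c(which(qb > 1 + 1e-12), which(lam > -margin / 2)))
    viol <- setdiff(viol, active)
    if (!length(viol))
      return(list(status = "certified", t = fit$t, M = M,
                  iterations = fit$iterations))
    ord <- viol[order(-(pmax(qb[viol] - 1, 0) + pmax(lam[viol], 0)))]
    active <- c(active, utils::head(ord, 24L))
  }
  list(status = "vertex-generation-exhausted", t = fit$t, M = NULL,
       iterations = fit$iterations)
}

## dense Lyapunov solve A'P + PA = -I via the Kronecker system
lyapunov_solve <- function(A) {
  n <- nrow(A)
  K <- kronecker(diag(n), t(A)) + kronecker(t(A), diag(n))
  P <- matrix(solve(K, as.numeric(-diag(n))), n, n)
  (P + t(P)) / 2
}

#' Independently re-verify a certificate
#'
#' Plugs `(gamma, M)` back into the three condition families using plain
#' eigenvalue computations at the full vertex set; no solver output is
#' trusted.
#'
#' @param quad the [quadratic_decomposition()].
#' @param box the certified shifted box.
#' @param gamma,M the certificate.
#' @param margin required margin on condition (c).
#' @return list with `valid` and the worst `margins` per family:
#'   `face` (min eigenvalue of `M - gamma^2 a a'`), `vertex`
#'   (`1 - max v'Mv`), `lyapunov` (`-max` eigenvalue of the (c) matrices),
#'   `M_pd` (min eigenvalue of M).
#' @export
check_certificate <- function(quad, box, gamma, M, margin = 0) {
  verts <- box_vertices(box)
  Amat <- face_normals(box)
  face <- min(vapply(seq_len(ncol(Amat)), function(k)
    min(eigen(M - gamma^2 * tcrossprod(Amat[, k]), symmetric = TRUE,
              only.values = TRUE)$values), 0))
  vertex <- 1 - max(apply(verts, 2, function(v) sum(v * (M %*% v))))
  sym_part <- gamma * (t(quad$A) %*% M + M %*% quad$A)
  lyap <- -max(vapply(seq_len(ncol(verts)), function(j) {
    D <- quad_D(quad, verts[, j])
    max(eigen(sym_part + M %*% D + t(D) %*% M, symmetric = TRUE,
              only.values = TRUE)$values)
  }, 0))
  mpd <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  margins <- list(face = face, vertex = vertex, lyapunov = lyap, M_pd = mpd)
  list(valid = face >= -1e-12 && vertex >= -1e-12 && lyap > margin &&
         mpd > 0, margins = margins)
}

#' @export
print.da_certificate <- function(x, ...) {
  cat("DA certificate: gamma =", format(x$gamma), "\n")
  cat("  margins: face", format(x$margins$face, digits = 3),
      "| vertex", format(x$margins$vertex, digits = 3),
      "| lyapunov", format(x$margins$lyapunov, digits = 3), "\n")
  invisible(x)
}

#' Grow a certified box by iterative face stretching
#'
#' Starting from a certifiable seed box, faces are visited round-robin
#' (upper faces first, then lower) and stretched multiplicatively by
#' `growth`; a face is frozen after its first rejected stretch, and growth
#' stops when every face is frozen (or `max_steps` accepted stretches).
#' Lower faces may optionally be floored so the absolute-frame box stays
#' nonnegative.
#'
#' @param quad the [quadratic_decomposition()].
#' @param seed_box certifiable shifted-frame [axis_box()].
#' @param growth multiplicative stretch per accepted step.
#' @param gamma_grid passed to [certify_box()].
#' @param nonneg_floor floor absolute coordinates at zero (uses
#'   `quad$origin_state`).
#' @param max_steps cap on accepted stretches.
#' @param verbose print progress.
#' @return list with `box` (largest certified) and `certificate`.
#' @export
grow_box <- function(quad, seed_box, growth = 1.1,
                     gamma_grid = default_gamma_grid(),
                     nonneg_floor = TRUE, max_steps = 200L,
                     verbose = FALSE) {
  cert <- certify_box(quad, seed_box, gamma_grid)
  if (!inherits(cert, "da_certificate"))
    stop("seed box is not certifiable")
  box <- seed_box
  n <- length(box$lower)
  frozen <- rep(FALSE, 2L * n)      # 1..n upper faces, n+1..2n lower faces
  floor_lower <- if (nonneg_floor)
    ifelse(quad$origin_state > 0, -quad$origin_state, -Inf) else rep(-Inf, n)
  accepted <- 0L
  ## put the last successful gamma first to warm-start the grid
  grid_for <- function(g) c(g, setdiff(gamma_grid, g))
  while (!all(frozen) && accepted < max_steps) {
    progressed <- FALSE
    for (f in seq_len(2L * n)) {
      if (frozen[f] || accepted >= max_steps) next
      trial <- box
      if (f <= n) trial$upper[f] <- box$upper[f] * growth
      else {
        i <- f - n
        newlow <- box$lower[i] * growth
        at_floor <- newlow <= floor_lower[i]
        if (at_floor) newlow <- floor_lower[i] * (1 - 1e-9)
        trial$lower[i] <- newlow
        if (at_floor) frozen[f] <- TRUE
      }
      fit <- certify_box(quad, trial, grid_for(cert$gamma))
      if (inherits(fit, "da_certificate")) {
        box <- trial; cert <- fit
        accepted <- accepted + 1L
        progressed <- TRUE
        if (verbose)
          message(sprintf("  face %d stretched (step %d), gamma = %.3f",
                          f, accepted, fit$gamma))
      } else frozen[f] <- TRUE
    }
    if (!progressed) break
  }
  list(box = box, certificate = cert, accepted_steps = accepted,
       frozen = frozen)
}

#' Verify a box by direct simulation
#'
#' Samples the box (all vertices plus seeded Latin-hypercube interior
#' points), integrates each initial condition and reports the fraction of
#' trajectories ending within `tol` (relative, componentwise with floor 1)
#' of the equilibrium. Certificate soundness demands a fraction of 1.
#'
#' @inheritParams rate_vector
#' @param box absolute-frame [axis_box()].
#' @param equilibrium target state vector or `"equilibrium"` object.
#' @param n_interior interior sample count.
#' @param seed sampler seed.
#' @param horizon integration horizon (hours).
#' @param tol convergence tolerance.
#' @param rtol,atol solver tolerances.
#' @param include_vertices include all `2^n` corners in the sample?
#' @return list with `fraction`, `n_samples`, `failures` (indices).
#' @export
verify_box_by_simulation <- function(network, p, box, equilibrium,
                                     n_interior = 50, seed = 1L,
                                     horizon = 200, tol = 0.01,
                                     rtol = 1e-6, atol = 1e-8,
                                     include_vertices = TRUE) {
  stopifnot(inherits(box, "axis_box"), box$frame == "absolute")
  xe <- if (inherits(equilibrium, "equilibrium")) equilibrium$state
        else as.numeric(equilibrium)
  pts <- sample_box(box, n_interior = n_interior, seed = seed,
                    include_vertices = include_vertices)
  pts[pts < 0] <- 0
  ok <- logical(ncol(pts))
  for (j in seq_len(ncol(pts))) {
    tr <- simulate_network(network, p, pts[, j], horizon, rtol = rtol,
                           atol = atol, keep = "last")
    xT <- tr$state[nrow(tr$state), ]
    ok[j] <- tr$success && max(abs(xT - xe) / pmax(1, abs(xe))) <= tol
  }
  list(fraction = mean(ok), n_samples = ncol(pts), failures = which(!ok))
}
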