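## Small LMI feasibility solver.
##
## The certification conditions are linear matrix inequalities in a single
## symmetric matrix variable M (at fixed gamma). No semidefinite-programming
## library is available in this environment, so feasibility is solved
## directly by a standard Phase-I barrier method: minimize t subject to
## B_k(m) + t I >= 0 over the vech coordinates m of M, via damped Newton on
## t - mu * sum_k log det(B_k(m) + t I) with a decreasing barrier weight.
## A strictly negative optimal t certifies strict feasibility; every
## returned certificate is re-verified afterwards with plain eigenvalue
## computations, so the solver itself is not part of the trusted base.
##
## Block types (variable M is n x n symmetric, m = vech(M)):
##   "var"  : B(M) = M - Q                   (derivative in direction E_i is E_i)
##   "lyap" : B(M) = -(C' M + M C) - Q       (derivative -(C' E_i + E_i C))
## plus dense scalar constraints  c' m <= d  handled as log barriers.

## symmetric vech basis bookkeeping for an n x n matrix variable
vech_index <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

vech_to_mat <- function(m, n, idx = vech_index(n)) {
  M <- matrix(0, n, n)
  M[idx] <- m
  M[idx[, c(2, 1)]] <- m
  M
}

mat_to_vech <- function(M, idx = vech_index(nrow(M))) M[idx]

## basis matrices E_i (symmetrized unit elements)
vech_basis <- function(n, idx = vech_index(n)) {
  lapply(seq_len(nrow(idx)), function(k) {
    E <- matrix(0, n, n)
    a <- idx[k, 1]; b <- idx[k, 2]
    E[a, b] <- E[a, b] + 1
    E[b, a] <- E[b, a] + 1
    if (a == b) E[a, b] <- 1
    E
  })
}

block_value <- function(block, M) {
  switch(block$type,
         var  = M - block$Q,
         lyap = -(t(block$C) %*% M + M %*% block$C) - block$Q,
         stop("unknown block type"))
}

## derivative matrices of a block along every basis direction (list over i)
block_derivs <- function(block, basis) {
  switch(block$type,
         var  = basis,
         lyap = lapply(basis, function(E)
           -(t(block$C) %*% E + E %*% block$C)),
         stop("unknown block type"))
}

## Phase-I barrier solve.
## blocks: list of PSD blocks; lin: optional list(Amat, b) meaning
## Amat %*% m <= b. m0: start. Returns list(m, t, converged, iterations).
lmi_phase1 <- function(blocks, n, m0, lin = NULL, t_stop = -1e-7,
                       mu0 = 1, mu_min = 1e-9, max_newton = 400L) {
  idx <- vech_index(n)
  basis <- vech_basis(n, idx)
  nv <- nrow(idx)
  nb <- length(blocks)
  dims <- vapply(blocks, function(b) nrow(b$Q), 0L)
  ## per block: rows = vec of the derivative matrices along each basis
  ## direction, with the Phase-I t direction (identity) appended last
  Dmat <- lapply(seq_len(nb), function(k) {
    dm <- block_derivs(blocks[[k]], basis)
    rbind(t(vapply(dm, as.numeric, numeric(dims[k]^2))),
          as.numeric(diag(dims[k])))
  })
  tperm <- lapply(seq_len(nb), function(k)
    as.numeric(t(matrix(seq_len(dims[k]^2), dims[k], dims[k]))))
  diagidx <- lapply(seq_len(nb), function(k)
    seq(1L, dims[k]^2, by = dims[k] + 1L))

  eval_blocks <- function(m) {
    M <- vech_to_mat(m, n, idx)
    lapply(blocks, block_value, M = M)
  }
  min_eigs <- function(Bs, tt) {
    vapply(Bs, function(B) {
      ev <- eigen(B + tt * diag(nrow(B)), symmetric = TRUE,
                  only.values = TRUE)$values
      min(ev)
    }, 0)
  }
  lin_slack <- function(m, tt) {
    if (is.null(lin)) return(numeric())
    as.numeric(lin$b - lin$Amat %*% m) + tt
  }

  m <- m0
  Bs <- eval_blocks(m)
  t_cur <- max(0, -min(min_eigs(Bs, 0),
                       if (is.null(lin)) Inf else lin_slack(m, 0))) * 1.5 + 1e-3
  mu <- mu0 * max(1, abs(t_cur))
  total_it <- 0L

  repeat {
    for (newton_it in seq_len(40L)) {
      total_it <- total_it + 1L
      if (total_it > max_newton) break
      ## gradient and Hessian of t - mu * sum log det(B_k + tI) (+ lin barrier)
      g <- numeric(nv + 1L)
      H <- matrix(0, nv + 1L, nv + 1L)
      g[nv + 1L] <- 1
      ok <- TRUE
      for (k in seq_len(nb)) {
        Bk <- Bs[[k]] + t_cur * diag(dims[k])
        ch <- tryCatch(chol(Bk), error = function(e) NULL)
        if (is.null(ch)) { ok <- FALSE; break }
        S <- chol2inv(ch)
        ## rows of R1 are vec(S %*% dB_i); vec(S E) = (I (x) S) vec(E)
        R1 <- Dmat[[k]] %*% kronecker(diag(dims[k]), S)
        g <- g - mu * rowSums(R1[, diagidx[[k]], drop = FALSE])
        H <- H + mu * (R1 %*% t(R1[, tperm[[k]], drop = FALSE]))
      }
      if (!ok) { t_cur <- t_cur * 2 + 1e-3; Bs <- eval_blocks(m); next }
      if (!is.null(lin)) {
        s <- lin_slack(m, t_cur)
        if (any(s <= 0)) { t_cur <- t_cur + 2 * max(0, -min(s)) + 1e-6; next }
        Aext <- cbind(-lin$Amat, 1)       # d/d(m,t) of slack
        g <- g - mu * colSums(Aext / s)
        H <- H + mu * t(Aext) %*% (Aext / s^2)
      }
      step <- tryCatch(solve(H + 1e-12 * max(diag(H)) * diag(nv + 1L), -g),
                       error = function(e) NULL)
      if (is.null(step)) break
      lambda2 <- -sum(step * g)
      ## backtracking line search preserving strict feasibility
      alpha <- 1
      accepted <- FALSE
      for (ls in 1:30) {
        m_try <- m + alpha * step[seq_len(nv)]
        t_try <- t_cur + alpha * step[nv + 1L]
        Bs_try <- eval_blocks(m_try)
        me <- min(min_eigs(Bs_try, t_try),
                  if (is.null(lin)) Inf else min(lin_slack(m_try, t_try)))
        if (is.finite(me) && me > 0) {
          m <- m_try; t_cur <- t_try; Bs <- Bs_try
          accepted <- TRUE
          break
        }
        alpha <- alpha / 2
      }
      if (!accepted) break
      if (t_cur < t_stop) break                        # feasible enough
      if (is.finite(lambda2) && lambda2 < 1e-10 * max(1, abs(t_cur))) break
    }
    if (t_cur < t_stop || mu <= mu_min * max(1, abs(t_cur)) ||
        total_it > max_newton) break
    mu <- mu / 8
  }
  list(m = m, M = vech_to_mat(m, n, idx), t = t_cur,
       feasible = t_cur < t_stop, iterations = total_it)
}
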