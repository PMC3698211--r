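## Exact linear + quadratic decomposition of a mass-action RHS about an
## equilibrium. Because every mass-action rate has molecularity at most two,
## the shifted system z = x - xe satisfies, exactly,
##   zdot_i = (A z)_i + z' F_i z,
## with A the state Jacobian at xe and F_i constant symmetric matrices (half
## the constant Hessian of component i).

#' Quadratic-system form of a network about an equilibrium
#'
#' @inheritParams rate_vector
#' @param equilibrium an `"equilibrium"` object (from [find_equilibria()] or
#'   [newton_equilibrium()] plus classification), or a bare state vector with
#'   residual below `residual_tol`.
#' @param residual_tol largest admissible equilibrium residual; above it the
#'   shifted system would retain a constant term.
#' @return object of class `"quadratic_system"`: list with `A` (n x n),
#'   `F` (list of n symmetric n x n matrices), `origin_state`, `species`.
#' @examples
#' toy <- toy_models()$toy1d
#' qs <- quadratic_decomposition(toy$network, toy$parameters, 0)
#' qs$A        # -1
#' qs$F[[1]]   # 1
#' @export
quadratic_decomposition <- function(network, p = nominal_parameters(network),
                                    equilibrium, residual_tol = 1e-6) {
  xe <- if (inherits(equilibrium, "equilibrium")) equilibrium$state
        else as.numeric(equilibrium)
  res <- max(abs(rhs(network, xe, p)))
  if (res > residual_tol * max(1, max(abs(xe))))
    stop("state is not an equilibrium (residual ", format(res),
         "); the shifted system would retain a constant term")
  A <- jacobian_x(network, xe, p)
  H <- hessian_tensor(network, p)
  F <- lapply(H, function(h) (h + t(h)) / 4)   # F_i = H_i / 2, symmetrized
  structure(list(A = A, F = F, origin_state = xe,
                 species = network$species_names),
            class = "quadratic_system")
}

#' Evaluate a quadratic system at a shifted state
#'
#' @param quad a [quadratic_decomposition()].
#' @param z state in the shifted frame (`z = x - origin_state`).
#' @return derivative vector `A z + (z' F_i z)_i`.
#' @export
quadratic_rhs <- function(quad, z) {
  as.numeric(quad$A %*% z) +
    vapply(quad$F, function(Fi) sum(z * (Fi %*% z)), 0)
}

## D(z): matrix whose i-th row is z' F_i; the quadratic part is D(z) z and
## the Jacobian of the quadratic part is 2 D(z).
quad_D <- function(quad, z) {
  t(vapply(quad$F, function(Fi) as.numeric(Fi %*% z), numeric(length(z))))
}
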