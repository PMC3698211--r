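#' Elementary mass-action reaction
#'
#' Builds a single elementary reaction with mass-action kinetics. The rate of
#' the reaction is `k * prod(concentrations of reactants)`, so the molecularity
#' (total number of reactant molecules, including constant inputs) must be at
#' most two for the network right-hand side to be (at most) quadratic in the
#' state.
#'
#' @param reactants character vector of reactant identifiers (possibly empty
#'   for zero-order production; duplicated names encode stoichiometry 2).
#' @param products character vector of product identifiers (possibly empty for
#'   degradation).
#' @param rate_name name of the rate constant, e.g. `"k5"`.
#' @param rate_value strictly positive rate constant. Units are 1/h, 1/(uM h)
#'   or uM/h depending on molecularity.
#' @return an object of class `"reaction"`.
#' @examples
#' reaction(c("G4", "G80"), "G480", "k11", 85.8185)
#' reaction(character(), "G4", "k5", 22.0604)  # zero-order production
#' @export
reaction <- function(reactants, products, rate_name, rate_value) {
  stopifnot(is.character(reactants), is.character(products),
            is.character(rate_name), length(rate_name) == 1L)
  if (!is.numeric(rate_value) || length(rate_value) != 1L ||
      !is.finite(rate_value) || rate_value <= 0) {
    stop("rate constant '", rate_name, "' must be a strictly positive number")
  }
  if (length(reactants) > 2L) {
    stop("reaction '", rate_name, "' has molecularity ", length(reactants),
         " > 2; mass-action right-hand sides must be at most quadratic")
  }
  structure(list(reactants = reactants, products = products,
                 rate_name = rate_name, rate_value = as.numeric(rate_value)),
            class = "reaction")
}

#' Mass-action reaction network
#'
#' Assembles a validated reaction network: an ordered species list, a list of
#' elementary [reaction()]s and a named vector of constant inputs (boundary
#' species held at fixed concentration, e.g. external galactose). The network
#' dynamics are `xdot = N v(x, p)` where `N` is the stoichiometric matrix and
#' `v` the vector of mass-action rates; each reaction carries its own rate
#' constant, so the parameter vector `p` has one entry per reaction, ordered
#' as the reactions.
#'
#' @param species character vector of state species identifiers (the state
#'   ordering used by all matrices and boxes).
#' @param reactions list of [reaction()] objects.
#' @param constant_inputs named numeric vector of boundary-species
#'   concentrations (uM); may be empty.
#' @return an object of class `"reaction_network"` with precomputed
#'   stoichiometric matrix and rate-evaluation tables.
#' @seealso [rhs()], [jacobian_x()], [find_equilibria()], [gal_model()]
#' @export
reaction_network <- function(species, reactions, constant_inputs = numeric()) {
  stopifnot(is.character(species), length(species) >= 1L,
            !anyDuplicated(species), is.list(reactions))
  if (length(constant_inputs)) {
    stopifnot(is.numeric(constant_inputs), !is.null(names(constant_inputs)))
    if (any(names(constant_inputs) %in% species))
      stop("constant inputs must not shadow state species")
  }
  n <- length(species)
  m <- length(reactions)
  known <- c(species, names(constant_inputs))
  N <- matrix(0, n, m, dimnames = list(species, vapply(reactions, `[[`,
                                                       "", "rate_name")))
  i1 <- integer(m); i2 <- integer(m)       # state reactant slots (n+1 = none)
  cfac <- numeric(m)                        # constant-input factor of the rate
  rate_values <- numeric(m)
  for (r in seq_len(m)) {
    rx <- reactions[[r]]
    if (!inherits(rx, "reaction")) stop("reactions[[", r, "]] is not a reaction")
    bad <- setdiff(c(rx$reactants, rx$products), known)
    if (length(bad))
      stop("reaction '", rx$rate_name, "' references unknown species: ",
           paste(bad, collapse = ", "))
    st <- match(rx$reactants, species)       # NA for constant inputs
    st_idx <- st[!is.na(st)]
    i1[r] <- if (length(st_idx) >= 1L) st_idx[1L] else n + 1L
    i2[r] <- if (length(st_idx) >= 2L) st_idx[2L] else n + 1L
    const_r <- rx$reactants[is.na(st)]
    cfac[r] <- prod(constant_inputs[const_r])
    for (s in st_idx) N[s, r] <- N[s, r] - 1
    pt <- match(rx$products, species)
    for (s in pt[!is.na(pt)]) N[s, r] <- N[s, r] + 1
    rate_values[r] <- rx$rate_value
  }
  names(rate_values) <- colnames(N)
  if (anyDuplicated(names(rate_values)))
    stop("rate constant names must be unique (one parameter per reaction)")
  structure(list(species_names = species, reactions = reactions,
                 constant_inputs = constant_inputs,
                 n_species = n, n_reactions = m,
                 N = N, i1 = i1, i2 = i2, cfac = cfac,
                 rate_values = rate_values),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Mass-action reaction network:", x$n_species, "species,",
      x$n_reactions, "reactions\n")
  cat("  species:", paste(x$species_names, collapse = ", "), "\n")
  if (length(x$constant_inputs))
    cat("  constant inputs:",
        paste(names(x$constant_inputs), "=", x$constant_inputs,
              collapse = ", "), "\n")
  invisible(x)
}

#' Stoichiometric matrix
#'
#' @param network a [reaction_network()].
#' @return the `n_species x n_reactions` stoichiometric matrix `N`.
#' @export
stoichiometry <- function(network) network$N

#' Nominal parameter vector of a network
#'
#' The rate constants declared with the reactions, in reaction order. This is
#' the `p` accepted by [rhs()] and friends.
#'
#' @param network a [reaction_network()].
#' @return named numeric vector of length `n_reactions`.
#' @export
nominal_parameters <- function(network) network$rate_values

## monomial part of each rate (everything except the rate constant)
rate_monomials <- function(network, x) {
  xx <- c(x, 1)
  network$cfac * xx[network$i1] * xx[network$i2]
}

#' Mass-action rate vector
#'
#' @param network a [reaction_network()].
#' @param x state vector (uM), ordered as `network$species_names`.
#' @param p parameter vector (defaults to the nominal rate constants).
#' @return numeric vector of reaction rates `v(x, p)`.
#' @export
rate_vector <- function(network, x, p = nominal_parameters(network)) {
  check_xp(network, x, p)
  stats::setNames(as.numeric(p) * rate_monomials(network, x),
                  names(network$rate_values))
}

check_xp <- function(network, x, p) {
  if (length(x) != network$n_species)
    stop("state vector has length ", length(x), ", expected ",
         network$n_species)
  if (length(p) != network$n_reactions)
    stop("parameter vector has length ", length(p), ", expected ",
         network$n_reactions)
  invisible(TRUE)
}

#' Network right-hand side
#'
#' Evaluates the vector field `N v(x, p)` of the mass-action ODE system.
#'
#' @inheritParams rate_vector
#' @return numeric vector `xdot` of length `n_species`.
#' @export
rhs <- function(network, x, p = nominal_parameters(network)) {
  check_xp(network, x, p)
  as.numeric(network$N %*% (as.numeric(p) * rate_monomials(network, x)))
}

#' State Jacobian of the right-hand side
#'
#' Exact analytic derivative of `N v(x, p)` with respect to the state.
#'
#' @inheritParams rate_vector
#' @return `n_species x n_species` matrix.
#' @export
jacobian_x <- function(network, x, p = nominal_parameters(network)) {
  check_xp(network, x, p)
  n <- network$n_species
  xx <- c(x, 1)
  kc <- as.numeric(p) * network$cfac
  ## dv_r/dx_j is nonzero only for the (at most two) state reactants
  dV <- matrix(0, network$n_reactions, n)
  has1 <- network$i1 <= n
  has2 <- network$i2 <= n
  idx1 <- which(has1)
  if (length(idx1))
    dV[cbind(idx1, network$i1[idx1])] <-
      dV[cbind(idx1, network$i1[idx1])] + kc[idx1] * xx[network$i2[idx1]]
  idx2 <- which(has2)
  if (length(idx2))
    dV[cbind(idx2, network$i2[idx2])] <-
      dV[cbind(idx2, network$i2[idx2])] + kc[idx2] * xx[network$i1[idx2]]
  network$N %*% dV
}

#' Parameter Jacobian of the right-hand side
#'
#' Since each mass-action rate is linear in its own rate constant,
#' `d(Nv)/dp = N diag(m(x))` where `m` are the rate monomials.
#'
#' @inheritParams rate_vector
#' @return `n_species x n_reactions` matrix.
#' @export
jacobian_p <- function(network, x, p = nominal_parameters(network)) {
  check_xp(network, x, p)
  sweep(network$N, 2L, rate_monomials(network, x), `*`)
}

## Constant second-derivative tensor of the RHS: list of n symmetric matrices
## H_i with (H_i)_{ab} = d^2 f_i / dx_a dx_b. Mass-action RHS is quadratic, so
## this does not depend on x.
hessian_tensor <- function(network, p = nominal_parameters(network)) {
  n <- network$n_species
  H <- lapply(seq_len(n), function(i) matrix(0, n, n))
  kc <- as.numeric(p) * network$cfac
  for (r in seq_len(network$n_reactions)) {
    a <- network$i1[r]; b <- network$i2[r]
    if (a > n || b > n) next                 # not bimolecular in the state
    for (i in seq_len(n)) {
      s <- network$N[i, r] * kc[r]
      if (s == 0) next
      H[[i]][a, b] <- H[[i]][a, b] + s
      H[[i]][b, a] <- H[[i]][b, a] + s
    }
  }
  H
}

## Gradients of the rate monomials m_r(x) (one row per reaction): used for
## parameter-direction derivatives of the Jacobian, d J/dp_r = N_r grad(m_r)'.
monomial_gradients <- function(network, x) {
  n <- network$n_species
  xx <- c(x, 1)
  G <- matrix(0, network$n_reactions, n)
  for (r in seq_len(network$n_reactions)) {
    a <- network$i1[r]; b <- network$i2[r]
    if (a <= n) G[r, a] <- G[r, a] + network$cfac[r] * xx[b]
    if (b <= n) G[r, b] <- G[r, b] + network$cfac[r] * xx[a]
  }
  G
}

## Directional Hessian application: matrix with entries (H_i v)_j, i.e. the
## x-derivative of J(x) v along the state (constant for mass-action systems).
hessian_apply <- function(H, v) {
  n <- length(H)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) out[i, ] <- as.numeric(H[[i]] %*% v)
  out
}
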