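## Packaged model fixtures: the GAL switch and small closed-form toys.

the_gal_cache <- new.env(parent = emptyenv())

#' The packaged GAL regulatory network model
#'
#' Loads the nine-species mass-action model of the yeast galactose switch
#' from the packaged model file. The model has 23 elementary reactions
#' (hence 23 rate constants) and one constant input, external galactose at
#' 1000 uM. With the packaged nominal parameters the system is bistable:
#' a low-expression and a high-expression stable steady state coexist,
#' separated by a saddle.
#'
#' The returned object is built afresh from the package file on first use
#' and then served from a cache; mutating a returned copy does not affect
#' later calls.
#'
#' @return a list with components
#'   \item{network}{the [reaction_network()] (9 species, 23 reactions)}
#'   \item{parameters}{named nominal rate-constant vector (length 23)}
#'   \item{gex}{the constant external-galactose concentration, 1000 uM}
#'   \item{reference_states}{2-column matrix of the published low/high
#'     steady states (4-decimal precision), usable as search guesses}
#' @examples
#' gal <- gal_model()
#' max(abs(rhs(gal$network, gal$reference_states[, "low"], gal$parameters)))
#' @export
gal_model <- function() {
  if (is.null(the_gal_cache$model)) {
    path <- system.file("extdata", "gal_network.txt", package = "bistacert",
                        mustWork = TRUE)
    mod <- parse_model(path)
    ref <- cbind(
      low  = c(172.8212, 172.8208, 1.0, 1.0, 1.0, 21.0604, 7.5945, 1.0, 1.0),
      high = c(2711.1839, 2711.2003, 318.5443, 19.9479, 0.3061, 2.1126,
               589.1342, 19.9479, 19.9479))
    rownames(ref) <- mod$network$species_names
    the_gal_cache$model <- list(network = mod$network,
                                parameters = mod$parameters,
                                gex = unname(mod$network$constant_inputs["Gex"]),
                                reference_states = ref)
  }
  the_gal_cache$model
}

#' Catalog of small fixture models with closed-form oracles
#'
#' A set of tiny mass-action networks whose equilibria and domains of
#' attraction are known in closed form, used throughout the test suite as
#' independent oracles:
#'
#' * `toy1d`: one species with `xdot = -x + x^2` (degradation plus
#'   autocatalytic duplication). Equilibria 0 (stable) and 1 (unstable); the
#'   domain of attraction of 0 is exactly `x < 1`.
#' * `birth_death`: `xdot = k - mu * x`, single stable equilibrium `k/mu`.
#' * `toy2d`: two-species competitive Lotka-Volterra network
#'   `xdot = x (1 - x - 2 y)`, `ydot = y (1 - y - 2 x)`; four equilibria:
#'   unstable origin, stable `(1, 0)` and `(0, 1)`, saddle `(1/3, 1/3)` -
#'   a bistable quadratic system with brute-force-computable equilibria.
#' * `linear2d`: a stable purely first-order chain `X -> Y -> 0`; unique
#'   globally attractive equilibrium at the origin.
#'
#' @return named list; each entry has `network`, `parameters`, `description`
#'   and `known_equilibria` (matrix, one column per equilibrium).
#' @export
toy_models <- function() {
  toy1d <- reaction_network("X", list(
    reaction("X", character(), "mu", 1),
    reaction(c("X", "X"), c("X", "X", "X"), "k", 1)))
  birth_death <- reaction_network("X", list(
    reaction(character(), "X", "k", 1.5),
    reaction("X", character(), "mu", 1)))
  toy2d <- reaction_network(c("X", "Y"), list(
    reaction("X", c("X", "X"), "rx", 1),
    reaction(c("X", "X"), "X", "dx", 1),
    reaction(c("X", "Y"), "Y", "bx", 2),
    reaction("Y", c("Y", "Y"), "ry", 1),
    reaction(c("Y", "Y"), "Y", "dy", 1),
    reaction(c("X", "Y"), "X", "by", 2)))
  linear2d <- reaction_network(c("X", "Y"), list(
    reaction("X", "Y", "k1", 1),
    reaction("Y", character(), "k2", 1)))
  list(
    toy1d = list(network = toy1d, parameters = nominal_parameters(toy1d),
                 description = "xdot = -x + x^2; DA of 0 is x < 1",
                 known_equilibria = cbind(stable = 0, unstable = 1)),
    birth_death = list(network = birth_death,
                       parameters = nominal_parameters(birth_death),
                       description = "xdot = k - mu x; equilibrium k/mu",
                       known_equilibria = cbind(stable = 1.5)),
    toy2d = list(network = toy2d, parameters = nominal_parameters(toy2d),
                 description = "competitive LV, bistable",
                 known_equilibria = cbind(origin = c(0, 0),
                                          ex_x = c(1, 0), ex_y = c(0, 1),
                                          coex = c(1 / 3, 1 / 3))),
    linear2d = list(network = linear2d,
                    parameters = nominal_parameters(linear2d),
                    description = "stable linear chain; equilibrium origin",
                    known_equilibria = cbind(origin = c(0, 0))))
}
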