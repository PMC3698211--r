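## Three-phase analysis workflow: nominal analysis (equilibria), state-space
## robustness (domain-of-attraction certificates), and parametric
## robustness (sensitivity ranking, bifurcation mapping, exclusion-based
## two-box certification), with JSON/CSV artifact round-tripping and a
## small command-line front end (inst/cli/bistacert.R).

SCHEMA_VERSION <- "1"

#' Workflow configuration
#'
#' @param model `"gal"` or a path to a model-definition file.
#' @param stages subset of `c("equilibria", "da", "sensitivity",
#'   "bifurcation", "robust")`.
#' @param seed single integer seed; every stochastic element consumes a
#'   fixed substream derived from it.
#' @param out_dir output directory (`NULL` for none).
#' @param da,sensitivity,bifurcation,robust stage parameter lists; see the
#'   defaults in the function body.
#' @return a validated config list of class `"run_config"`.
#' @export
run_config <- function(model = "gal",
                       stages = c("equilibria", "da", "sensitivity",
                                  "bifurcation", "robust"),
                       seed = 1L, out_dir = NULL,
                       da = list(), sensitivity = list(),
                       bifurcation = list(), robust = list()) {
  known <- c("equilibria", "da", "sensitivity", "bifurcation", "robust")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage name(s): ", paste(bad, collapse = ", "))
  defaults <- list(
    da = list(rel_halfwidth = 0.01, grow_steps = 0L,
              gamma_grid = default_gamma_grid(), verify_samples = 20L),
    sensitivity = list(horizon = 20),
    bifurcation = list(param = "k5", range = c(1, 50), fold_curve = FALSE,
                       fold_params = c("k7", "k5"),
                       fold_range = list(a = c(0.5, 200), b = c(0.5, 4000))),
    robust = list(deltas = 2, max_rounds = 10L, slab_fraction = 0.1,
                  rho_grid = c(1, 2, 4, 8),
                  theta = c("k1", "k2", "k5", "k7", "k8", "k9", "mu13",
                            "mu16", "mu17")))
  merge <- function(dflt, user) utils::modifyList(dflt, user)
  structure(list(model = model, stages = stages, seed = as.integer(seed),
                 out_dir = out_dir,
                 da = merge(defaults$da, da),
                 sensitivity = merge(defaults$sensitivity, sensitivity),
                 bifurcation = merge(defaults$bifurcation, bifurcation),
                 robust = merge(defaults$robust, robust)),
            class = "run_config")
}

load_workflow_model <- function(model) {
  if (identical(model, "gal")) return(gal_model())
  mod <- parse_model(model)
  list(network = mod$network, parameters = mod$parameters,
       reference_states = NULL)
}

#' Run the full certification workflow
#'
#' Executes the configured stages in dependency order (equilibria feed
#' every later stage; the robustness stage additionally consumes the DA
#' boxes when available, falling back to the packaged estimates for the
#' GAL model). A failing stage is recorded and its dependents skipped;
#' independent stages still run.
#'
#' @param config a [run_config()].
#' @return a report bundle (list) with one entry per executed stage plus
#'   `summary`; written to `config$out_dir` via [write_report()] when set.
#' @export
run_workflow <- function(config) {
  stopifnot(inherits(config, "run_config"))
  mod <- load_workflow_model(config$model)
  net <- mod$network; p <- mod$parameters
  bundle <- list(schema = SCHEMA_VERSION, config = config)
  errors <- character()

  eqs <- NULL
  if ("equilibria" %in% config$stages) {
    ms <- multistart_spec(n_random = 400, guesses = mod$reference_states,
                          seed = config$seed + 101L)
    eqs <- tryCatch(find_equilibria(net, p, ms), error = function(e) {
      errors <<- c(errors, paste("equilibria:", conditionMessage(e))); NULL
    })
    if (!is.null(eqs))
      bundle$equilibria <- list(
        states = lapply(eqs, `[[`, "state"),
        stable = vapply(eqs, `[[`, TRUE, "stable"),
        residuals = vapply(eqs, `[[`, 0, "residual_norm"))
  }
  stable_eqs <- if (is.null(eqs)) list() else Filter(function(e) e$stable, eqs)

  if ("da" %in% config$stages) {
    if (!length(stable_eqs)) {
      errors <- c(errors, "da: skipped (no stable equilibria)")
    } else {
      bundle$da <- lapply(stable_eqs, function(e) {
        tryCatch({
          qs <- quadratic_decomposition(net, p, e)
          hw <- config$da$rel_halfwidth * pmax(abs(e$state), 0.5)
          box <- axis_box(-hw, hw, "shifted", species = net$species_names)
          cert <- if (config$da$grow_steps > 0) {
            gr <- grow_box(qs, box, gamma_grid = config$da$gamma_grid,
                           max_steps = config$da$grow_steps)
            box <- gr$box
            gr$certificate
          } else certify_box(qs, box, gamma_grid = config$da$gamma_grid)
          if (!inherits(cert, "da_certificate"))
            return(list(certified = FALSE, report = cert$report))
          vb <- verify_box_by_simulation(
            net, p, from_shifted(box, e), e,
            n_interior = config$da$verify_samples,
            seed = config$seed + 202L)
          list(certified = TRUE, gamma = cert$gamma, M = cert$M,
               box_lower = box$lower + e$state,
               box_upper = box$upper + e$state,
               margins = cert$margins, sim_fraction = vb$fraction)
        }, error = function(err) {
          errors <<- c(errors, paste("da:", conditionMessage(err)))
          list(certified = FALSE)
        })
      })
    }
  }

  if ("sensitivity" %in% config$stages) {
    if (!length(stable_eqs)) {
      errors <- c(errors, "sensitivity: skipped (no stable equilibria)")
    } else {
      runs <- tryCatch(
        lapply(stable_eqs, function(e)
          sensitivity_integrate(net, p, e$state,
                                horizon = config$sensitivity$horizon)),
        error = function(e) {
          errors <<- c(errors, paste("sensitivity:", conditionMessage(e)))
          NULL
        })
      if (!is.null(runs))
        bundle$sensitivity <- list(ranking = rank_parameters(runs),
                                   horizon = config$sensitivity$horizon,
                                   nominal = as.list(runs[[1]]$parameters))
    }
  }

  if ("bifurcation" %in% config$stages) {
    if (!length(stable_eqs)) {
      errors <- c(errors, "bifurcation: skipped (no stable equilibria)")
    } else {
      bundle$bifurcation <- tryCatch({
        br <- continue_equilibria(net, p, config$bifurcation$param,
                                  config$bifurcation$range,
                                  x0 = stable_eqs[[1]]$state)
        out <- list(param = config$bifurcation$param,
                    folds = lapply(br$folds, function(f)
                      list(param = f$param, state = f$state)),
                    interval = bistable_interval(br),
                    n_points = length(br$param))
        if (isTRUE(config$bifurcation$fold_curve) && length(br$folds)) {
          f0 <- br$folds[[which.min(vapply(br$folds, `[[`, 0, "param"))]]
          fc <- continue_fold_curve(net, p, config$bifurcation$fold_params,
                                    f0, config$bifurcation$fold_range)
          out$cusps <- lapply(fc$cusps, function(cp)
            list(param_a = cp$param_a, param_b = cp$param_b))
        }
        out
      }, error = function(e) {
        errors <<- c(errors, paste("bifurcation:", conditionMessage(e)))
        NULL
      })
    }
  }

  if ("robust" %in% config$stages) {
    D <- if (identical(config$model, "gal")) printed_da_boxes() else NULL
    if (is.null(D) && !is.null(bundle$da) && length(bundle$da) >= 2 &&
        all(vapply(bundle$da, `[[`, TRUE, "certified"))) {
      D <- list(D1 = axis_box(bundle$da[[1]]$box_lower,
                              bundle$da[[1]]$box_upper),
                D2 = axis_box(bundle$da[[2]]$box_lower,
                              bundle$da[[2]]$box_upper))
    }
    if (is.null(D)) {
      errors <- c(errors, "robust: skipped (no DA boxes available)")
    } else {
      bundle$robust <- lapply(config$robust$deltas, function(dd) {
        tryCatch({
          r <- robust_bistability(net, p, D$D1, D$D2,
                                  theta = config$robust$theta, delta = dd,
                                  rho_grid = config$robust$rho_grid,
                                  slab_fraction = config$robust$slab_fraction,
                                  max_rounds = config$robust$max_rounds,
                                  seed = config$seed + 303L)
          list(delta = dd, status = r$status, disjoint = r$disjoint,
               rho = r$rho, separating = r$separating_coords,
               S1_lower = r$S1$lower, S1_upper = r$S1$upper,
               S2_lower = r$S2$lower, S2_upper = r$S2$upper)
        }, error = function(e) {
          errors <<- c(errors, paste("robust:", conditionMessage(e)))
          list(delta = dd, status = "error")
        })
      })
    }
  }

  bundle$errors <- errors
  bundle$summary <- list(
    n_equilibria = length(eqs),
    n_stable = length(stable_eqs),
    da_certified = if (!is.null(bundle$da))
      sum(vapply(bundle$da, `[[`, TRUE, "certified")) else NA,
    bistable_interval = bundle$bifurcation$interval,
    robust_disjoint = if (!is.null(bundle$robust))
      vapply(bundle$robust, function(r) isTRUE(r$disjoint), TRUE) else NULL)
  if (!is.null(config$out_dir)) write_report(bundle, config$out_dir)
  bundle
}

#' Write a report bundle to disk
#'
#' JSON for structured artifacts (full precision), CSV for the flat
#' tables, plus a short human-readable summary with concentrations at
#' 4-decimal precision.
#'
#' @param bundle a [run_workflow()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(bundle[setdiff(names(bundle), "config")],
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null",
                       force = TRUE)
  if (!is.null(bundle$sensitivity))
    utils::write.csv(bundle$sensitivity$ranking,
                     file.path(dir, "sensitivity_ranking.csv"),
                     row.names = FALSE)
  lines <- c(paste("schema:", bundle$schema),
             paste("equilibria:", bundle$summary$n_equilibria,
                   "(", bundle$summary$n_stable, "stable )"))
  if (!is.null(bundle$equilibria))
    for (s in bundle$equilibria$states)
      lines <- c(lines, paste(" ", paste(sprintf("%.4f", s),
                                         collapse = " ")))
  if (!is.null(bundle$summary$bistable_interval))
    lines <- c(lines, paste("bistable interval:",
                            paste(sprintf("%.4f",
                                          bundle$summary$bistable_interval),
                                  collapse = " - ")))
  if (length(bundle$errors))
    lines <- c(lines, paste("ERROR:", bundle$errors))
  writeLines(lines, file.path(dir, "summary.txt"))
  invisible(dir)
}

#' Read a report bundle back from disk
#'
#' @param dir directory written by [write_report()].
#' @return the parsed bundle (lists/vectors; matrices come back as lists).
#' @export
read_artifacts <- function(dir) {
  path <- file.path(dir, "report.json")
  if (!file.exists(path))
    stop("no artifacts found in '", dir, "' (missing report.json)")
  bundle <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(as.character(bundle$schema), SCHEMA_VERSION))
    stop("schema mismatch: artifact version '", bundle$schema,
         "', package version '", SCHEMA_VERSION, "'")
  bundle
}
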