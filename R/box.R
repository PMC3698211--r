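## Axis-aligned boxes in state (or parameter) space, with the face-normal
## and vertex views needed by the domain-of-attraction certificates.

#' Axis-aligned box
#'
#' @param lower,upper numeric bound vectors, `lower < upper` componentwise.
#' @param frame `"absolute"` (concentrations) or `"shifted"` (coordinates
#'   relative to an equilibrium; the origin must then be strictly interior).
#' @param species optional coordinate names.
#' @return object of class `"axis_box"`.
#' @export
axis_box <- function(lower, upper, frame = c("absolute", "shifted"),
                     species = NULL) {
  frame <- match.arg(frame)
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  stopifnot(length(lower) == length(upper))
  if (any(lower >= upper))
    stop("box requires lower < upper componentwise")
  if (frame == "shifted" && (any(lower >= 0) || any(upper <= 0)))
    stop("shifted-frame box must contain the origin strictly in its interior")
  structure(list(lower = lower, upper = upper, frame = frame,
                 species = species), class = "axis_box")
}

#' @export
print.axis_box <- function(x, ...) {
  nm <- if (is.null(x$species)) paste0("x", seq_along(x$lower)) else x$species
  cat("Axis box (", x$frame, " frame):\n", sep = "")
  for (i in seq_along(nm))
    cat(sprintf("  %-8s [%g, %g]\n", nm[i], x$lower[i], x$upper[i]))
  invisible(x)
}

#' Shift a box to equilibrium-centred coordinates
#'
#' @param box an absolute-frame [axis_box()].
#' @param equilibrium state vector or `"equilibrium"` object strictly inside
#'   the box.
#' @return the box in the shifted frame (`z = x - xe`).
#' @export
to_shifted <- function(box, equilibrium) {
  stopifnot(inherits(box, "axis_box"), box$frame == "absolute")
  xe <- if (inherits(equilibrium, "equilibrium")) equilibrium$state
        else as.numeric(equilibrium)
  if (any(xe <= box$lower) || any(xe >= box$upper))
    stop("equilibrium must lie strictly inside the box")
  axis_box(box$lower - xe, box$upper - xe, "shifted", species = box$species)
}

#' Map a shifted box back to absolute coordinates
#'
#' @param box a shifted-frame [axis_box()].
#' @param equilibrium the centring state.
#' @return absolute-frame box.
#' @export
from_shifted <- function(box, equilibrium) {
  stopifnot(inherits(box, "axis_box"), box$frame == "shifted")
  xe <- if (inherits(equilibrium, "equilibrium")) equilibrium$state
        else as.numeric(equilibrium)
  axis_box(box$lower + xe, box$upper + xe, "absolute", species = box$species)
}

#' Face-normal description of a shifted box
#'
#' Returns the `2n` vectors `a_k` such that the box is
#' `{z : a_k' z <= 1, k = 1..2n}`: `a_k = e_k / upper_k` for the upper faces
#' and `a_{n+k} = -e_k / (-lower_k)` for the lower faces. Requires the
#' shifted frame (the canonical form needs 0 interior).
#'
#' @param box a shifted-frame [axis_box()].
#' @return matrix with one column per face normal (`n x 2n`).
#' @export
face_normals <- function(box) {
  stopifnot(inherits(box, "axis_box"), box$frame == "shifted")
  n <- length(box$lower)
  cbind(diag(1 / box$upper, n), diag(1 / box$lower, n))
}

#' Vertex view of a box
#'
#' All `2^n` corners, one per column. Intended for the moderate dimensions
#' of the certification problems (n = 9 gives 512 vertices).
#'
#' @param box an [axis_box()].
#' @return `n x 2^n` matrix of vertices.
#' @export
box_vertices <- function(box) {
  n <- length(box$lower)
  picks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  t(ifelse(picks, rep(box$upper, each = 2^n), rep(box$lower, each = 2^n)))
}

#' Scale a box towards its centre of frame
#'
#' In the shifted frame scaling is about the origin; in the absolute frame
#' about a supplied centre. Scaling by `rho < 1` shrinks.
#'
#' @param box an [axis_box()].
#' @param rho positive scale factor.
#' @param centre centre for absolute-frame boxes.
#' @return scaled box.
#' @export
scale_box <- function(box, rho, centre = NULL) {
  stopifnot(rho > 0)
  if (box$frame == "shifted")
    return(axis_box(box$lower * rho, box$upper * rho, "shifted",
                    species = box$species))
  stopifnot(!is.null(centre))
  axis_box(centre + (box$lower - centre) * rho,
           centre + (box$upper - centre) * rho, "absolute",
           species = box$species)
}

box_contains <- function(box, x, tol = 0) {
  all(x >= box$lower - tol) && all(x <= box$upper + tol)
}

#' Sample points from a box
#'
#' Seeded sampler returning all vertices plus Latin-hypercube interior
#' points, used for simulation-based certificate verification.
#'
#' @param box an [axis_box()].
#' @param n_interior number of Latin-hypercube interior samples.
#' @param seed integer seed.
#' @param include_vertices include all `2^n` corners?
#' @return matrix with one sample per column.
#' @export
sample_box <- function(box, n_interior = 50, seed = 1L,
                       include_vertices = TRUE) {
  n <- length(box$lower)
  pts <- if (include_vertices) box_vertices(box) else
    matrix(numeric(), n, 0)
  if (n_interior > 0) {
    u <- with_seed(seed, {
      m <- vapply(seq_len(n), function(i)
        (sample(n_interior) - stats::runif(n_interior)) / n_interior,
        numeric(n_interior))
      t(m)
    })
    pts <- cbind(pts, box$lower + (box$upper - box$lower) * u)
  }
  pts
}

#' Box serialization to JSON
#'
#' @param box an [axis_box()].
#' @param path optional path; when `NULL` the JSON string is returned.
#' @return JSON (invisibly when written to a file).
#' @export
box_to_json <- function(box, path = NULL) {
  payload <- list(frame = box$frame, species = box$species,
                  lower = box$lower, upper = box$upper)
  if (is.null(path))
    return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname box_to_json
#' @param json a path or JSON string produced by [box_to_json()].
#' @export
box_from_json <- function(json) {
  payload <- jsonlite::fromJSON(json)
  axis_box(payload$lower, payload$upper,
           if (payload$frame == "shifted") "shifted" else "absolute",
           species = payload$species)
}
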