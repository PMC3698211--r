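#' Parse a declarative model-definition document
#'
#' Reads the plain-text network format used by the packaged models. The
#' format has four sections: `species:` (list of identifiers), `constants:`
#' (map of boundary species to concentrations), `parameters:` (map of rate
#' constant names to values) and `reactions:` (list of reaction strings of
#' the form `"A + B -> C + D @ k"`, with `"0"` denoting the empty complex).
#' Lines starting with `#` are comments. List items are introduced by `- `,
#' map entries by `name: value`.
#'
#' @param text either a path to a model file or a character vector of lines.
#' @return a list with components `network` (a [reaction_network()]) and
#'   `parameters` (the named rate-constant vector, in reaction order).
#' @examples
#' mod <- parse_model(c("species:", "  - X",
#'                      "parameters:", "  k: 2.5",
#'                      "reactions:", "  - 0 -> X @ k", "  - X -> 0 @ k"))
#' mod$network$n_reactions
#' @export
parse_model <- function(text) {
  lines <- if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    readLines(text) else unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]

  section <- NULL
  species <- character()
  constants <- numeric()
  parameters <- numeric()
  reaction_strings <- character()
  for (raw in lines) {
    line <- trimws(raw)
    if (grepl("^(species|constants|parameters|reactions):\\s*$", line)) {
      section <- sub(":\\s*$", "", line)
      next
    }
    if (is.null(section)) stop("content before any section header: '", line, "'")
    if (startsWith(line, "- ")) {
      item <- trimws(substring(line, 3L))
      if (section == "species") species <- c(species, item)
      else if (section == "reactions") reaction_strings <- c(reaction_strings, item)
      else stop("list item not allowed in section '", section, "': '", line, "'")
    } else if (grepl(":", line, fixed = TRUE)) {
      kv <- strsplit(line, ":", fixed = TRUE)[[1L]]
      if (length(kv) != 2L) stop("malformed map entry: '", line, "'")
      key <- trimws(kv[1L]); val <- suppressWarnings(as.numeric(trimws(kv[2L])))
      if (is.na(val)) stop("non-numeric value in '", line, "'")
      if (section == "constants") constants[key] <- val
      else if (section == "parameters") parameters[key] <- val
      else stop("map entry not allowed in section '", section, "': '", line, "'")
    } else stop("unparseable line: '", line, "'")
  }
  if (!length(species)) stop("model defines no species")
  if (!length(reaction_strings)) stop("model defines no reactions")

  reactions <- lapply(reaction_strings, function(s) {
    m <- regmatches(s, regexec("^(.*)->(.*)@(.*)$", s))[[1L]]
    if (length(m) != 4L)
      stop("reaction must look like 'A + B -> C @ k': '", s, "'")
    k <- trimws(m[4L])
    if (!k %in% names(parameters))
      stop("reaction '", s, "' uses undeclared rate constant '", k, "'")
    reaction(parse_complex(m[2L]), parse_complex(m[3L]), k, parameters[[k]])
  })
  net <- reaction_network(species, reactions, constants)
  list(network = net, parameters = nominal_parameters(net))
}

## "A + 2 B" -> c("A", "B", "B"); "0" or "" -> character()
parse_complex <- function(s) {
  parts <- trimws(strsplit(s, "+", fixed = TRUE)[[1L]])
  parts <- parts[nzchar(parts)]
  if (!length(parts) || identical(parts, "0")) return(character())
  out <- character()
  for (pt in parts) {
    m <- regmatches(pt, regexec("^([0-9]+)\\s+(.*)$", pt))[[1L]]
    if (length(m) == 3L) out <- c(out, rep(m[3L], as.integer(m[2L])))
    else out <- c(out, pt)
  }
  out
}

#' Serialize a network back to the model-definition format
#'
#' Inverse of [parse_model()]; numeric values are written with 17 significant
#' digits so that a parse/write/parse round trip reproduces rate constants
#' bit-exactly.
#'
#' @param network a [reaction_network()].
#' @param path optional file path; if `NULL` the lines are returned.
#' @return character vector of lines (invisibly when `path` is given).
#' @export
write_model <- function(network, path = NULL) {
  num <- function(x) formatC(x, digits = 17, format = "g")
  fmt_complex <- function(v) if (length(v)) paste(v, collapse = " + ") else "0"
  lines <- c("species:", paste0("  - ", network$species_names))
  if (length(network$constant_inputs))
    lines <- c(lines, "constants:",
               paste0("  ", names(network$constant_inputs), ": ",
                      num(network$constant_inputs)))
  lines <- c(lines, "parameters:",
             paste0("  ", names(network$rate_values), ": ",
                    num(network$rate_values)))
  lines <- c(lines, "reactions:",
             vapply(network$reactions, function(r)
               paste0("  - ", fmt_complex(r$reactants), " -> ",
                      fmt_complex(r$products), " @ ", r$rate_name), ""))
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}
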