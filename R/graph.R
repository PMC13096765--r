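#' Define a multistate transition graph
#'
#' A transition graph lists the states of a multistate process and the
#' permitted directed transitions between them. Transitions are indexed
#' \code{g = 1, ..., G} in the order supplied; this index is the one used in
#' long-format data files and in every diagnostic output.
#'
#' @param n_states number of states, numbered \code{1:n_states}.
#' @param transitions two-column integer matrix (or data.frame) of
#'   (from, to) state pairs; row \code{g} defines transition \code{g}.
#' @param absorbing integer vector of absorbing state ids (no outgoing
#'   transitions allowed).
#'
#' @return An object of class \code{"transition_graph"} with elements
#'   \code{n_states}, \code{transitions} (data.frame with columns
#'   \code{trans}, \code{from}, \code{to}) and \code{absorbing}.
#'
#' @examples
#' g <- transition_graph(3, rbind(c(1, 2), c(1, 3), c(2, 3)), absorbing = 3)
#' g
#' @seealso [figure1_graph()] for the built-in 5-state breast-cancer preset.
#' @export
transition_graph <- function(n_states, transitions, absorbing = integer()) {
  transitions <- as.matrix(transitions)
  if (ncol(transitions) != 2L)
    stop("'transitions' must have two columns (from, to)")
  storage.mode(transitions) <- "integer"
  n_states <- as.integer(n_states)
  absorbing <- as.integer(absorbing)
  G <- nrow(transitions)
  if (G < 1L) stop("at least one transition is required")
  if (any(transitions < 1L) || any(transitions > n_states))
    stop("transition endpoints must be states in 1..n_states")
  if (any(transitions[, 1L] == transitions[, 2L]))
    stop("self-transitions are not allowed")
  key <- paste(transitions[, 1L], transitions[, 2L])
  if (anyDuplicated(key))
    stop("duplicate (from, to) transition pair")
  if (any(transitions[, 1L] %in% absorbing))
    stop("transition leaves an absorbing state: ",
         paste(which(transitions[, 1L] %in% absorbing), collapse = ", "))
  structure(
    list(n_states = n_states,
         transitions = data.frame(trans = seq_len(G),
                                  from = transitions[, 1L],
                                  to = transitions[, 2L]),
         absorbing = sort(absorbing)),
    class = "transition_graph")
}

#' Five-state breast-cancer progression graph
#'
#' The preset \code{"figure1_breast5"}: states are 1 = post-surgery,
#' 2 = local relapse, 3 = distant relapse, 4 = cancer death,
#' 5 = other-cause death. Nine transitions are permitted
#' (1\eqn{\to}{->}2, 1\eqn{\to}{->}3, 1\eqn{\to}{->}4, 1\eqn{\to}{->}5,
#' 2\eqn{\to}{->}3, 2\eqn{\to}{->}4, 2\eqn{\to}{->}5, 3\eqn{\to}{->}4,
#' 3\eqn{\to}{->}5); both death states are absorbing.
#'
#' @return A \code{"transition_graph"} with 5 states and 9 transitions.
#' @export
figure1_graph <- function() {
  transition_graph(
    n_states = 5L,
    transitions = rbind(
      c(1L, 2L), c(1L, 3L), c(1L, 4L), c(1L, 5L),
      c(2L, 3L), c(2L, 4L), c(2L, 5L),
      c(3L, 4L), c(3L, 5L)),
    absorbing = c(4L, 5L))
}

#' @export
print.transition_graph <- function(x, ...) {
  cat("Transition graph:", x$n_states, "states,",
      nrow(x$transitions), "transitions\n")
  tr <- x$transitions
  cat(paste0("  g=", tr$trans, ": ", tr$from, " -> ", tr$to), sep = "\n")
  if (length(x$absorbing))
    cat("Absorbing states:", paste(x$absorbing, collapse = ", "), "\n")
  invisible(x)
}

n_transitions <- function(graph) nrow(graph$transitions)

#' Read a transition graph (and optional covariate mapping) from a config file
#'
#' The config is a YAML key-value file with fields \code{n_states},
#' \code{transitions} (list of two-element \code{[from, to]} pairs, in
#' transition-index order), \code{absorbing}, and optionally
#' \code{covariate_map} (named map from coefficient name to a list with
#' \code{covariate} and \code{transitions}). Alternatively \code{preset:
#' figure1_breast5} selects the built-in graph.
#'
#' @param path path to the YAML config.
#' @return A list with elements \code{graph} (a \code{"transition_graph"}) and
#'   \code{covariate_map} (a mapping usable by [expand_covariates()], or
#'   \code{NULL}).
#' @export
read_graph_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$preset)) {
    if (cfg$preset != "figure1_breast5")
      stop("unknown graph preset: ", cfg$preset)
    graph <- figure1_graph()
  } else {
    tr <- do.call(rbind, lapply(cfg$transitions, as.integer))
    graph <- transition_graph(cfg$n_states, tr,
                              absorbing = as.integer(cfg$absorbing %||% integer()))
  }
  map <- NULL
  if (!is.null(cfg$covariate_map)) {
    map <- lapply(cfg$covariate_map, function(m)
      list(covariate = m$covariate, transitions = as.integer(m$transitions)))
  }
  list(graph = graph, covariate_map = map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
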