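#' Construct a long-format multistate dataset
#'
#' One row per patient-at-risk-for-transition. Times follow the clock-reset
#' convention: each record's own time axis starts at 0 when the patient enters
#' the transition's origin state, so the modelling time of a record is
#' \code{Tstop - Tstart} (its sojourn in the origin state), regardless of the
#' study-time origin \code{Tstart}.
#'
#' @param records data.frame with columns \code{id}, \code{from}, \code{to},
#'   \code{trans}, \code{Tstart}, \code{Tstop}, \code{status}.
#' @param graph a [transition_graph()].
#' @param covariates data.frame of per-record base covariates (one row per
#'   record row), or \code{NULL}.
#'
#' @return An object of class \code{"msdata"}: a list with \code{graph},
#'   \code{records} (with derived clock-reset columns \code{entry} = 0 and
#'   \code{time} = \code{Tstop - Tstart}), \code{covariates}, and (after
#'   [expand_covariates()]) a transition-specific \code{design} matrix.
#'   Derived dimensions are available through [dims()].
#' @export
msdata <- function(records, graph, covariates = NULL) {
  stopifnot(inherits(graph, "transition_graph"))
  needed <- c("id", "from", "to", "trans", "Tstart", "Tstop", "status")
  miss <- setdiff(needed, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  records <- as.data.frame(records)
  records$id <- as.character(records$id)
  records$trans <- as.integer(records$trans)
  G <- n_transitions(graph)
  bad <- which(records$trans < 1L | records$trans > G)
  if (length(bad))
    stop("unknown transition id in row(s): ", paste(bad, collapse = ", "))
  tr <- graph$transitions
  mism <- which(records$from != tr$from[records$trans] |
                records$to != tr$to[records$trans])
  if (length(mism))
    stop("(from, to) disagrees with graph transition in row(s): ",
         paste(mism, collapse = ", "))
  dur <- records$Tstop - records$Tstart
  bad <- which(!(dur > 0))
  if (length(bad))
    stop("non-positive duration (Tstop <= Tstart) in row(s): ",
         paste(bad, collapse = ", "))
  if (!all(records$status %in% c(0, 1)))
    stop("status must be 0 or 1")
  dup <- which(duplicated(records[c("id", "trans")]))
  if (length(dup))
    stop("duplicated (id, trans) pair in row(s): ", paste(dup, collapse = ", "))
  records$entry <- 0
  records$time <- dur
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(records))
      stop("covariates must have one row per record")
  }
  structure(list(graph = graph, records = records, covariates = covariates,
                 design = NULL, coef_names = character(),
                 covariate_map = NULL),
            class = "msdata")
}

#' Dataset dimensions
#'
#' @param data an \code{"msdata"} object.
#' @return list with \code{G} (transitions), \code{N_g} (records per
#'   transition), \code{N} (total records), \code{M} (distinct patients) and
#'   \code{p} (expanded design columns, 0 before [expand_covariates()]).
#' @export
dims <- function(data) {
  stopifnot(inherits(data, "msdata"))
  G <- n_transitions(data$graph)
  N_g <- tabulate(data$records$trans, nbins = G)
  list(G = G, N_g = N_g, N = nrow(data$records),
       M = length(unique(data$records$id)),
       p = if (is.null(data$design)) 0L else ncol(data$design))
}

#' @export
print.msdata <- function(x, ...) {
  d <- dims(x)
  cat("Multistate dataset:", d$M, "patients,", d$N, "records,",
      d$G, "transitions\n")
  cat("Records per transition:", paste(d$N_g, collapse = ", "), "\n")
  if (!is.null(x$design))
    cat("Expanded design: p =", ncol(x$design), "(",
        paste(colnames(x$design), collapse = ", "), ")\n")
  invisible(x)
}

#' Patient ids in their canonical (first-appearance) order
#' @param data an \code{"msdata"} object.
#' @return character vector of length M.
#' @export
patient_ids <- function(data) unique(data$records$id)

#' Transition-membership indicator matrix
#'
#' Element (g, i) is \code{TRUE} exactly when patient i has a record for
#' transition g.
#'
#' @param data an \code{"msdata"} object.
#' @return G x M logical matrix with patient ids as column names.
#' @export
membership_matrix <- function(data) {
  ids <- patient_ids(data)
  G <- n_transitions(data$graph)
  I <- matrix(FALSE, G, length(ids), dimnames = list(NULL, ids))
  idx <- cbind(data$records$trans, match(data$records$id, ids))
  I[idx] <- TRUE
  I
}

#' Read long-format multistate data from a delimited text file
#'
#' Expects a header row \code{id, from, to, trans, Tstart, Tstop, status}
#' followed by covariate columns; the delimiter (comma or tab) is
#' auto-detected. Malformed rows are rejected with row-numbered diagnostics.
#'
#' @param path path to the file.
#' @param graph a [transition_graph()] the \code{trans} ids must match.
#' @return A validated \code{"msdata"} object; clock-reset record time is
#'   \code{Tstop - Tstart}.
#' @export
read_long_format <- function(path, graph) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("id", "from", "to", "trans", "Tstart", "Tstop", "status")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("file lacks required columns: ", paste(miss, collapse = ", "))
  covnames <- setdiff(names(df), needed)
  covs <- if (length(covnames)) df[covnames] else NULL
  msdata(df[needed], graph, covariates = covs)
}

#' Write a multistate dataset back to delimited text
#'
#' Inverse of [read_long_format()]: emits the standard columns followed by the
#' base covariates, at full precision, so a write/read round trip reproduces
#' the numeric content exactly.
#'
#' @param data an \code{"msdata"} object.
#' @param path output path.
#' @param sep field separator (default tab).
#' @export
write_long_format <- function(data, path, sep = "\t") {
  out <- data$records[c("id", "from", "to", "trans", "Tstart", "Tstop",
                        "status")]
  if (!is.null(data$covariates)) out <- cbind(out, data$covariates)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Resolve simultaneous local and distant relapses in a patient timeline
#'
#' When a local (state 2) and a distant (state 3) relapse are recorded at the
#' identical time, progression is taken to be sequential from local to distant
#' and 0.1 months is added to the distant-relapse time so no interval has zero
#' length. A local relapse recorded strictly after a distant relapse is
#' dropped. The operation is idempotent.
#'
#' @param timeline data.frame with columns \code{id}, \code{state},
#'   \code{time} (study-time of entering the state, in months).
#' @param local,distant state ids of the local- and distant-relapse states.
#' @param increment months added to the distant time on a tie (default 0.1).
#' @return the adjusted timeline (rows possibly dropped, distant times
#'   possibly shifted).
#' @export
resolve_simultaneous_relapse <- function(timeline, local = 2L, distant = 3L,
                                         increment = 0.1) {
  stopifnot(all(c("id", "state", "time") %in% names(timeline)))
  drop <- logical(nrow(timeline))
  for (pid in unique(timeline$id)) {
    rows <- which(timeline$id == pid)
    li <- rows[timeline$state[rows] == local]
    di <- rows[timeline$state[rows] == distant]
    if (!length(li) || !length(di)) next
    tl <- timeline$time[li[1L]]; td <- timeline$time[di[1L]]
    if (tl == td) {
      timeline$time[di[1L]] <- td + increment
    } else if (tl > td) {
      drop[li[1L]] <- TRUE
    }
  }
  timeline[!drop, , drop = FALSE]
}

#' Truncate (winsorize from above) a base covariate
#'
#' Values greater than \code{cap} are recoded to \code{cap}; all other values
#' are untouched. Returns a new dataset; if a design matrix had been expanded
#' it is re-expanded from the truncated covariates.
#'
#' @param data an \code{"msdata"} object.
#' @param name covariate name.
#' @param cap upper cap (same units as the covariate).
#' @return a new \code{"msdata"} object.
#' @export
truncate_covariate <- function(data, name, cap) {
  stopifnot(inherits(data, "msdata"))
  if (is.null(data$covariates) || !name %in% names(data$covariates))
    stop("unknown covariate: ", name)
  data$covariates[[name]] <- pmin(data$covariates[[name]], cap)
  if (!is.null(data$covariate_map))
    data <- expand_covariates(data, data$covariate_map)
  data
}

#' Expand base covariates into a transition-specific design
#'
#' Each mapping entry defines one model coefficient: the named base covariate
#' enters the linear predictor only for the listed transitions (zero
#' elsewhere). Mapping one covariate to several transitions shares a single
#' coefficient across them; transition-specific effects are obtained by
#' listing the same covariate under several entries with disjoint transition
#' sets.
#'
#' @param data an \code{"msdata"} object carrying base covariates.
#' @param mapping named list; each element is either an integer vector of
#'   transition ids (the entry name is then the covariate name) or a list
#'   with fields \code{covariate} and \code{transitions}. Entry names become
#'   coefficient names.
#' @return a new \code{"msdata"} with \code{design} (N x p matrix) and
#'   \code{coef_names} filled in. An empty mapping yields p = 0.
#' @export
expand_covariates <- function(data, mapping) {
  stopifnot(inherits(data, "msdata"))
  G <- n_transitions(data$graph)
  N <- nrow(data$records)
  p <- length(mapping)
  cn <- names(mapping)
  if (p > 0 && (is.null(cn) || any(cn == "")))
    stop("every mapping entry must be named (the coefficient name)")
  Z <- matrix(0, N, p, dimnames = list(NULL, cn))
  for (j in seq_len(p)) {
    m <- mapping[[j]]
    if (is.list(m)) {
      covname <- m$covariate; gset <- as.integer(m$transitions)
    } else {
      covname <- cn[j]; gset <- as.integer(m)
    }
    if (any(gset < 1L | gset > G))
      stop("mapping '", cn[j], "' references unknown transition")
    if (is.null(data$covariates) || !covname %in% names(data$covariates))
      stop("mapping '", cn[j], "' references unknown covariate: ", covname)
    on <- data$records$trans %in% gset
    Z[on, j] <- data$covariates[[covname]][on]
  }
  data$design <- Z
  data$coef_names <- cn %||% character()
  data$covariate_map <- mapping
  data
}

# Rows of each transition, as a list of integer vectors (internal).
transition_rows <- function(data) {
  G <- n_transitions(data$graph)
  split(seq_len(nrow(data$records)),
        factor(data$records$trans, levels = seq_len(G)))
}

# Drop all records of the given patient ids; keeps design columns (internal).
drop_patients <- function(data, ids) {
  keep <- !(data$records$id %in% ids)
  data$records <- data$records[keep, , drop = FALSE]
  if (!is.null(data$covariates))
    data$covariates <- data$covariates[keep, , drop = FALSE]
  if (!is.null(data$design))
    data$design <- data$design[keep, , drop = FALSE]
  rownames(data$records) <- NULL
  data
}
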