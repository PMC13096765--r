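#' Configuration for the synthetic multistate cohort generator
#'
#' Defaults emulate a breast-cancer progression cohort on the five-state
#' graph of [figure1_graph()]: months as the time unit, constant
#' per-transition baseline hazards, tumour size (mm, lognormal around 22 mm),
#' a high-grade indicator, and age centred at 60 years; administrative
#' censoring uniform between 60 and 300 months. Size and grade drive the
#' three transitions out of surgery, size drives post-relapse progression and
#' cancer death, and age drives the transitions to other-cause death only.
#'
#' @param n cohort size (>= 2).
#' @param graph a [transition_graph()].
#' @param rates positive per-transition baseline hazard rates (per month),
#'   length G.
#' @param shape Weibull shape per transition (length 1 or G); 1 gives
#'   constant (exponential) baseline hazards.
#' @param effects named list of coefficient definitions, each a list with
#'   \code{covariate}, \code{transitions}, and true value \code{beta}.
#' @param covariates function of n returning a data.frame of per-patient
#'   base covariates; the default draws \code{size}, \code{grade},
#'   \code{agec}.
#' @param censoring length-2 window (months): administrative censoring time
#'   is uniform on it.
#' @return a \code{"sim_config"} list; its \code{beta_true} element is the
#'   true coefficient vector in expanded-design order.
#' @export
sim_config <- function(n = 300,
                       graph = figure1_graph(),
                       rates = c(0.0008, 0.0012, 0.0002, 0.0008,
                                 0.02, 0.005, 0.001, 0.03, 0.001),
                       shape = 1,
                       effects = list(
                         size_surgery = list(covariate = "size",
                                             transitions = c(1L, 2L, 3L),
                                             beta = 0.04),
                         grade_surgery = list(covariate = "grade",
                                              transitions = c(1L, 2L, 3L),
                                              beta = 0.5),
                         size_relapse = list(covariate = "size",
                                             transitions = c(5L, 6L, 8L),
                                             beta = 0.015),
                         age_death = list(covariate = "agec",
                                          transitions = c(4L, 7L, 9L),
                                          beta = 0.05)),
                       covariates = NULL,
                       censoring = c(60, 300)) {
  G <- n_transitions(graph)
  if (length(rates) != G) stop("need one baseline rate per transition")
  if (any(rates <= 0)) stop("baseline rates must be positive")
  if (length(shape) == 1L) shape <- rep(shape, G)
  if (any(shape <= 0)) stop("Weibull shapes must be positive")
  if (n < 2) stop("n must be at least 2")
  if (length(censoring) != 2L || any(censoring <= 0) ||
      censoring[2] < censoring[1])
    stop("censoring must be an increasing positive window")
  if (is.null(covariates))
    covariates <- function(n)
      data.frame(size = stats::rlnorm(n, log(22), 0.45),
                 grade = stats::rbinom(n, 1L, 0.5),
                 agec = stats::rnorm(n, 0, 10))
  beta_true <- vapply(effects, function(e) e$beta, numeric(1))
  structure(list(n = as.integer(n), graph = graph, rates = rates,
                 shape = shape, effects = effects, covariates = covariates,
                 censoring = censoring, beta_true = beta_true),
            class = "sim_config")
}

#' Simulate a clock-reset multistate cohort with known truth
#'
#' Each patient starts in state 1. From the current state, one latent clock
#' per outgoing transition is drawn from a Weibull (by default exponential)
#' hazard \eqn{\lambda_{g,0}(t) \exp(\beta_{true}^T Z_g)} on the clock-reset
#' scale; the minimum wins, the clock resets on entry to the next state, and
#' the trajectory stops at an absorbing state or administrative censoring
#' (applied on the study-time scale). Every at-risk transition of every
#' occupied state yields one long-format record. Deterministic given the
#' seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed for the cohort's pseudo-random stream.
#' @return list with \code{data} (an \code{"msdata"} with the design already
#'   expanded from the config's covariate mapping) and \code{truth}
#'   (\code{beta_true}, the covariate mapping, the seed, and the config).
#' @export
simulate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  graph <- config$graph
  tr <- graph$transitions
  G <- nrow(tr)
  covs <- config$covariates(config$n)
  mapping <- lapply(config$effects, function(e)
    list(covariate = e$covariate, transitions = e$transitions))
  # per-transition log hazard multiplier for each patient
  logmult <- matrix(0, config$n, G)
  for (e in config$effects)
    logmult[, e$transitions] <- logmult[, e$transitions] +
      e$beta * covs[[e$covariate]]
  cens <- stats::runif(config$n, config$censoring[1], config$censoring[2])
  out_from <- split(seq_len(G), factor(tr$from, levels = seq_len(graph$n_states)))
  recs <- vector("list", config$n)
  for (k in seq_len(config$n)) {
    state <- 1L
    now <- 0
    krecs <- list()
    while (!(state %in% graph$absorbing)) {
      gs <- out_from[[state]]
      if (!length(gs)) break                       # dead-end non-absorbing
      # Weibull latent clocks: T = (E / rate)^(1/shape), E ~ Exp(1)
      lat <- (stats::rexp(length(gs)) /
                (config$rates[gs] * exp(logmult[k, gs])))^(1 / config$shape[gs])
      tmin <- min(lat)
      win <- gs[which.min(lat)]
      sojourn <- min(tmin, cens[k] - now)
      event <- tmin < cens[k] - now
      krecs[[length(krecs) + 1L]] <- data.frame(
        id = sprintf("P%04d", k), from = state, to = tr$to[gs], trans = gs,
        Tstart = now, Tstop = now + sojourn,
        status = as.integer(event & gs == win))
      if (!event) break
      now <- now + tmin
      state <- tr$to[win]
    }
    recs[[k]] <- do.call(rbind, krecs)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  base <- covs[match(match(records$id, sprintf("P%04d", seq_len(config$n))),
                     seq_len(config$n)), , drop = FALSE]
  rownames(base) <- NULL
  data <- msdata(records, graph, covariates = base)
  data <- expand_covariates(data, mapping)
  list(data = data,
       truth = list(beta_true = config$beta_true, mapping = mapping,
                    seed = seed, config = config))
}

#' Inject contaminated (influential) patients into a simulated cohort
#'
#' Emulates the kinds of anomalies case-influence diagnostics should catch:
#' patients with extreme covariate values (e.g., tumour sizes far above the
#' cohort's range) and/or atypically fast progression (a sharply shrunken
#' sojourn before their first event) or atypically long post-relapse
#' survival. Targets are drawn among patients with at least one event
#' (preferring relapse events out of state 1, where such anomalies distort
#' risk sets most). The original dataset is not modified; the contaminated
#' ids are returned as ground truth.
#'
#' @param data an \code{"msdata"} (with design expanded from a covariate
#'   map, as produced by [simulate_cohort()]).
#' @param n_outliers number of patients to contaminate (< number of
#'   patients).
#' @param covariate base covariate to inflate (default \code{"size"}).
#' @param factor multiplier for the extreme-covariate mechanism.
#' @param time_factor multiplier (< 1) for the fast-transition mechanism.
#' @param slow_factor multiplier (> 1) for the slow-survival mechanism.
#' @param mechanisms subset of \code{c("extreme_covariate",
#'   "fast_transition", "slow_survival")} applied to every target.
#' @param seed seed for the contamination's own pseudo-random stream.
#' @return list with \code{data} (modified copy, design re-expanded) and
#'   \code{ids} (character vector of contaminated patient ids).
#' @export
inject_outliers <- function(data, n_outliers = 2L, covariate = "size",
                            factor = 6, time_factor = 0.2, slow_factor = 4,
                            mechanisms = c("extreme_covariate",
                                           "fast_transition"),
                            seed = 1L) {
  stopifnot(inherits(data, "msdata"))
  mechanisms <- match.arg(mechanisms, c("extreme_covariate",
                                        "fast_transition", "slow_survival"),
                          several.ok = TRUE)
  ids <- patient_ids(data)
  if (!length(ids)) stop("empty dataset")
  if (n_outliers >= length(ids))
    stop("n_outliers must be smaller than the number of patients")
  set.seed(seed)
  rec <- data$records
  ev_ids <- unique(rec$id[rec$status == 1])
  relapse_ids <- unique(rec$id[rec$status == 1 & rec$from == 1L &
                                 rec$to %in% c(2L, 3L)])
  pool <- if (length(relapse_ids) >= n_outliers) relapse_ids
          else if (length(ev_ids) >= n_outliers) ev_ids else ids
  targets <- sample(pool, n_outliers)
  for (pid in targets) {
    if ("extreme_covariate" %in% mechanisms) {
      on <- rec$id == pid
      data$covariates[[covariate]][on] <- data$covariates[[covariate]][on] *
        factor
    }
    if ("fast_transition" %in% mechanisms) {
      prow <- which(rec$id == pid & rec$status == 1)[1L]
      if (!is.na(prow))
        rec <- scale_epoch(rec, pid, rec$from[prow], time_factor)
    }
    if ("slow_survival" %in% mechanisms) {
      prows <- which(rec$id == pid & rec$from %in% c(2L, 3L))
      for (s in unique(rec$from[prows]))
        rec <- scale_epoch(rec, pid, s, slow_factor)
    }
  }
  data$records <- rec
  data$records$time <- rec$Tstop - rec$Tstart
  if (!is.null(data$covariate_map))
    data <- expand_covariates(data, data$covariate_map)
  list(data = data, ids = targets)
}

# Scale the sojourn of one patient's epoch (records sharing the origin
# state), shifting the patient's later epochs to keep the study-time
# trajectory coherent (internal).
scale_epoch <- function(rec, pid, from_state, factor) {
  on <- rec$id == pid & rec$from == from_state
  if (!any(on)) return(rec)
  epoch_start <- rec$Tstart[on][1L]
  old <- rec$Tstop[on] - rec$Tstart[on]
  new <- old * factor
  shift <- (new - old)[1L]
  rec$Tstop[on] <- rec$Tstart[on] + new
  later <- rec$id == pid & !on & rec$Tstart >= epoch_start + old[1L] - 1e-12
  rec$Tstart[later] <- rec$Tstart[later] + shift
  rec$Tstop[later] <- rec$Tstop[later] + shift
  rec
}
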