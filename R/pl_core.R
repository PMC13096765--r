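# Model: for transition g (a permitted move between states) and patient k the
# hazard is lambda_g(t) = lambda_{g,0}(t) exp(beta' Z_{g,k}) on the
# clock-reset scale (t = months since entering the origin state). The
# generalized partial likelihood multiplies the usual Cox factors over all
# transitions, with risk sets formed within each transition; tied event times
# share the full risk-set denominator (Breslow).

# One pass over all event records: log partial likelihood, score, Hessian,
# and per-event quantities reused by every influence measure.
# Event order is g-major, record order within g.
pl_eval <- function(beta, data, need_hessian = TRUE) {
  Z <- data$design
  if (is.null(Z)) stop("no design matrix; call expand_covariates() first")
  p <- ncol(Z)
  stopifnot(length(beta) == p)
  rec <- data$records
  rows_by_g <- transition_rows(data)
  loglik <- 0
  U <- numeric(p)
  H <- matrix(0, p, p)
  ev_row <- integer(0); ev_v <- numeric(0); ev_C <- numeric(0)
  Uev <- NULL
  for (g in seq_along(rows_by_g)) {
    rows <- rows_by_g[[g]]
    if (!length(rows)) next
    Zg <- Z[rows, , drop = FALSE]
    entry <- rec$entry[rows]; exit <- rec$time[rows]
    eta <- if (p) drop(Zg %*% beta) else numeric(length(rows))
    evs <- which(rec$status[rows] == 1)
    for (e in evs) {
      t_e <- exit[e]
      at_risk <- entry < t_e & t_e <= exit
      if (!any(at_risk))
        stop("event with empty risk set (transition ", g, "); broken data prep")
      # log-sum-exp shift: every downstream quantity is a ratio, so it is
      # invariant to the shift, and exp() can no longer over/underflow
      m <- max(eta[at_risk])
      Q <- exp(eta[at_risk] - m)
      C <- sum(Q)
      loglik <- loglik + eta[e] - m - log(C)
      if (p) {
        Zr <- Zg[at_risk, , drop = FALSE]
        S1 <- drop(crossprod(Zr, Q))            # sum Q_l Z_l (shifted)
        u <- Zg[e, ] - S1 / C
        U <- U + u
        if (need_hessian) {
          S2 <- crossprod(Zr, Zr * Q)           # sum Q_l Z_l Z_l' (shifted)
          H <- H + (tcrossprod(S1) / C - S2) / C
        }
        Uev <- rbind(Uev, u)
      }
      ev_row <- c(ev_row, rows[e])
      ev_v <- c(ev_v, 1 - exp(eta[e] - m) / C)
      ev_C <- c(ev_C, C * exp(m))
    }
  }
  if (is.null(Uev)) Uev <- matrix(0, length(ev_row), p)
  dimnames(Uev) <- list(NULL, colnames(Z))
  list(loglik = loglik, score = U, hessian = H,
       events = data.frame(row = ev_row,
                           id = rec$id[ev_row],
                           trans = rec$trans[ev_row],
                           time = rec$time[ev_row],
                           v = ev_v, C = ev_C),
       U_events = Uev)
}

#' Risk set of a transition at a given time
#'
#' All records of transition \code{g} whose clock-reset interval
#' (entry, time] contains \code{t}; records exiting exactly at \code{t} are
#' included regardless of event status (Breslow convention).
#'
#' @param data an \code{"msdata"} object.
#' @param g transition id.
#' @param t clock-reset time, > 0.
#' @return integer vector of record row indices (rows of
#'   \code{data$records}).
#' @export
risk_set <- function(data, g, t) {
  stopifnot(inherits(data, "msdata"), t > 0)
  G <- n_transitions(data$graph)
  if (!(g %in% seq_len(G))) stop("unknown transition: ", g)
  rows <- which(data$records$trans == g)
  rows[data$records$entry[rows] < t & t <= data$records$time[rows]]
}

#' Log generalized Cox partial likelihood
#'
#' \deqn{\ell_P(\beta) = \sum_g \sum_{k: d_{g,k}=1} \left[ Z_{g,k}^T\beta -
#'   \log \sum_{l \in R(t_{g,k})} \exp(Z_{g,l}^T\beta) \right]}
#' with risk sets formed within each transition on the clock-reset scale.
#'
#' @param beta coefficient vector (length p of the expanded design).
#' @param data an \code{"msdata"} with an expanded design.
#' @return scalar log partial likelihood.
#' @export
log_partial_likelihood <- function(beta, data)
  pl_eval(beta, data, need_hessian = FALSE)$loglik

#' Score of the log partial likelihood
#'
#' Each event record (g, k) contributes
#' \eqn{U_{g,k} = Z_{g,k} - \sum_l Q_{g,l} Z_{g,l} / C_{g,k}} where
#' \eqn{Q_{g,l} = \exp(\beta^T Z_{g,l})} and \eqn{C_{g,k} = \sum_l Q_{g,l}}
#' over the risk set; censored records contribute nothing.
#'
#' @inheritParams log_partial_likelihood
#' @return list with \code{total} (length-p score vector) and
#'   \code{per_event} (events x p matrix, events in g-major order, with
#'   companion columns in \code{events}).
#' @export
pl_score <- function(beta, data) {
  ev <- pl_eval(beta, data, need_hessian = FALSE)
  list(total = ev$score, per_event = ev$U_events, events = ev$events)
}

#' Hessian of the log partial likelihood
#'
#' @inheritParams log_partial_likelihood
#' @return p x p symmetric negative semidefinite matrix.
#' @export
pl_hessian <- function(beta, data) pl_eval(beta, data)$hessian

#' Fit the multistate Cox model by Newton-Raphson
#'
#' Maximizes the generalized partial likelihood with analytic score and
#' Hessian, step-halving when a step fails to increase the likelihood.
#' Convergence is declared when the largest absolute score component drops
#' below \code{tol}; if an iteration makes exactly zero log-likelihood
#' progress (the floating-point stall that occurs when covariates are large
#' enough that the score's accuracy floor exceeds \code{tol}), the fit is
#' instead accepted once the Newton decrement
#' \eqn{U^T(-\ddot\ell_P)^{-1}U} — the expected remaining log-likelihood
#' improvement, invariant to covariate scaling — is below \code{tol}.
#'
#' @param data an \code{"msdata"} with an expanded design
#'   (see [expand_covariates()]).
#' @param init starting value (default all zeros).
#' @param tol convergence tolerance on \code{max(abs(score))}.
#' @param max_iter maximum Newton iterations.
#' @return An object of class \code{"mscox"}: \code{beta} (named),
#'   \code{loglik}, \code{score}, \code{hessian}, \code{V}
#'   (\eqn{-\ddot\ell_P^{-1}}, the large-sample covariance of
#'   \eqn{\hat\beta}), \code{U_events} and \code{events} (per-event score
#'   contributions and bookkeeping), \code{baseline} (per-transition
#'   Nelson-Aalen cumulative baseline hazards), \code{iter},
#'   \code{converged}.
#' @examples
#' cfg <- sim_config(n = 80)
#' sim <- simulate_cohort(cfg, seed = 1)
#' fit <- fit_mscox(sim$data)
#' summary(fit)
#' @export
fit_mscox <- function(data, init = NULL, tol = 1e-8, max_iter = 50L) {
  Z <- data$design
  if (is.null(Z)) stop("no design matrix; call expand_covariates() first")
  p <- ncol(Z)
  beta <- if (is.null(init)) numeric(p) else as.numeric(init)
  stopifnot(length(beta) == p)
  if (p == 0L) {
    ev <- pl_eval(numeric(0), data, need_hessian = FALSE)
    fit <- structure(
      list(beta = numeric(0), loglik = ev$loglik, score = numeric(0),
           hessian = matrix(0, 0, 0), V = matrix(0, 0, 0),
           U_events = ev$U_events, events = ev$events,
           iter = 0L, converged = TRUE, tol = tol),
      class = "mscox")
    fit$baseline <- lapply(seq_len(n_transitions(data$graph)),
                           function(g) nelson_aalen_baseline(fit, data, g))
    return(fit)
  }
  newton_decrement <- function(ev) {
    Hs <- (ev$hessian + t(ev$hessian)) / 2
    dec <- tryCatch(drop(crossprod(ev$score, solve(-Hs, ev$score))),
                    error = function(e) Inf)
    if (is.finite(dec)) dec else Inf
  }
  ev <- pl_eval(beta, data)
  iter <- 0L
  converged <- max(abs(ev$score)) <= tol
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    Hs <- (ev$hessian + t(ev$hessian)) / 2
    step <- tryCatch(solve(Hs, -ev$score), error = function(e)
      stop("singular Hessian: collinear design within the risk sets"))
    new_beta <- beta + step
    new_ev <- pl_eval(new_beta, data)
    halvings <- 0L
    while ((!is.finite(new_ev$loglik) || new_ev$loglik < ev$loglik) &&
           halvings < 30L) {
      halvings <- halvings + 1L
      step <- step / 2
      new_beta <- beta + step
      new_ev <- pl_eval(new_beta, data)
    }
    if (new_ev$loglik < ev$loglik) {
      # no representable ascent along the Newton direction: accept the
      # current iterate if the expected remaining gain is below tolerance
      if (newton_decrement(ev) <= tol) { converged <- TRUE; break }
      stop("partial likelihood failed to increase after 30 step halvings")
    }
    improve <- new_ev$loglik - ev$loglik
    beta <- new_beta
    ev <- new_ev
    converged <- max(abs(ev$score)) <= tol ||
      (improve == 0 && newton_decrement(ev) <= tol)
  }
  if (!converged)
    stop("Newton-Raphson did not converge in ", max_iter, " iterations")
  Hs <- (ev$hessian + t(ev$hessian)) / 2
  V <- chol2inv(chol(-Hs))
  dimnames(V) <- dimnames(Hs) <- list(colnames(Z), colnames(Z))
  names(beta) <- colnames(Z)
  fit <- structure(
    list(beta = beta, loglik = ev$loglik, score = ev$score, hessian = Hs,
         V = V, U_events = ev$U_events, events = ev$events,
         iter = iter, converged = TRUE, tol = tol),
    class = "mscox")
  fit$baseline <- lapply(seq_len(n_transitions(data$graph)),
                         function(g) nelson_aalen_baseline(fit, data, g))
  fit
}

#' Nelson-Aalen cumulative baseline hazard for one transition
#'
#' \deqn{\hat\Lambda_{g,0}(t) = \sum_{t_{g,k} \le t, d_{g,k}=1}
#'   \frac{1}{\sum_{l \in R(t_{g,k})} \exp(\hat\beta^T Z_{g,l})}}
#' a right-continuous non-decreasing step function, zero before the first
#' event time of the transition.
#'
#' @param fit an \code{"mscox"} fit.
#' @param data the dataset the model was fitted to.
#' @param g transition id.
#' @return data.frame with columns \code{time} (event times, ascending) and
#'   \code{cumhaz}; zero rows when the transition has no events.
#' @export
nelson_aalen_baseline <- function(fit, data, g) {
  G <- n_transitions(data$graph)
  if (!(g %in% seq_len(G))) stop("unknown transition: ", g)
  ev <- fit$events[fit$events$trans == g, , drop = FALSE]
  if (!nrow(ev)) return(data.frame(time = numeric(0), cumhaz = numeric(0)))
  ord <- order(ev$time)
  data.frame(time = ev$time[ord], cumhaz = cumsum(1 / ev$C[ord]))
}

#' @export
print.mscox <- function(x, ...) {
  cat("Multistate Cox fit:", length(x$beta), "coefficients,",
      nrow(x$events), "events,", x$iter, "Newton iterations\n")
  if (length(x$beta)) {
    print(data.frame(coef = x$beta, `exp(coef)` = exp(x$beta),
                     se = sqrt(diag(x$V)), check.names = FALSE))
  }
  cat("Log partial likelihood:", format(x$loglik), "\n")
  invisible(x)
}

#' @export
summary.mscox <- function(object, ...) {
  se <- sqrt(diag(object$V))
  z <- object$beta / se
  tab <- data.frame(coef = object$beta, `exp(coef)` = exp(object$beta),
                    se = se, z = z,
                    p = 2 * stats::pnorm(-abs(z)), check.names = FALSE)
  out <- list(coefficients = tab, loglik = object$loglik,
              n_events = nrow(object$events), iter = object$iter)
  class(out) <- "summary.mscox"
  out
}

#' @export
print.summary.mscox <- function(x, ...) {
  stats::printCoefmat(as.matrix(x$coefficients), P.values = TRUE,
                      has.Pvalue = TRUE)
  cat("Events:", x$n_events,
      " log partial likelihood:", format(x$loglik), "\n")
  invisible(x)
}
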