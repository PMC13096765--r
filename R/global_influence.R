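#' Patient contribution to the score
#'
#' Sums the patient's own event-record score contributions across all
#' transitions they were a member of,
#' \eqn{U_i(\hat\beta) = \sum_g U_{g,i}(\hat\beta) I_{gi}}. Fully censored
#' patients contribute the zero vector. The patient's presence in other
#' patients' risk sets is deliberately not part of \eqn{U_i}; that
#' approximation is exactly what one-step deletion trades against an exact
#' refit.
#'
#' @param fit an \code{"mscox"} fit.
#' @param data the dataset the model was fitted to.
#' @param i patient id (as in \code{data$records$id}).
#' @return numeric vector of length p.
#' @export
patient_score <- function(fit, data, i) {
  ids <- patient_ids(data)
  if (!(i %in% ids)) stop("unknown patient: ", i)
  rows <- fit$events$id == i
  if (!any(rows)) return(stats::setNames(numeric(length(fit$beta)),
                                         names(fit$beta)))
  colSums(fit$U_events[rows, , drop = FALSE])
}

# All patient scores at once: M x p matrix in patient_ids() order (internal).
patient_score_matrix <- function(fit, data) {
  ids <- patient_ids(data)
  p <- length(fit$beta)
  U <- matrix(0, length(ids), p, dimnames = list(ids, names(fit$beta)))
  if (nrow(fit$events)) {
    agg <- rowsum(fit$U_events, group = fit$events$id)
    U[rownames(agg), ] <- agg
  }
  U
}

#' One-step deleted estimate
#'
#' Single Newton-step approximation to the estimate obtained by deleting all
#' records of patient i: \eqn{\hat\beta_{(i)}^{(1)} = \hat\beta -
#' V U_i(\hat\beta)}.
#'
#' @inheritParams patient_score
#' @return numeric vector of length p.
#' @export
one_step_deletion <- function(fit, data, i) {
  Ui <- patient_score(fit, data, i)
  drop(fit$beta - fit$V %*% Ui)
}

#' Likelihood displacement for a deleted patient
#'
#' \eqn{LD_i = 2[\ell_P(\hat\beta) - \ell_P(\hat\beta_{(i)})]}, where the log
#' partial likelihood is always evaluated on the full data and
#' \eqn{\hat\beta_{(i)}} is either the exact refit without patient i
#' (\code{mode = "exact"}, warm-started at \eqn{\hat\beta}) or the one-step
#' approximation (\code{mode = "one_step"}). Non-negative by maximality of
#' \eqn{\hat\beta}.
#'
#' @inheritParams patient_score
#' @param mode \code{"one_step"} or \code{"exact"}.
#' @return scalar \eqn{LD_i \ge 0}.
#' @export
likelihood_displacement <- function(fit, data, i,
                                    mode = c("one_step", "exact")) {
  mode <- match.arg(mode)
  beta_i <- if (mode == "one_step") one_step_deletion(fit, data, i)
            else fit_mscox(drop_patients(data, i), init = fit$beta)$beta
  2 * (fit$loglik - log_partial_likelihood(beta_i, data))
}

#' One-step generalized Cook distance
#'
#' \eqn{D_i^{(1)} = U_i(\hat\beta)^T V U_i(\hat\beta) / p}: the quadratic-form
#' leverage of patient i on \eqn{\hat\beta}. Equals \eqn{|b_{ii}|/p} of the
#' patient-level (Scheme III) curvature matrix, so both diagnostics flag the
#' same patients.
#'
#' @inheritParams patient_score
#' @return scalar \eqn{D_i^{(1)} \ge 0}; zero exactly when \eqn{U_i = 0}.
#' @export
cook_distance_one_step <- function(fit, data, i) {
  p <- length(fit$beta)
  if (p == 0L) stop("Cook distance undefined for p = 0")
  Ui <- patient_score(fit, data, i)
  drop(crossprod(Ui, fit$V %*% Ui)) / p
}

#' Case-deletion (global) influence diagnostics for every patient
#'
#' Computes, per patient: the score contribution \eqn{U_i}, the one-step
#' generalized Cook distance \eqn{D_i^{(1)}}, the one-step likelihood
#' displacement \eqn{LD_i^{(1)}}, and optionally the exact deletion refit and
#' its displacement. Patients are flagged when \eqn{D_i^{(1)}} exceeds the
#' mean plus two sample standard deviations across patients (the same rule,
#' and by proportionality the same flags, as the patient-level curvature
#' index).
#'
#' @param fit an \code{"mscox"} fit.
#' @param data the dataset the model was fitted to.
#' @param exact if \code{TRUE}, additionally refit without each patient
#'   (independent per patient; warm-started at \eqn{\hat\beta}).
#' @return An object of class \code{"ms_global_influence"}: a data.frame with
#'   columns \code{id}, \code{cook1}, \code{ld1}, optional \code{ld_exact},
#'   \code{flag}; attributes \code{beta_onestep} (M x p) and, in exact mode,
#'   \code{beta_exact}.
#' @export
global_influence <- function(fit, data, exact = FALSE) {
  p <- length(fit$beta)
  if (p == 0L) stop("influence diagnostics undefined for p = 0")
  ids <- patient_ids(data)
  U <- patient_score_matrix(fit, data)
  VU <- U %*% fit$V
  cook1 <- rowSums(VU * U) / p
  beta1 <- sweep(-VU, 2L, fit$beta, `+`)   # row r: beta_hat - V U_i
  ld1 <- vapply(seq_along(ids), function(r)
    2 * (fit$loglik - log_partial_likelihood(beta1[r, ], data)), numeric(1))
  out <- data.frame(id = ids, cook1 = cook1, ld1 = ld1,
                    stringsAsFactors = FALSE)
  if (exact) {
    bex <- matrix(NA_real_, length(ids), p, dimnames = list(ids, names(fit$beta)))
    ldex <- numeric(length(ids))
    for (r in seq_along(ids)) {
      refit <- fit_mscox(drop_patients(data, ids[r]), init = fit$beta)
      bex[r, ] <- refit$beta
      ldex[r] <- 2 * (fit$loglik - log_partial_likelihood(refit$beta, data))
    }
    out$ld_exact <- ldex
    attr(out, "beta_exact") <- bex
  }
  cut <- mean(cook1) + 2 * stats::sd(cook1)
  out$flag <- cook1 > cut
  attr(out, "beta_onestep") <- beta1
  attr(out, "cutoff") <- cut
  class(out) <- c("ms_global_influence", "data.frame")
  out
}
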