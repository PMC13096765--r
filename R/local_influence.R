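# Case-weight local influence perturbs the weight of each component of the
# log partial likelihood and measures the curvature of the induced influence
# surface at the null perturbation. The schemes differ in what a "component"
# is: each (transition, patient) record (Scheme I, r = N), each transition
# (Scheme II, r = G), each patient (Scheme III, r = M).

# Column order for Scheme I: records sorted g-major, file order within g.
scheme1_column_order <- function(data) {
  rec <- data$records
  order(rec$trans)              # stable sort: keeps file order within g
}

new_delta <- function(scheme, Delta, omega0, labels) {
  structure(list(scheme = scheme, Delta = Delta, omega0 = omega0,
                 labels = labels, r = ncol(Delta)),
            class = "ms_delta")
}

#' @export
print.ms_delta <- function(x, ...) {
  cat("Perturbation Jacobian (", x$scheme, "): ", nrow(x$Delta), " x ",
      x$r, ", omega0 = ", x$omega0[1], "\n", sep = "")
  invisible(x)
}

#' Perturbation Jacobian, Scheme I (transition, patient)
#'
#' One column per long-format record, ordered transition-major (file order
#' within a transition). With the printed closed form, the column of event
#' record (g, k) is \eqn{v_{gk} U_{g,k}(\hat\beta)} with
#' \eqn{v_{gk} = 1 - \exp(Z_{g,k}^T\hat\beta) / \sum_{l \in R}
#' \exp(Z_{g,l}^T\hat\beta)}; censored records give zero columns (they carry
#' a weight but no likelihood term of their own).
#'
#' \code{form = "full"} instead returns the complete mixed partial of the
#' Scheme-I perturbed log partial likelihood, which adds the cross-risk-set
#' terms linking a record to every event whose risk set contains it. It is
#' provided as a labelled diagnostic for comparing the two derivations, not
#' as the canonical Jacobian.
#'
#' @param fit an \code{"mscox"} fit.
#' @param data the dataset the model was fitted to.
#' @param form \code{"printed"} (default) or \code{"full"}.
#' @return an \code{"ms_delta"} with a p x N matrix, null perturbation 1.
#' @export
delta_scheme1 <- function(fit, data, form = c("printed", "full")) {
  form <- match.arg(form)
  rec <- data$records
  ord <- scheme1_column_order(data)
  N <- nrow(rec)
  p <- length(fit$beta)
  col_of_row <- match(seq_len(N), ord)  # record row -> column index
  Delta <- matrix(0, p, N,
                  dimnames = list(names(fit$beta),
                                  paste0("g", rec$trans[ord], ":", rec$id[ord])))
  if (nrow(fit$events)) {
    cols <- col_of_row[fit$events$row]
    Delta[, cols] <- t(fit$U_events * fit$events$v)
  }
  if (form == "full" && p > 0) {
    Z <- data$design
    rows_by_g <- transition_rows(data)
    for (g in seq_along(rows_by_g)) {
      rows <- rows_by_g[[g]]
      if (!length(rows)) next
      evg <- fit$events[fit$events$trans == g, , drop = FALSE]
      if (!nrow(evg)) next
      Ug <- fit$U_events[fit$events$trans == g, , drop = FALSE]
      Q <- exp(drop(Z[rows, , drop = FALSE] %*% fit$beta))
      entry <- rec$entry[rows]; exit <- rec$time[rows]
      for (e in seq_len(nrow(evg))) {
        t_e <- evg$time[e]
        zstar <- Z[evg$row[e], ] - Ug[e, ]        # risk-set weighted mean
        members <- which(entry < t_e & t_e <= exit)
        for (m in members) {
          row_m <- rows[m]
          cross <- (Q[m] / evg$C[e]) * (Z[row_m, ] - zstar)
          Delta[, col_of_row[row_m]] <- Delta[, col_of_row[row_m]] -
            if (row_m == evg$row[e]) 0 else cross
        }
      }
    }
  }
  new_delta(paste0("scheme1_transition_patient",
                   if (form == "full") "_full" else ""),
            Delta, rep(1, N), colnames(Delta))
}

#' Perturbation Jacobian, Scheme II (transition)
#'
#' One column per transition: \eqn{\Delta_g = (N_g/N) \sum_{k: d_{g,k}=1}
#' U_{g,k}(\hat\beta)}, the mixed partial of the perturbed log partial
#' likelihood whose component weights are \eqn{1 + (N_g/N)\,\omega_g} (null
#' perturbation \eqn{\omega_0 = 0}).
#'
#' @inheritParams delta_scheme1
#' @return an \code{"ms_delta"} with a p x G matrix, null perturbation 0.
#' @export
delta_scheme2 <- function(fit, data) {
  d <- dims(data)
  p <- length(fit$beta)
  Delta <- matrix(0, p, d$G,
                  dimnames = list(names(fit$beta), paste0("g", seq_len(d$G))))
  if (nrow(fit$events)) {
    agg <- rowsum(fit$U_events, group = fit$events$trans)
    gset <- as.integer(rownames(agg))
    Delta[, gset] <- t(agg * (d$N_g[gset] / d$N))
  }
  new_delta("scheme2_transition", Delta, rep(0, d$G), colnames(Delta))
}

#' Perturbation Jacobian, Scheme III (patient)
#'
#' One column per patient: \eqn{\Delta_i = \sum_g U_{g,i}(\hat\beta) I_{gi}},
#' identical to the patient score [patient_score()] (null perturbation 1).
#' Columns sum to the total score, which vanishes at \eqn{\hat\beta}.
#'
#' @inheritParams delta_scheme1
#' @return an \code{"ms_delta"} with a p x M matrix, null perturbation 1.
#' @export
delta_scheme3 <- function(fit, data) {
  U <- patient_score_matrix(fit, data)
  new_delta("scheme3_patient", t(U), rep(1, nrow(U)), rownames(U))
}

#' Perturbed log partial likelihood for the case-weight schemes
#'
#' The perturbed objective whose mixed second derivative (in \eqn{\beta} and
#' \eqn{\omega}, at \eqn{\hat\beta} and the null perturbation) is the
#' corresponding Jacobian. Scheme I weights each record's likelihood
#' component \emph{and} its risk-set contribution by \eqn{\omega_{gk}};
#' Scheme II multiplies each event component by \eqn{1 + (N_g/N)\omega_g};
#' Scheme III multiplies each event component by the patient's weight
#' \eqn{\omega_k}.
#'
#' @param beta coefficient vector.
#' @param data an \code{"msdata"} with an expanded design.
#' @param scheme \code{"I"}, \code{"II"} or \code{"III"}.
#' @param omega perturbation vector: length N (Scheme I record order,
#'   transition-major), G, or M (patient order of [patient_ids()]).
#' @return scalar perturbed log partial likelihood.
#' @export
perturbed_log_partial_likelihood <- function(beta, data,
                                             scheme = c("I", "II", "III"),
                                             omega) {
  scheme <- match.arg(scheme)
  rec <- data$records
  Z <- data$design
  d <- dims(data)
  rows_by_g <- transition_rows(data)
  if (scheme == "I") {
    stopifnot(length(omega) == d$N)
    w_rec <- numeric(d$N)
    w_rec[scheme1_column_order(data)] <- omega
  } else if (scheme == "II") {
    stopifnot(length(omega) == d$G)
  } else {
    stopifnot(length(omega) == d$M)
    w_pat <- stats::setNames(omega, patient_ids(data))
  }
  ll <- 0
  for (g in seq_along(rows_by_g)) {
    rows <- rows_by_g[[g]]
    if (!length(rows)) next
    eta <- if (ncol(Z)) drop(Z[rows, , drop = FALSE] %*% beta)
           else numeric(length(rows))
    expeta <- exp(eta)
    entry <- rec$entry[rows]; exit <- rec$time[rows]
    for (e in which(rec$status[rows] == 1)) {
      at_risk <- entry < exit[e] & exit[e] <= exit
      lgk <- switch(scheme,
        I = {
          w <- w_rec[rows]
          w[e] * (eta[e] - log(sum(w[at_risk] * expeta[at_risk])))
        },
        II = (1 + d$N_g[g] / d$N * omega[g]) *
          (eta[e] - log(sum(expeta[at_risk]))),
        III = w_pat[[rec$id[rows[e]]]] *
          (eta[e] - log(sum(expeta[at_risk]))))
      ll <- ll + lgk
    }
  }
  ll
}

#' Conformal normal curvature of a perturbation scheme
#'
#' Builds \eqn{B = \Delta^T \ddot\ell_P^{-1} \Delta} by linear solves against
#' the Hessian (never an explicit inverse), and derives the index curvatures
#' \eqn{B_i = |b_{ii}/\mathrm{tr}(B)|}, the direction of maximal curvature
#' \code{hmax}, the flagging cutoff \eqn{\bar B + 2\,\mathrm{sd}(B)} (sample
#' standard deviation), and the flagged labels. \eqn{B} is negative
#' semidefinite, so the \eqn{B_i} sum to one whenever
#' \eqn{\mathrm{tr}(B) \ne 0}.
#'
#' @param fit an \code{"mscox"} fit.
#' @param delta an \code{"ms_delta"} from one of the \code{delta_scheme*}
#'   functions.
#' @return An object of class \code{"ms_curvature"}: \code{B}, \code{trace},
#'   \code{Bi} (named by the scheme's labels), \code{hmax}, \code{cutoff},
#'   \code{flagged} (labels with \eqn{B_i} strictly above the cutoff),
#'   \code{scheme}.
#' @export
curvature_matrix <- function(fit, delta) {
  stopifnot(inherits(delta, "ms_delta"))
  Delta <- delta$Delta
  r <- ncol(Delta)
  if (nrow(Delta) == 0L) stop("curvature undefined for p = 0")
  # hessian is negative definite; B = Delta' H^{-1} Delta
  B <- crossprod(Delta, solve(fit$hessian, Delta))
  B <- (B + t(B)) / 2
  dimnames(B) <- list(delta$labels, delta$labels)
  trB <- sum(diag(B))
  if (trB == 0) {
    warning("tr(B) = 0: degenerate perturbation, all curvatures reported 0")
    Bi <- stats::setNames(numeric(r), delta$labels)
    hm <- stats::setNames(numeric(r), delta$labels)
    res <- list(B = B, trace = 0, Bi = Bi, hmax = hm,
                cutoff = NA_real_, flagged = character(0),
                scheme = delta$scheme)
    class(res) <- "ms_curvature"
    return(res)
  }
  Bi <- abs(diag(B) / trB)
  ei <- eigen(B, symmetric = TRUE)
  k <- which.max(abs(ei$values))            # ties: lowest index wins
  hm <- ei$vectors[, k]
  hm <- hm / sqrt(sum(hm^2))
  if (hm[which.max(abs(hm))] < 0) hm <- -hm
  names(hm) <- delta$labels
  cutoff <- mean(Bi) + 2 * stats::sd(Bi)
  res <- list(B = B, trace = trB, Bi = Bi, hmax = hm, cutoff = cutoff,
              flagged = delta$labels[!is.na(cutoff) & Bi > cutoff],
              scheme = delta$scheme)
  class(res) <- "ms_curvature"
  res
}

#' @export
print.ms_curvature <- function(x, ...) {
  cat("Conformal normal curvature (", x$scheme, "): r = ", length(x$Bi),
      ", tr(B) = ", format(x$trace), "\n", sep = "")
  cat("Cutoff (mean + 2 sd):", format(x$cutoff), "\n")
  cat("Flagged:", if (length(x$flagged)) paste(x$flagged, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Conformal normal curvature in a given unit direction
#'
#' \eqn{B_h = |h^T B h| / |\mathrm{tr}(B)|}, bounded in \eqn{[0, 1]} for any
#' unit direction h; at a standard basis vector it equals the corresponding
#' index curvature \eqn{B_i}.
#'
#' @param result an \code{"ms_curvature"}.
#' @param h direction vector with unit Euclidean norm (checked to 1e-12).
#' @return scalar in \eqn{[0, 1]}.
#' @export
directional_curvature <- function(result, h) {
  stopifnot(inherits(result, "ms_curvature"))
  if (abs(sum(h^2) - 1) > 1e-12) stop("h must have unit Euclidean norm")
  if (result$trace == 0) stop("tr(B) = 0: directional curvature undefined")
  abs(drop(crossprod(h, result$B %*% h))) / abs(result$trace)
}

#' Conformal normal curvature along many random unit directions
#'
#' Draws uniform random unit directions and evaluates
#' \eqn{B_h = |h^T B h| / |\mathrm{tr}(B)|} for each without ever forming the
#' r x r matrix B: with \eqn{y = \Delta h}, \eqn{h^T B h =
#' y^T \ddot\ell_P^{-1} y}, so the work per direction is O(r p). Intended for
#' stress-testing the \eqn{0 \le B_h \le 1} bound when r is large (e.g.
#' Scheme I, one direction component per record).
#'
#' @param fit an \code{"mscox"} fit.
#' @param delta an \code{"ms_delta"}.
#' @param ndirs number of random unit directions.
#' @param chunk directions evaluated per block (memory knob).
#' @return numeric vector of length \code{ndirs} of curvatures in
#'   \eqn{[0, 1]}; draws from the current RNG stream.
#' @export
random_direction_curvatures <- function(fit, delta, ndirs = 10000L,
                                        chunk = 500L) {
  Delta <- delta$Delta
  r <- ncol(Delta)
  Hinv_Delta <- solve(fit$hessian, Delta)
  trB <- sum(Delta * Hinv_Delta)
  if (trB == 0) stop("tr(B) = 0: directional curvature undefined")
  out <- numeric(ndirs)
  done <- 0L
  while (done < ndirs) {
    m <- min(chunk, ndirs - done)
    Hm <- matrix(stats::rnorm(r * m), r, m)
    Hm <- sweep(Hm, 2L, sqrt(colSums(Hm^2)), `/`)
    Y <- Delta %*% Hm                       # p x m
    out[done + seq_len(m)] <- abs(colSums(Y * solve(fit$hessian, Y)))
    done <- done + m
  }
  out / abs(trB)
}

#' Direction of maximal local influence
#'
#' The unit eigenvector of B for the eigenvalue of largest magnitude, sign
#' fixed so the entry of largest magnitude is positive. The index plot of
#' \code{abs(hmax(result))} reveals which components drive the most
#' influential joint perturbation.
#'
#' @param result an \code{"ms_curvature"}.
#' @return named unit vector of length r.
#' @export
hmax <- function(result) {
  stopifnot(inherits(result, "ms_curvature"))
  result$hmax
}

#' Flag potentially influential components
#'
#' Components whose index curvature exceeds the cutoff
#' \eqn{\bar B + 2\,\mathrm{sd}(B)} (strict inequality; sample standard
#' deviation over the r index curvatures).
#'
#' @param result an \code{"ms_curvature"}.
#' @return character vector of flagged labels (possibly empty).
#' @export
flag_influential <- function(result) {
  stopifnot(inherits(result, "ms_curvature"))
  if (length(result$Bi) < 2L)
    stop("flagging needs at least 2 components (sd undefined)")
  result$flagged
}

#' Local influence analysis for one or more perturbation schemes
#'
#' Convenience wrapper building the Jacobian and curvature for each requested
#' scheme.
#'
#' @param fit an \code{"mscox"} fit.
#' @param data the dataset the model was fitted to.
#' @param schemes subset of \code{c("I", "II", "III")}.
#' @return named list of \code{"ms_curvature"} objects.
#' @export
local_influence <- function(fit, data, schemes = c("I", "II", "III")) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  out <- list()
  for (s in schemes) {
    delta <- switch(s, I = delta_scheme1(fit, data),
                    II = delta_scheme2(fit, data),
                    III = delta_scheme3(fit, data))
    out[[s]] <- curvature_matrix(fit, delta)
  }
  out
}
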