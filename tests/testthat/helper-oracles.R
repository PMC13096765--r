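# Shared fixtures and independent numerical oracles.

# Central finite-difference gradient of a scalar- or vector-valued f.
num_grad <- function(f, x, eps = 1e-6) {
  cols <- lapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- eps
    (f(x + e) - f(x - e)) / (2 * eps)
  })
  out <- do.call(cbind, cols)
  if (nrow(out) == 1L) drop(out) else out
}

# Hand-built single-transition dataset (Tstart = 0, all clock-reset).
toy_single <- function(times, status, x, mapping = list(x = 1L)) {
  n <- length(times)
  rec <- data.frame(id = sprintf("t%02d", seq_len(n)), from = 1L, to = 2L,
                    trans = 1L, Tstart = 0, Tstop = times, status = status)
  d <- msdata(rec, transition_graph(2L, rbind(c(1L, 2L)), absorbing = 2L),
              covariates = data.frame(x = x))
  expand_covariates(d, mapping)
}

# Random small multistate dataset (n <= 30, p <= 3, G <= 4) with its own
# seed; returns the dataset and a non-null beta at which to test derivatives.
rand_small_data <- function(seed) {
  set.seed(seed)
  kind <- sample(3L, 1L)
  if (kind == 1L) {          # single transition
    graph <- transition_graph(2L, rbind(c(1L, 2L)), absorbing = 2L)
    rates <- 0.05
    effects <- list(x = list(covariate = "x", transitions = 1L,
                             beta = stats::runif(1, -0.5, 0.5)))
  } else if (kind == 2L) {   # illness-death, 3 transitions
    graph <- transition_graph(3L, rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)),
                              absorbing = 3L)
    rates <- c(0.04, 0.02, 0.08)
    effects <- list(
      x12 = list(covariate = "x", transitions = 1:2,
                 beta = stats::runif(1, -0.5, 0.5)),
      w = list(covariate = "w", transitions = 1:3,
               beta = stats::runif(1, -0.5, 0.5)))
  } else {                   # 4 transitions, competing + progression
    graph <- transition_graph(4L, rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L),
                                        c(2L, 4L)), absorbing = 3:4)
    rates <- c(0.05, 0.02, 0.06, 0.04)
    effects <- list(
      x = list(covariate = "x", transitions = 1:2,
               beta = stats::runif(1, -0.5, 0.5)),
      w = list(covariate = "w", transitions = c(1L, 3L),
               beta = stats::runif(1, -0.5, 0.5)),
      v = list(covariate = "v", transitions = 4L,
               beta = stats::runif(1, -0.5, 0.5)))
  }
  cfg <- sim_config(
    n = sample(10:30, 1L), graph = graph, rates = rates, effects = effects,
    covariates = function(n) data.frame(x = stats::rnorm(n),
                                        w = stats::rbinom(n, 1L, 0.5),
                                        v = stats::runif(n)),
    censoring = c(20, 120))
  sim <- simulate_cohort(cfg, seed = seed + 7L)
  # retry until at least two events (derivatives of a flat surface are dull)
  tries <- 0L
  while (sum(sim$data$records$status) < 2L && tries < 10L) {
    tries <- tries + 1L
    sim <- simulate_cohort(cfg, seed = seed + 7L + 100L * tries)
  }
  list(data = sim$data,
       beta = stats::runif(ncol(sim$data$design), -0.4, 0.4))
}

# Mixed partial d2 L(beta|omega) / d beta d omega_j for schemes II and III.
# L is linear in omega for these schemes, so the omega-derivative is an exact
# unit difference; only beta is differenced numerically.
fd_mixed_delta_linear <- function(fit, data, scheme, eps = 1e-5) {
  d <- dims(data)
  r <- switch(scheme, II = d$G, III = d$M)
  omega0 <- switch(scheme, II = rep(0, d$G), III = rep(1, d$M))
  cols <- lapply(seq_len(r), function(j) {
    gj <- function(b)
      perturbed_log_partial_likelihood(b, data, scheme,
                                       replace(omega0, j, omega0[j] + 1)) -
        perturbed_log_partial_likelihood(b, data, scheme, omega0)
    num_grad(gj, fit$beta, eps)
  })
  matrix(unlist(cols), nrow = length(fit$beta))
}

# Four-point cross difference for Scheme I (omega enters the risk sets, so
# the perturbed objective is not linear in omega).
fd_mixed_delta_scheme1 <- function(fit, data, eps = 3e-4) {
  d <- dims(data)
  omega0 <- rep(1, d$N)
  p <- length(fit$beta)
  out <- matrix(0, p, d$N)
  for (j in seq_len(d$N)) {
    for (k in seq_len(p)) {
      f <- function(sb, so) {
        b <- fit$beta; b[k] <- b[k] + sb * eps
        perturbed_log_partial_likelihood(b, data, "I",
                                         replace(omega0, j, 1 + so * eps))
      }
      out[k, j] <- (f(1, 1) - f(1, -1) - f(-1, 1) + f(-1, -1)) / (4 * eps^2)
    }
  }
  out
}

# Matrix infinity-norm relative error.
rel_err <- function(a, b) max(abs(a - b)) / max(abs(b))
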