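test_that("risk sets follow the (entry, exit] convention with ties included", {
  d <- toy_single(times = c(2, 5, 9), status = c(1, 1, 0), x = c(0, 1, 2))
  expect_setequal(risk_set(d, 1, 5), 2:3)
  expect_setequal(risk_set(d, 1, 2), 1:3)
  expect_length(risk_set(d, 1, 10), 0)           # beyond all exits
  expect_error(risk_set(d, 2, 5), "unknown transition")
  # two tied event times: each event's risk set contains the other
  d4 <- toy_single(times = c(2, 5, 5, 9), status = c(0, 1, 1, 0),
                   x = c(0, 1, 0, 1))
  rs <- risk_set(d4, 1, 5)
  expect_setequal(rs, 2:4)    # hand enumeration: exits {5, 5, 9} >= 5
})

test_that("log partial likelihood matches closed forms and brute force", {
  # beta = 0: exponentials collapse to risk-set sizes
  d <- toy_single(times = c(2, 5, 9), status = c(1, 1, 0), x = c(0, 1, 2))
  expect_equal(log_partial_likelihood(0, d), -(log(3) + log(2)))
  # single event alone in its risk set contributes 0 for any beta
  d1 <- toy_single(times = 3, status = 1, x = 1.7)
  expect_equal(log_partial_likelihood(2.3, d1), 0)
  # brute-force product of partial-likelihood factors, direct enumeration
  times <- c(3, 6, 10); status <- c(1, 1, 1); x <- c(0.5, -1, 2)
  d3 <- toy_single(times, status, x)
  beta <- 0.8
  brute <- 0
  for (k in which(status == 1)) {
    rs <- which(times >= times[k])
    brute <- brute + log(exp(beta * x[k]) / sum(exp(beta * x[rs])))
  }
  expect_equal(log_partial_likelihood(beta, d3), brute)
  # event with an empty risk set signals broken data preparation
  broken <- toy_single(times = c(2, 5), status = c(0, 1), x = c(1, 2))
  broken$records$entry[2] <- 5     # corrupt: entry not before the event time
  expect_error(log_partial_likelihood(0, broken), "empty risk set")
})

test_that("analytic score matches closed forms and finite differences", {
  d <- toy_single(times = c(2, 5, 9), status = c(1, 0, 0), x = c(3, 1, 2))
  # beta = 0: U = Z_event - arithmetic mean of risk-set covariates
  s <- pl_score(0, d)
  expect_equal(drop(s$per_event), 3 - mean(c(3, 1, 2)), ignore_attr = TRUE)
  # risk set of size one: zero contribution
  d1 <- toy_single(times = 3, status = 1, x = 1.7)
  expect_equal(drop(pl_score(1.1, d1)$per_event), 0, ignore_attr = TRUE)
  # finite-difference oracle on random small datasets
  for (seed in c(11, 23, 35)) {
    rd <- rand_small_data(seed)
    ga <- pl_score(rd$beta, rd$data)$total
    gfd <- num_grad(function(b) log_partial_likelihood(b, rd$data), rd$beta)
    expect_lt(rel_err(ga, gfd), 1e-6)
  }
})

test_that("analytic Hessian matches hand values and finite differences", {
  # beta = 0, one event, risk set {Z=0, Z=1}: contribution -1/4
  d <- toy_single(times = c(1, 2), status = c(1, 0), x = c(0, 1))
  expect_equal(drop(pl_hessian(0, d)), -0.25)
  # all covariates equal within the risk set: zero contribution
  dc <- toy_single(times = c(1, 2, 3), status = c(1, 0, 0), x = c(2, 2, 2))
  expect_equal(drop(pl_hessian(0.7, dc)), 0)
  for (seed in c(12, 24)) {
    rd <- rand_small_data(seed)
    Ha <- pl_hessian(rd$beta, rd$data)
    Hfd <- num_grad(function(b) pl_score(b, rd$data)$total, rd$beta)
    Hfd <- matrix(Hfd, length(rd$beta))
    expect_lt(rel_err(Ha, Hfd), 1e-5)
    expect_equal(Ha, t(Ha), tolerance = 1e-10)
    expect_true(all(eigen((Ha + t(Ha)) / 2, only.values = TRUE)$values < 1e-8))
  }
})

test_that("with G = 1 the fit reproduces a standard Cox model (Breslow ties)", {
  skip_if_not_installed("survival")
  g1 <- transition_graph(2L, rbind(c(1L, 2L)), absorbing = 2L)
  cfg <- sim_config(
    n = 60, graph = g1, rates = 0.02,
    effects = list(x = list(covariate = "x", transitions = 1L, beta = 0.7),
                   w = list(covariate = "w", transitions = 1L, beta = -0.4)),
    covariates = function(n) data.frame(x = stats::rnorm(n),
                                        w = stats::rbinom(n, 1L, 0.4)),
    censoring = c(20, 80))
  sim <- simulate_cohort(cfg, seed = 3)
  fit <- fit_mscox(sim$data)
  df <- cbind(sim$data$records, sim$data$covariates)
  cph <- survival::coxph(
    survival::Surv(time, status) ~ x + w, data = df, ties = "breslow",
    control = survival::coxph.control(eps = 1e-12, toler.chol = 1e-13, iter.max = 100))
  expect_equal(unname(fit$beta), unname(coef(cph)), tolerance = 1e-6)
  expect_equal(fit$loglik, cph$loglik[2], tolerance = 1e-6)
  expect_equal(unname(fit$V), unname(vcov(cph)), tolerance = 1e-6)
  bh <- survival::basehaz(cph, centered = FALSE)
  mine <- nelson_aalen_baseline(fit, sim$data, 1)
  merged <- merge(mine, bh, by = "time")
  expect_equal(merged$cumhaz, merged$hazard, tolerance = 1e-6)
})

test_that("the fitted score vanishes and V is symmetric positive definite", {
  sim <- simulate_cohort(sim_config(n = 120), seed = 8)
  fit <- fit_mscox(sim$data)
  expect_true(fit$converged)
  dec <- drop(crossprod(fit$score, solve(-fit$hessian, fit$score)))
  expect_lt(dec, 1e-8)
  expect_equal(fit$V, t(fit$V))
  expect_true(all(eigen(fit$V, only.values = TRUE)$values > 0))
})

test_that("p = 0 yields the null model with loglik -sum log |R|", {
  sim <- simulate_cohort(sim_config(n = 20), seed = 13)
  null_d <- expand_covariates(sim$data, list())
  fit <- fit_mscox(null_d)
  expect_length(fit$beta, 0)
  hand <- 0
  rec <- null_d$records
  for (r in which(rec$status == 1))
    hand <- hand - log(length(risk_set(null_d, rec$trans[r], rec$time[r])))
  expect_equal(fit$loglik, hand)
})

test_that("Nelson-Aalen baselines are non-decreasing step functions", {
  # beta = 0, one event among 4 at risk: jump of 1/4
  d <- toy_single(times = c(1, 2, 3, 4), status = c(1, 0, 0, 0),
                  x = c(0, 0, 0, 0))
  fit <- fit_mscox(expand_covariates(d, list()))
  expect_equal(fit$baseline[[1]],
               data.frame(time = 1, cumhaz = 0.25))
  # three events: hand-summed increments
  d3 <- toy_single(times = c(1, 2, 3), status = c(1, 1, 1), x = c(0, 0, 0))
  f3 <- fit_mscox(expand_covariates(d3, list()))
  expect_equal(f3$baseline[[1]]$cumhaz, cumsum(c(1 / 3, 1 / 2, 1)))
  # a transition with no events is identically zero
  sim <- simulate_cohort(sim_config(n = 15), seed = 2)
  fit <- fit_mscox(sim$data)
  for (g in 1:9) {
    bl <- fit$baseline[[g]]
    expect_true(all(diff(bl$cumhaz) > 0) || nrow(bl) <= 1)
    if (!any(fit$events$trans == g)) expect_equal(nrow(bl), 0L)
  }
})

test_that("log partial likelihood is concave along random segments", {
  rd <- rand_small_data(77)
  set.seed(1)
  for (rep in 1:5) {
    b1 <- stats::runif(length(rd$beta), -1, 1)
    b2 <- stats::runif(length(rd$beta), -1, 1)
    lam <- stats::runif(1)
    mid <- lam * b1 + (1 - lam) * b2
    expect_gte(log_partial_likelihood(mid, rd$data) + 1e-10,
               lam * log_partial_likelihood(b1, rd$data) +
                 (1 - lam) * log_partial_likelihood(b2, rd$data))
  }
})

test_that("permuting record order changes nothing but labels", {
  sim <- simulate_cohort(sim_config(n = 50), seed = 21)
  d <- sim$data
  set.seed(99)
  perm <- sample(nrow(d$records))
  d2 <- d
  d2$records <- d$records[perm, , drop = FALSE]
  rownames(d2$records) <- NULL
  d2$covariates <- d$covariates[perm, , drop = FALSE]
  rownames(d2$covariates) <- NULL
  d2 <- expand_covariates(d2, d$covariate_map)
  f1 <- fit_mscox(d)
  f2 <- fit_mscox(d2)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-9)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-9)
  cv1 <- curvature_matrix(f1, delta_scheme3(f1, d))
  cv2 <- curvature_matrix(f2, delta_scheme3(f2, d2))
  ids <- patient_ids(d)
  expect_equal(cv1$Bi[ids], cv2$Bi[ids], tolerance = 1e-9)
})
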