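# Minimal curvature inputs with a prescribed Hessian let the index
# curvatures be computed by direct arithmetic: B = Delta' H^{-1} Delta. With
# H = -I and Delta a single row d, B = -d'd and B_i = d_i^2 / sum(d^2).
fake_curvature <- function(Delta, H = -diag(nrow(Delta))) {
  if (is.null(dim(Delta))) Delta <- matrix(Delta, 1)
  delta <- structure(list(scheme = "arith", Delta = Delta,
                          omega0 = rep(1, ncol(Delta)),
                          labels = paste0("u", seq_len(ncol(Delta))),
                          r = ncol(Delta)),
                     class = "ms_delta")
  curvature_matrix(list(hessian = H), delta)
}

test_that("scheme I columns are v * U on events and zero on censored records", {
  d <- toy_single(times = c(2, 4, 7, 9), status = c(1, 1, 0, 0),
                  x = c(1.2, -0.3, 0.8, 0))
  fit <- fit_mscox(d)
  D1 <- delta_scheme1(fit, d)
  expect_equal(dim(D1$Delta), c(1L, 4L))
  expect_equal(D1$omega0, rep(1, 4))
  # hand computation at beta-hat for the two events
  b <- fit$beta; x <- d$covariates$x
  for (e in 1:2) {
    rs <- which(c(2, 4, 7, 9) >= c(2, 4)[e])
    q <- exp(b * x[rs]); C <- sum(q)
    v <- 1 - exp(b * x[e]) / C
    u <- x[e] - sum(q * x[rs]) / C
    expect_equal(D1$Delta[1, e], unname(v * u), tolerance = 1e-12)
  }
  expect_equal(D1$Delta[1, 3:4], c(0, 0), ignore_attr = TRUE)
  # an event alone in its risk set gives v = 0 and U = 0: a zero column
  d1b <- toy_single(times = c(3, 1), status = c(1, 1), x = c(2, 1))
  f1b <- fit_mscox(d1b)
  D <- delta_scheme1(f1b, d1b)$Delta
  expect_equal(D[1, 1], 0)    # t=3 event: risk set is only itself
})

test_that("scheme II and III Jacobians match finite-difference mixed partials", {
  rd <- rand_small_data(41)
  fit <- fit_mscox(rd$data)
  D2 <- delta_scheme2(fit, rd$data)
  expect_lt(rel_err(D2$Delta, fd_mixed_delta_linear(fit, rd$data, "II")),
            1e-6)
  D3 <- delta_scheme3(fit, rd$data)
  expect_lt(rel_err(D3$Delta, fd_mixed_delta_linear(fit, rd$data, "III")),
            1e-6)
  # scheme III columns sum to the score at the optimum: the zero vector
  expect_lt(max(abs(rowSums(D3$Delta))), 1e-6)
  # scheme II with G = 1 degenerates to the single zero column
  g1 <- rand_small_data(11)     # seed 11 draws the single-transition graph
  if (dims(g1$data)$G == 1L) {
    f1 <- fit_mscox(g1$data)
    expect_lt(max(abs(delta_scheme2(f1, g1$data)$Delta)), 1e-6)
  }
  # a transition with no events gives a zero column
  noev <- which(tabulate(fit$events$trans, dims(rd$data)$G) == 0)
  for (g in noev) expect_equal(unname(D2$Delta[, g]),
                               rep(0, length(fit$beta)))
})

test_that("the printed scheme I form keeps own-record terms; the full mixed partial matches finite differences", {
  rd <- rand_small_data(53)
  fit <- fit_mscox(rd$data)
  Dfull <- delta_scheme1(fit, rd$data, form = "full")
  Dfd <- fd_mixed_delta_scheme1(fit, rd$data)
  expect_lt(rel_err(Dfull$Delta, Dfd), 1e-4)
  # printed form equals the full form's own-record part on event columns
  Dp <- delta_scheme1(fit, rd$data)$Delta
  expect_false(isTRUE(all.equal(Dp, Dfull$Delta)))  # cross terms do differ
})

test_that("curvature matrix on a 2x2 toy matches direct arithmetic", {
  # rank-1: B = -[3, r3; r3, 1], Bi = {3/4, 1/4}, hmax along (r3, 1)/2
  cv <- fake_curvature(c(sqrt(3), 1))
  expect_equal(unname(diag(cv$B)), c(-3, -1))
  expect_equal(unname(cv$Bi), c(0.75, 0.25))
  expect_equal(sum(cv$Bi), 1)
  expect_equal(unname(cv$hmax), c(sqrt(3), 1) / 2)
  # full-rank diagonal: B = diag(-3, -1), hmax is the first basis vector
  cvd <- fake_curvature(diag(c(sqrt(3), 1)))
  expect_equal(unname(cvd$B), diag(c(-3, -1)))
  expect_equal(unname(cvd$hmax), c(1, 0))
  # degenerate Delta = 0
  expect_warning(cv0 <- fake_curvature(c(0, 0)), "tr\\(B\\) = 0")
  expect_equal(unname(cv0$Bi), c(0, 0))
})

test_that("directional curvature is bounded, matches B_i at basis vectors, peaks at hmax", {
  sim <- simulate_cohort(sim_config(n = 60), seed = 31)
  fit <- fit_mscox(sim$data)
  for (delta in list(delta_scheme1(fit, sim$data),
                     delta_scheme2(fit, sim$data),
                     delta_scheme3(fit, sim$data))) {
    cv <- curvature_matrix(fit, delta)
    r <- length(cv$Bi)
    e7 <- replace(numeric(r), min(7, r), 1)
    expect_equal(directional_curvature(cv, e7), cv$Bi[[min(7, r)]])
    set.seed(2)
    bh <- random_direction_curvatures(fit, delta, ndirs = 200)
    expect_true(all(bh >= 0 & bh <= 1 + 1e-12))
    expect_equal(sum(cv$Bi), 1)
    # hmax attains at least the best sampled random direction
    expect_gte(directional_curvature(cv, hmax(cv)) + 1e-10, max(bh))
    expect_equal(sum(hmax(cv)^2), 1)
  }
  cv <- curvature_matrix(fit, delta_scheme3(fit, sim$data))
  expect_error(directional_curvature(cv, rep(1, length(cv$Bi))), "unit")
})

test_that("eigen tie-breaks are deterministic and the sign convention holds", {
  cv <- fake_curvature(c(1, 1))     # B = -[1 1; 1 1]: eigenvalues -2, 0
  expect_equal(unname(cv$hmax), c(1, 1) / sqrt(2))
  cv2 <- fake_curvature(c(1, 1))
  expect_identical(cv$hmax, cv2$hmax)
  expect_gt(cv$hmax[which.max(abs(cv$hmax))], 0)
  # duplicate extreme eigenvalue (B = -I): deterministic repeated choice
  tie1 <- fake_curvature(diag(2))
  tie2 <- fake_curvature(diag(2))
  expect_identical(tie1$hmax, tie2$hmax)
  expect_equal(sum(tie1$hmax^2), 1)
})

test_that("the mean + 2 sd flag rule follows direct arithmetic", {
  # Bi = {0.1, 0.1, 0.8}: cutoff 1/3 + 2*sd > 0.8, so nothing is flagged
  cv <- fake_curvature(sqrt(c(0.1, 0.1, 0.8)))
  expect_equal(unname(cv$Bi), c(0.1, 0.1, 0.8))
  expect_equal(cv$cutoff, mean(cv$Bi) + 2 * stats::sd(cv$Bi))
  expect_equal(flag_influential(cv), character(0))
  # all equal: sd = 0, strict inequality flags nothing
  cveq <- fake_curvature(rep(0.5, 4))
  expect_equal(flag_influential(cveq), character(0))
  # one dominant component among 100 is flagged
  d <- sqrt(c(0.5, rep(0.5 / 99, 99)))
  cvbig <- fake_curvature(d)
  expect_equal(flag_influential(cvbig), "u1")
  # r = 1: sd undefined
  cv1 <- fake_curvature(2)
  expect_error(flag_influential(cv1), "at least 2")
})

test_that("Remark-1: scheme III curvature is proportional to the one-step Cook distance", {
  sim <- simulate_cohort(sim_config(n = 80), seed = 19)
  fit <- fit_mscox(sim$data)
  cv <- curvature_matrix(fit, delta_scheme3(fit, sim$data))
  gi <- global_influence(fit, sim$data)
  p <- length(fit$beta)
  bii <- abs(diag(cv$B))
  expect_equal(unname(p * gi$cook1), unname(bii[gi$id]), tolerance = 1e-10)
  expect_equal(order(-gi$cook1), order(-cv$Bi[gi$id]))
  # identical flag sets
  expect_setequal(gi$id[gi$flag], flag_influential(cv))
})

test_that("index curvatures are invariant to covariate rescaling", {
  sim <- simulate_cohort(sim_config(n = 70), seed = 23)
  fit <- fit_mscox(sim$data)
  scaled <- sim$data
  scaled$covariates$size <- scaled$covariates$size / 100   # mm -> dm
  scaled <- expand_covariates(scaled, scaled$covariate_map)
  fit2 <- fit_mscox(scaled)
  for (s in c("I", "II", "III")) {
    cv1 <- local_influence(fit, sim$data, s)[[s]]
    cv2 <- local_influence(fit2, scaled, s)[[s]]
    expect_lt(max(abs(cv1$Bi - cv2$Bi)), 1e-8)
  }
})
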