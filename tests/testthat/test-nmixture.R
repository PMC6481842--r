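test_that("likelihood matches closed forms in pinned cases", {
  spec <- nmix_spec()
  # perfect detection pins N at the observed count
  pinned <- count_history(matrix(c(2, 2, 2), 1, 3))
  nll <- nmixture_negloglik(c(log(1), 20, -30), spec, pinned)
  expect_equal(exp(-nll), dpois(2, 1), tolerance = 1e-6)

  # all-zero counts, lambda = 1, p = 0.5, phi ~ 0:
  # L = sum_n e^-1 (0.125)^n / n! = exp(-0.875)
  zeros <- count_history(matrix(0, 1, 3))
  nll0 <- nmixture_negloglik(c(0, 0, -30), spec, zeros)
  expect_equal(exp(-nll0), exp(-0.875), tolerance = 1e-6)

  # phi -> 1 makes an all-zero site certain
  nll1 <- nmixture_negloglik(c(0, 0, 30), spec, zeros)
  expect_equal(exp(-nll1), 1, tolerance = 1e-6)
})

test_that("likelihood agrees with exhaustive latent-N enumeration", {
  set.seed(202)
  spec <- nmix_spec()
  for (rep in 1:30) {
    n <- sample(1:3, 1)
    J <- sample(1:3, 1)
    cm <- matrix(sample(0:4, n * J, replace = TRUE), n, J)
    if (J > 1 && rep %% 3 == 0) cm[1, 1] <- NA
    if (any(rowSums(!is.na(cm)) == 0)) next
    ch <- count_history(cm)
    par <- c(runif(1, -0.5, 1.5), runif(1, -1, 1), runif(1, -2, 1))
    expect_equal(
      nmixture_negloglik(par, spec, ch),
      oracle_nmixture_negloglik(par[1], par[2], par[3], cm),
      tolerance = 1e-6
    )
  }
})

test_that("the truncation bound is guarded and the likelihood stable to it", {
  ch <- count_history(matrix(c(3, 1, 2), 1, 3))
  spec <- nmix_spec()
  expect_error(nmixture_negloglik(c(0, 0, 0), spec, ch, K_max = 2),
               "largest observed count")
  par <- c(log(2), qlogis(0.4), qlogis(0.2))
  v1 <- nmixture_negloglik(par, spec, ch, K_max = 103)
  v2 <- nmixture_negloglik(par, spec, ch, K_max = 206)
  expect_lt(abs(v1 - v2), 1e-8)

  # with phi = 0 the zero-inflated likelihood reduces to the plain Poisson
  # N-mixture: the mixture weight on N = 0 is exactly dpois(0, lambda)
  plain <- nmixture_negloglik(c(log(2), qlogis(0.4), -50), spec, ch)
  no_phi <- nmixture_negloglik(c(log(2), qlogis(0.4)),
                               nmix_spec(zero_inflated = FALSE), ch)
  expect_equal(plain, no_phi, tolerance = 1e-8)
})

test_that("small-instance fits match the enumeration oracle at the optimum", {
  set.seed(303)
  sim <- simulate_nmixture_data(10, 3, lambda = 3, p = 0.6, phi = 0.1)
  fit <- fit_nmixture(sim$counts)
  par <- c(fit$beta_lambda[[1]], fit$alpha_p[[1]], fit$phi_logit)
  expect_equal(-fit$loglik,
               oracle_nmixture_negloglik(par[1], par[2], par[3], sim$counts$c),
               tolerance = 1e-6)
  # and the optimum beats a crude grid around the truth
  grid <- expand.grid(l = seq(0.5, 2, 0.1), p = seq(-1.5, 1.5, 0.2),
                      f = seq(-4, 1, 0.5))
  vals <- mapply(function(l, p, f) {
    oracle_nmixture_negloglik(l, p, f, sim$counts$c, N_big = 60)
  }, grid$l, grid$p, grid$f)
  expect_lte(-fit$loglik, min(vals) + 1e-3)
})

test_that("parameters are recovered within 15% on simulated data", {
  set.seed(404)
  sim <- simulate_nmixture_data(500, 3, lambda = 5, p = 0.4, phi = 0.2)
  fit <- fit_nmixture(sim$counts)
  expect_true(fit$converged)
  expect_lt(abs(exp(fit$beta_lambda[[1]]) - 5) / 5, 0.15)
  expect_lt(abs(plogis(fit$alpha_p[[1]]) - 0.4) / 0.4, 0.15)
  expect_lt(abs(fit$phi - 0.2) / 0.2, 0.25)
})

test_that("with perfect detection the fitted mean tracks the site maxima", {
  set.seed(505)
  N <- rpois(400, 6)
  cm <- matrix(rep(N, 3), 400, 3) # p = 1: every survey counts everyone
  # detection sits on the boundary by construction, so the fit warns
  expect_warning(
    fit <- fit_nmixture(count_history(cm),
                        spec = nmix_spec(zero_inflated = FALSE)),
    "boundary")
  expect_lt(abs(exp(fit$beta_lambda[[1]]) - mean(apply(cm, 1, max))), 0.25)
  expect_gt(plogis(fit$alpha_p[[1]]), 0.95)
})

test_that("site density averages across models and divides by volume", {
  mk_fit <- function(lam_int) {
    structure(list(beta_lambda = c(`(Intercept)` = lam_int),
                   alpha_p = c(`(Intercept)` = 0), phi = 0,
                   spec = nmix_spec(zero_inflated = FALSE)),
              class = "nmix_fit")
  }
  bundle <- covariate_bundle(tibble::tibble(site = c("a", "b")))
  vols <- c(a = 5000, b = 1000)

  one <- site_density(list(mk_fit(log(10))), 1, bundle, vols)
  expect_equal(one$density, c(10 / 5000, 10 / 1000))
  expect_equal(one$density[1], 0.002)

  twin <- site_density(list(mk_fit(log(10)), mk_fit(log(10))), c(0.3, 0.7),
                       bundle, vols)
  expect_equal(twin$expected_abundance, one$expected_abundance)

  first_only <- site_density(list(mk_fit(log(10)), mk_fit(log(99))), c(1, 0),
                             bundle, vols)
  expect_equal(first_only$expected_abundance, one$expected_abundance)

  expect_error(site_density(list(mk_fit(0)), 1, bundle, c(a = 5000)),
               "missing volume")
})

test_that("tidy and glance expose the fitted surface", {
  set.seed(7)
  sim <- simulate_nmixture_data(80, 3, lambda = 4, p = 0.5, phi = 0.15)
  fit <- fit_nmixture(sim$counts)
  td <- tidy(fit)
  expect_equal(td$component, c("lambda", "p", "phi"))
  gl <- glance(fit)
  expect_equal(gl$K, 3L)
  expect_equal(gl$AICc, aicc(fit$loglik, 3, 80))
  expect_true(gl$phi >= 0 && gl$phi <= 1)
})
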