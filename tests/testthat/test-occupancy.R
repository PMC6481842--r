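test_that("likelihood matches hand-computed two-term mixtures", {
  spec <- occu_spec()
  one_det <- detection_history(matrix(c(1, 0), 1, 2))
  # psi = p = 0.5: L = 0.5 * 0.5 * 0.5
  expect_equal(occupancy_negloglik(c(0, 0), spec, one_det), -log(0.125),
               tolerance = 1e-12)

  none <- detection_history(matrix(c(0, 0), 1, 2))
  # L = psi * (1-p)^2 + (1 - psi) = 0.125 + 0.5
  expect_equal(exp(-occupancy_negloglik(c(0, 0), spec, none)), 0.625,
               tolerance = 1e-12)

  certain <- detection_history(matrix(c(1, 1), 1, 2))
  fixed <- occu_spec(fix_psi = TRUE)
  expect_equal(occupancy_negloglik(c(30), fixed, certain), 0, tolerance = 1e-8)
})

test_that("likelihood agrees with latent-state enumeration on small instances", {
  set.seed(101)
  spec0 <- occu_spec()
  # exhaustive over every {0,1} history up to 2 x 2
  for (n in 1:2) {
    for (J in 1:2) {
      grids <- expand.grid(rep(list(c(0, 1)), n * J))
      for (g in seq_len(nrow(grids))) {
        y <- matrix(as.numeric(grids[g, ]), n, J)
        h <- detection_history(y)
        for (par in list(c(0, 0), c(0.7, -0.4), c(-1.2, 1.5))) {
          expect_equal(
            occupancy_negloglik(par, spec0, h),
            oracle_occupancy_negloglik(par, character(), character(), h$y),
            tolerance = 1e-9
          )
        }
      }
    }
  }
  # random 3 x 3 instances with missing values and covariates on both parts
  for (rep in 1:40) {
    y <- matrix(sample(c(0, 1, NA), 9, replace = TRUE, prob = c(.4, .4, .2)),
                3, 3)
    if (any(rowSums(!is.na(y)) == 0)) next
    h <- detection_history(y)
    X_site <- cbind(forest = rnorm(3))
    rownames(X_site) <- h$site_ids
    depth <- matrix(rnorm(9), 3, 3, dimnames = list(h$site_ids, NULL))
    bundle <- covariate_bundle(
      tibble::tibble(site = h$site_ids, forest = X_site[, "forest"]),
      list(depth = depth))
    spec <- occu_spec(psi = "forest", p = "depth")
    par <- rnorm(4)
    expect_equal(
      occupancy_negloglik(par, spec, h, bundle),
      oracle_occupancy_negloglik(par, "forest", "depth", h$y,
                                 X_site = X_site,
                                 p_mats = list(depth = bundle$obs_tables$depth)),
      tolerance = 1e-9
    )
  }
})

test_that("a site with every occasion missing contributes a factor of one", {
  spec <- occu_spec()
  with_site <- detection_history(rbind(c(1, 0), c(NA, 0)))
  # drop the all-missing-except row manually: compare against a history where
  # the second site has both occasions missing (allowed only via direct call)
  y <- rbind(c(1, 0), c(NA, NA))
  h <- structure(list(site_ids = c("a", "b"), y = y),
                 class = "detection_history")
  only_first <- detection_history(rbind(c(1, 0)))
  for (par in list(c(0, 0), c(1, -1))) {
    expect_equal(occupancy_negloglik(par, spec, h),
                 occupancy_negloglik(par, spec, only_first), tolerance = 1e-12)
  }
})

test_that("site order does not change the likelihood or fit", {
  set.seed(5)
  sim <- simulate_occupancy_data(40, 3, 0.5, 0.6)
  perm <- detection_history(sim$history$y[sample(40), ])
  spec <- occu_spec()
  expect_equal(occupancy_negloglik(c(0.2, -0.3), spec, sim$history),
               occupancy_negloglik(c(0.2, -0.3), spec, perm), tolerance = 1e-10)
  f1 <- fit_occupancy(sim$history)
  f2 <- fit_occupancy(perm)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("with occupancy fixed and one occasion the MLE is the raw frequency", {
  y <- matrix(c(1, 1, 0, 1, 0), 5, 1)
  fit <- fit_occupancy(detection_history(y), spec = occu_spec(fix_psi = TRUE))
  expect_equal(plogis(fit$alpha[[1]]), 0.6, tolerance = 1e-5)
  expect_equal(fit$K, 1L)
  expect_equal(length(fit$beta), 0L)
})

test_that("optimum matches a dense grid search on a 20-site instance", {
  set.seed(31)
  sim <- simulate_occupancy_data(20, 3, 0.6, 0.5)
  fit <- fit_occupancy(sim$history)
  grid <- expand.grid(lpsi = seq(-4, 4, by = 0.02), lp = seq(-4, 4, by = 0.02))
  nll <- ednaoccu:::occu_nll_factory(occu_spec(), sim$history, NULL)
  vals <- mapply(function(a, b) nll(c(a, b)), grid$lpsi, grid$lp)
  expect_lte(-fit$loglik, min(vals) + 1e-3)
})

test_that("intercept-only parameters are recovered from simulated data", {
  set.seed(77)
  sim <- simulate_occupancy_data(1000, 5, psi = 0.6, p = 0.7)
  fit <- fit_occupancy(sim$history)
  expect_true(fit$converged)
  expect_lt(abs(plogis(fit$beta[[1]]) - 0.6), 0.05)
  expect_lt(abs(plogis(fit$alpha[[1]]) - 0.7), 0.04)
  td <- tidy(fit)
  expect_equal(td$term, rep("(Intercept)", 2))
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(fit)
  expect_equal(gl$AICc, aicc(fit$loglik, 2, 1000))
})

test_that("an all-detected history is flagged as a boundary fit", {
  h <- detection_history(matrix(1, 10, 3))
  expect_warning(fit <- fit_occupancy(h), "boundary")
  expect_true(fit$boundary)
  expect_gt(plogis(fit$beta[[1]]), 0.99)
  expect_gt(plogis(fit$alpha[[1]]), 0.99)
})

test_that("occupancy predictions back-transform with delta-method intervals", {
  set.seed(12)
  sim <- simulate_occupancy_data(300, 4, 0.5, 0.6)
  fit <- fit_occupancy(sim$history)
  pr <- predict_occupancy(fit)
  expect_true(pr$lower > 0 && pr$upper < 1)
  expect_true(pr$lower < pr$estimate && pr$estimate < pr$upper)
  collapsed <- predict_occupancy(fit, z = 0)
  expect_equal(collapsed$lower, collapsed$estimate)
  expect_equal(collapsed$upper, collapsed$estimate)

  flat <- fit
  flat$beta <- c(`(Intercept)` = 0)
  expect_equal(predict_occupancy(flat, z = 0)$estimate, 0.5)
})

test_that("detection curves are monotone in a single active covariate", {
  fit <- structure(
    list(beta = c(`(Intercept)` = 0),
         alpha = c(`(Intercept)` = -0.5, density = 1.2, temp = -0.8),
         vcov = NULL, spec = occu_spec(psi = character(),
                                       p = c("density", "temp"))),
    class = "occu_fit")
  up <- predict_detection(fit, tibble::tibble(density = seq(-2, 2, 0.5)))
  expect_true(all(diff(up$estimate) > 0))
  down <- predict_detection(fit, tibble::tibble(temp = seq(-2, 2, 0.5)))
  expect_true(all(diff(down$estimate) < 0))
  flat <- predict_detection(fit, tibble::tibble(nothing = seq(-2, 2, 0.5)))
  expect_equal(unique(round(flat$estimate, 12)), plogis(-0.5))
  expect_s3_class(autoplot(up), "ggplot")
})
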