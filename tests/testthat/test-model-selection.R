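test_that("candidate enumeration counts match binomial arithmetic", {
  obs5 <- paste0("o", 1:5)
  site5 <- paste0("s", 1:5)
  stage1 <- enumerate_candidates(obs5, stage = "observation")
  expect_equal(nrow(stage1), 1 + 5 + 10 + 10) # sizes 0..3
  expect_equal(anyDuplicated(stage1$model), 0L)

  stage2 <- enumerate_candidates(c("o1", "o2"), site5, stage = "full")
  expect_equal(nrow(stage2), 1 + 5 + 10) # site sizes 0..2
  expect_true(all(purrr::map_lgl(stage2$obs_covs,
                                 ~ identical(.x, c("o1", "o2")))))

  empty_site <- enumerate_candidates(c("o1"), character(), stage = "full")
  expect_equal(nrow(empty_site), 1)
  expect_equal(empty_site$site_covs[[1]], character())
})

test_that("aicc reproduces its definition and limiting behaviour", {
  # closed form at small n
  expect_equal(aicc(-10, 2, 10), 20 + 4 + 12 / 7)
  # correction vanishes as n grows
  aic <- -2 * (-10) + 2 * 2
  expect_lt(aicc(-10, 2, 1e7) - aic, 1e-5)
  expect_error(aicc(-10, 5, 6), "n > K \\+ 1")
})

test_that("akaike weights follow the closed form and its invariances", {
  expect_equal(akaike_weights(42), 1)
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  # translation invariance
  set.seed(5)
  a <- runif(8, 50, 90)
  expect_equal(akaike_weights(a), akaike_weights(a + 17.3), tolerance = 1e-12)
  expect_equal(sum(akaike_weights(a)), 1, tolerance = 1e-12)
})

test_that("ranking sorts by AICc with deterministic tie-breaks", {
  tbl <- tibble::tibble(
    model = c("b_model", "a_model", "small_K", "big_K"),
    loglik = c(-10, -10, -12, -11),
    K = c(3L, 3L, 2L, 4L),
    n = 30L
  )
  r <- rank_models(tbl)
  expect_equal(r$delta[1], 0)
  expect_equal(sum(r$weight), 1, tolerance = 1e-10)
  # identical (loglik, K): alphabetical tie-break
  tied <- r$model[r$loglik == -10]
  expect_equal(tied, sort(tied))
  expect_s3_class(r, "ranked_models")

  expect_equal(nrow(top_set(r, 0)), sum(r$delta == 0))
  expect_gte(nrow(top_set(r, 4)), 1)
})

test_that("model averaging obeys its boundary cases", {
  same <- tibble::tibble(estimate = rep(0.3, 3), se = rep(0.1, 3),
                         weight = c(0.5, 0.3, 0.2))
  avg <- model_average(same, link = "logit")
  expect_equal(avg$link_estimate, 0.3)
  expect_equal(avg$estimate, plogis(0.3))

  degenerate <- tibble::tibble(estimate = c(0.1, 5), se = c(0.2, 0.2),
                               weight = c(1, 0))
  expect_equal(model_average(degenerate)$link_estimate, 0.1)

  two <- tibble::tibble(estimate = qlogis(c(0.4, 0.6)), se = c(0.1, 0.1),
                        weight = c(0.5, 0.5))
  est <- model_average(two)$estimate
  expect_gt(est, 0.4)
  expect_lt(est, 0.6)

  # unconverged models are dropped with renormalized weights
  mixed <- tibble::tibble(estimate = c(0.2, 9), se = c(0.1, 0.1),
                          weight = c(0.6, 0.4), converged = c(TRUE, FALSE))
  expect_warning(out <- model_average(mixed), "dropped")
  expect_equal(out$link_estimate, 0.2)
})

test_that("unconditional interval widens with between-model spread", {
  agree <- tibble::tibble(estimate = c(0, 0), se = c(0.2, 0.2),
                          weight = c(0.5, 0.5))
  disagree <- tibble::tibble(estimate = c(-1, 1), se = c(0.2, 0.2),
                             weight = c(0.5, 0.5))
  expect_gt(model_average(disagree)$link_se, model_average(agree)$link_se)
})
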