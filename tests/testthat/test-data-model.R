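test_that("histories validate their entries and keep site identity", {
  m <- rbind(site_a = c(1, 0, NA), site_b = c(0, 0, 0))
  dh <- detection_history(m)
  expect_equal(dim(dh), c(2L, 3L))
  expect_equal(dh$site_ids, c("site_a", "site_b"))

  expect_error(detection_history(rbind(c(2, 0))), "0, 1, or missing")
  expect_error(count_history(rbind(c(-1, 0))), "non-negative")
  expect_error(count_history(rbind(c(1.5, 0))), "non-negative")
  expect_error(detection_history(rbind(c(NA, NA))), "non-missing")

  long <- tibble::tibble(site = rep(c("a", "b"), each = 2),
                         occasion = rep(1:2, 2), value = c(1, 0, 0, 0))
  expect_equal(detection_history(long)$y, detection_history(
    rbind(a = c(1, 0), b = c(0, 0)))$y)
})

test_that("standardize centers, scales, records, and inverts", {
  bundle <- covariate_bundle(
    tibble::tibble(site = c("a", "b", "c"), forest = c(1, 2, 3)))
  std <- standardize(bundle, "forest")
  expect_equal(std$site_table$forest, c(-1, 0, 1))
  expect_equal(std$scaling$mean, 2)
  expect_equal(std$scaling$sd, 1)

  # idempotent: a second pass is a no-op
  expect_equal(standardize(std, "forest")$site_table$forest,
               std$site_table$forest, tolerance = 1e-12)

  set.seed(11)
  big <- covariate_bundle(
    tibble::tibble(site = as.character(1:100), x = rnorm(100, 50, 9)))
  sb <- standardize(big, "x")
  expect_lt(abs(mean(sb$site_table$x)), 1e-10)
  expect_lt(abs(sd(sb$site_table$x) - 1), 1e-10)
  back <- unstandardize(sb)
  expect_equal(back$site_table$x, big$site_table$x, tolerance = 1e-10)

  expect_error(standardize(covariate_bundle(
    tibble::tibble(site = c("a", "b"), flat = c(1, 1))), "flat"),
    "zero variance")
})

test_that("observation covariates standardize across the whole matrix", {
  obs <- matrix(1:12, 4, 3, dimnames = list(paste0("s", 1:4), NULL))
  bundle <- covariate_bundle(tibble::tibble(site = paste0("s", 1:4)),
                             list(depth = obs))
  std <- standardize(bundle, "depth")
  v <- as.vector(std$obs_tables$depth)
  expect_lt(abs(mean(v)), 1e-12)
  expect_equal(sd(v), 1, tolerance = 1e-12)
  expect_equal(unname(unstandardize(std)$obs_tables$depth), unname(obs),
               tolerance = 1e-10)
})

test_that("spearman screen flags perfectly correlated pairs and no others", {
  set.seed(42)
  x <- rnorm(200)
  bundle <- covariate_bundle(tibble::tibble(
    site = as.character(1:200), a = x, b = x, c = -x, u = runif(200)))
  flagged <- suppressWarnings(spearman_screen(bundle, threshold = 0.7))
  pair <- function(p, q) {
    any(flagged$covariate_1 == p & flagged$covariate_2 == q)
  }
  expect_true(pair("a", "b"))
  expect_equal(flagged$rho[flagged$covariate_1 == "a" &
                           flagged$covariate_2 == "b"], 1)
  expect_equal(flagged$rho[flagged$covariate_1 == "a" &
                           flagged$covariate_2 == "c"], -1)
  expect_false(any(flagged$covariate_1 == "u" | flagged$covariate_2 == "u"))

  # two independent uniforms almost surely fall below 0.7 at n = 200
  ind <- covariate_bundle(tibble::tibble(
    site = as.character(1:200), u1 = runif(200), u2 = runif(200)))
  expect_equal(nrow(spearman_screen(ind, 0.7)), 0)
})

test_that("spearman screen is invariant to monotone transforms", {
  set.seed(7)
  x <- rnorm(50)
  y <- x + rnorm(50, sd = 0.3)
  b1 <- covariate_bundle(tibble::tibble(site = as.character(1:50),
                                        p = x, q = y))
  b2 <- covariate_bundle(tibble::tibble(site = as.character(1:50),
                                        p = exp(x), q = y^3 + 5 * y))
  f1 <- suppressWarnings(spearman_screen(b1, threshold = 0))
  f2 <- suppressWarnings(spearman_screen(b2, threshold = 0))
  expect_equal(f1$rho, f2$rho, tolerance = 1e-12)
})

test_that("naive occupancy counts sites with any detection", {
  m <- rbind(c(1, 0, NA), c(0, 0, 0), c(NA, 1, 1))
  nv <- naive_occupancy(detection_history(m))
  expect_equal(nv$n_detected, 2)
  expect_equal(nv$proportion, 2 / 3)

  expect_equal(naive_occupancy(detection_history(matrix(0, 4, 2)))$proportion, 0)

  # invariant to occasion order and to an appended all-missing occasion
  # (appended to a history that already has data in every row)
  perm <- naive_occupancy(detection_history(m[, c(3, 1, 2)]))
  expect_equal(perm$proportion, nv$proportion)
  aug <- naive_occupancy(detection_history(cbind(m, NA)))
  expect_equal(aug$proportion, nv$proportion)
})

test_that("survey tables round-trip through CSV unchanged", {
  dir <- withr::local_tempdir()
  sc <- wood_turtle_scenario(n_sites = 12, seed = 3)
  sim <- simulate_study(sc)
  paths <- write_survey_tables(sim$ves, sim$bundle, dir, counts = sim$counts)
  back <- read_survey_tables(paths[["detection"]], paths[["covariates"]],
                             paths[["counts"]], paths[["obs_covariates"]])
  expect_equal(unname(back$detection$y), unname(sim$ves$y))
  expect_equal(back$detection$site_ids, sim$ves$site_ids)
  expect_equal(unname(back$counts$c), unname(sim$counts$c))
  expect_equal(back$covariates$site_table, sim$bundle$site_table)
  for (nm in names(sim$bundle$obs_tables)) {
    expect_equal(unname(back$covariates$obs_tables[[nm]]),
                 unname(sim$bundle$obs_tables[[nm]]), tolerance = 1e-12)
  }
})

test_that("site sets must agree across files", {
  dir <- withr::local_tempdir()
  sim <- simulate_study(wood_turtle_scenario(n_sites = 6, seed = 4))
  paths <- write_survey_tables(sim$ves, sim$bundle, dir)
  covs <- readr::read_csv(paths[["covariates"]], show_col_types = FALSE)
  covs$site[1] <- "somewhere_else"
  readr::write_csv(covs, paths[["covariates"]])
  expect_error(read_survey_tables(paths[["detection"]], paths[["covariates"]]),
               "site sets differ")
})

test_that("the bundled synthetic wood turtle fixture matches its margins", {
  ves <- read_fixture_history("synthetic_wood_turtle_ves.csv")
  edna <- read_fixture_history("synthetic_wood_turtle_edna.csv")
  expect_equal(dim(ves), c(37L, 3L))
  expect_equal(naive_occupancy(ves)$n_detected, 17)
  expect_equal(naive_occupancy(edna)$n_detected, 16)
})
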