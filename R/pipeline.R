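#' Subset survey objects to a set of sites
#'
#' Restricts a [detection_history()], [count_history()], or
#' [covariate_bundle()] to the given sites, preserving the order in `sites`.
#'
#' @param x the object to subset.
#' @param sites character vector of site identifiers.
#' @return an object of the same class.
#' @export
filter_sites <- function(x, sites) UseMethod("filter_sites")

#' @export
filter_sites.detection_history <- function(x, sites) {
  idx <- match(sites, x$site_ids)
  if (any(is.na(idx))) abort("unknown site identifier(s)")
  detection_history(x$y[idx, , drop = FALSE])
}

#' @export
filter_sites.count_history <- function(x, sites) {
  idx <- match(sites, x$site_ids)
  if (any(is.na(idx))) abort("unknown site identifier(s)")
  count_history(x$c[idx, , drop = FALSE])
}

#' @export
filter_sites.covariate_bundle <- function(x, sites) {
  idx <- match(sites, x$site_table$site)
  if (any(is.na(idx))) abort("unknown site identifier(s)")
  x$site_table <- x$site_table[idx, ]
  x$obs_tables <- purrr::map(x$obs_tables, ~ .x[idx, , drop = FALSE])
  x
}

detected_sites <- function(history) {
  history$site_ids[apply(history$y, 1, function(r) any(r == 1, na.rm = TRUE))]
}

# fit every candidate row; returns fits plus a ranked_models table with a
# converged column (failed fits enter with -Inf log-likelihood and are
# excluded from averaging downstream)
fit_occu_candidates <- function(history, bundle, candidates, fix_psi = FALSE) {
  n <- nrow(history$y)
  fits <- purrr::pmap(candidates, function(model, site_covs, obs_covs) {
    spec <- occu_spec(psi = if (fix_psi) character() else site_covs,
                      p = obs_covs, fix_psi = fix_psi)
    tryCatch(suppressWarnings(fit_occupancy(history, bundle, spec)),
             error = function(e) NULL)
  })
  names(fits) <- candidates$model
  tab <- tibble::tibble(
    model = candidates$model,
    loglik = purrr::map_dbl(fits, ~ if (is.null(.x)) -Inf else .x$loglik),
    K = purrr::map_int(fits, ~ if (is.null(.x)) NA_integer_ else .x$K),
    n = n,
    converged = purrr::map_lgl(fits, ~ !is.null(.x) && .x$converged),
    boundary = purrr::map_lgl(fits, ~ !is.null(.x) && isTRUE(.x$boundary))
  )
  tab$K[is.na(tab$K)] <- 0L
  list(fits = fits, ranked = rank_models(tab))
}

fit_nmix_candidates <- function(counts, bundle, candidates) {
  n <- nrow(counts$c)
  fits <- purrr::pmap(candidates, function(model, site_covs, obs_covs) {
    spec <- nmix_spec(lambda = site_covs, p = obs_covs)
    tryCatch(suppressWarnings(fit_nmixture(counts, bundle, spec)),
             error = function(e) NULL)
  })
  names(fits) <- candidates$model
  tab <- tibble::tibble(
    model = candidates$model,
    loglik = purrr::map_dbl(fits, ~ if (is.null(.x)) -Inf else .x$loglik),
    K = purrr::map_int(fits, ~ if (is.null(.x)) NA_integer_ else .x$K),
    n = n,
    converged = purrr::map_lgl(fits, ~ !is.null(.x) && .x$converged),
    boundary = purrr::map_lgl(fits, ~ !is.null(.x) && isTRUE(.x$boundary))
  )
  tab$K[is.na(tab$K)] <- 0L
  list(fits = fits, ranked = rank_models(tab))
}

# model-averaged back-transformed estimate at covariate means; boundary fits
# are excluded like unconverged ones (their link-scale estimates diverge and
# would dominate the average), unless nothing else is available
average_component <- function(fits, ranked, component, z) {
  preds <- purrr::map(ranked$model, function(m) {
    f <- fits[[m]]
    if (is.null(f)) return(c(eta = NA_real_, se = NA_real_))
    fit_link_prediction(f, component, list())
  })
  usable <- ranked$converged
  if ("boundary" %in% names(ranked) && any(usable & !ranked$boundary)) {
    usable <- usable & !ranked$boundary
  }
  model_average(
    tibble::tibble(
      estimate = purrr::map_dbl(preds, "eta"),
      se = purrr::map_dbl(preds, "se"),
      weight = ranked$weight,
      converged = usable
    ),
    link = "logit", z = z
  )
}

#' VES occupancy stage: two-stage selection and model averaging
#'
#' Stage one screens observation covariates (every combination of up to
#' `max_obs`) on the known-occupied subset with occupancy fixed to one; the
#' covariates of the stage-one best model are then carried, fixed, into stage
#' two, which crosses them with every site-covariate combination of up to
#' `max_site` on the full data. Occupancy and detection are model averaged
#' over the full stage-two candidate set at covariate means.
#'
#' @param history VES [detection_history()].
#' @param bundle standardized [covariate_bundle()].
#' @param obs_covariates,site_covariates candidate covariate names.
#' @param max_obs,max_site per-model covariate caps (3 and 2).
#' @param z interval multiplier.
#' @return list with `stage1` and `ranked` ([rank_models()] tables), `fits`,
#'   `influential_obs`, `occupancy` and `detection` (model-averaged one-row
#'   tibbles).
#' @export
run_ves_stage <- function(history, bundle, obs_covariates, site_covariates,
                          max_obs = 3, max_site = 2, z = 1.96) {
  occ_sites <- detected_sites(history)
  if (!length(occ_sites)) abort("no detections: cannot screen observation covariates")
  s1_cands <- enumerate_candidates(obs_covariates, stage = "observation",
                                   max_obs = max_obs)
  s1 <- fit_occu_candidates(filter_sites(history, occ_sites),
                            filter_sites(bundle, occ_sites),
                            s1_cands, fix_psi = TRUE)
  influential <- s1$ranked$model[1]
  influential_obs <- s1_cands$obs_covs[[match(influential, s1_cands$model)]]

  s2_cands <- enumerate_candidates(influential_obs, site_covariates,
                                   stage = "full", max_site = max_site)
  s2 <- fit_occu_candidates(history, bundle, s2_cands, fix_psi = FALSE)

  list(
    stage1 = s1$ranked,
    ranked = s2$ranked,
    fits = s2$fits,
    influential_obs = influential_obs,
    occupancy = average_component(s2$fits, s2$ranked, "psi", z),
    detection = average_component(s2$fits, s2$ranked, "p", z)
  )
}

#' Abundance stage: N-mixture selection and model-averaged density
#'
#' Fits zero-inflated-Poisson N-mixture candidates to the counts at occupied
#' sites with the same two-stage protocol as [run_ves_stage()] (observation
#' covariates first, abundance held constant), then model averages per-site
#' expected abundance over the full stage-two set and converts to density
#' through per-site stream volumes. Densities are predicted for every site in
#' the bundle; sites outside the fitting subset are flagged `imputed` (their
#' density comes from the covariate model, not their own counts).
#'
#' @param counts [count_history()] over all sites.
#' @param bundle standardized [covariate_bundle()].
#' @param occupied_sites sites used for fitting (VES-occupied).
#' @param obs_covariates,site_covariates candidate covariate names.
#' @param volumes named per-site stream volume (m^3/km).
#' @param max_obs,max_site per-model covariate caps.
#' @param z interval multiplier.
#' @return list with `stage1`, `ranked`, `fits`, `influential_obs`,
#'   `detection` (model-averaged individual detection), and `density_table`
#'   (`site`, `expected_abundance`, `volume`, `density`, `imputed`).
#' @export
run_abundance_stage <- function(counts, bundle, occupied_sites,
                                obs_covariates, site_covariates, volumes,
                                max_obs = 3, max_site = 2, z = 1.96) {
  if (!length(occupied_sites)) abort("occupied subset is empty")
  if (length(occupied_sites) < 5) {
    warn("very few occupied sites: abundance estimates will be unstable")
  }
  sub_counts <- filter_sites(counts, occupied_sites)
  sub_bundle <- filter_sites(bundle, occupied_sites)
  s1_cands <- enumerate_candidates(obs_covariates, stage = "observation",
                                   max_obs = max_obs)
  s1 <- fit_nmix_candidates(sub_counts, sub_bundle, s1_cands)
  influential <- s1$ranked$model[1]
  influential_obs <- s1_cands$obs_covs[[match(influential, s1_cands$model)]]

  s2_cands <- enumerate_candidates(influential_obs, site_covariates,
                                   stage = "full", max_site = max_site)
  s2 <- fit_nmix_candidates(sub_counts, sub_bundle, s2_cands)

  ok <- s2$ranked$converged & !s2$ranked$boundary
  if (!any(ok)) ok <- s2$ranked$converged
  fits_ok <- s2$fits[s2$ranked$model[ok]]
  w_ok <- s2$ranked$weight[ok]
  density_table <- site_density(fits_ok, w_ok, bundle, volumes)
  density_table$imputed <- !density_table$site %in% occupied_sites

  detection <- model_average(
    tibble::tibble(
      estimate = purrr::map_dbl(s2$ranked$model, function(m) {
        f <- s2$fits[[m]]
        if (is.null(f)) NA_real_ else unname(f$alpha_p[1])
      }),
      se = purrr::map_dbl(s2$ranked$model, function(m) {
        f <- s2$fits[[m]]
        if (is.null(f) || is.null(f$vcov)) return(NA_real_)
        i <- length(f$beta_lambda) + 1L
        v <- f$vcov[i, i]
        if (is.finite(v) && v >= 0) sqrt(v) else NA_real_
      }),
      weight = s2$ranked$weight,
      converged = ok
    ),
    link = "logit", z = z
  )

  list(stage1 = s1$ranked, ranked = s2$ranked, fits = s2$fits,
       influential_obs = influential_obs,
       detection = detection,
       density_table = density_table)
}

#' eDNA stage: all-sites and occupied-sites detection models
#'
#' The all-sites model keeps the site covariates identified as influential by
#' the VES stage fixed in every candidate and evaluates every observation
#' covariate combination of up to `max_obs`. The occupied-sites (OS) variant
#' restricts to the occupied subset, holds occupancy at one, and adds
#' model-averaged turtle density (standardized within the subset) to the
#' observation covariate pool.
#'
#' @param history eDNA [detection_history()] (filter-replicate positives).
#' @param bundle standardized [covariate_bundle()].
#' @param site_covariates site covariates fixed in all-sites models (default
#'   `"forest"`).
#' @param obs_covariates observation covariate candidates.
#' @param density_table output of [run_abundance_stage()] (used for the OS
#'   density covariate); `NULL` to skip the density covariate.
#' @param occupied_sites the occupied subset for the OS model (VES-confirmed
#'   plus eDNA-positive sites).
#' @param max_obs per-model observation covariate cap.
#' @param z interval multiplier.
#' @return list with `ranked` (all-sites), `os_ranked`, `fits`, `os_fits`,
#'   `occupancy` and `detection` (all-sites averages), `os_detection`.
#' @export
run_edna_stage <- function(history, bundle, site_covariates = "forest",
                           obs_covariates, density_table = NULL,
                           occupied_sites, max_obs = 3, z = 1.96) {
  all_cands <- enumerate_candidates(obs_covariates, stage = "observation",
                                    max_obs = max_obs)
  all_cands$site_covs <- purrr::map(seq_len(nrow(all_cands)),
                                    ~ site_covariates)
  lab <- function(covs) if (length(covs)) paste(covs, collapse = " + ") else "1"
  all_cands$model <- purrr::map2_chr(
    all_cands$site_covs, all_cands$obs_covs,
    ~ sprintf("state(%s), p(%s)", lab(.x), lab(.y))
  )
  all_fit <- fit_occu_candidates(history, bundle, all_cands, fix_psi = FALSE)

  os_pool <- obs_covariates
  os_bundle <- filter_sites(bundle, occupied_sites)
  if (!is.null(density_table)) {
    dens <- density_table$density[match(occupied_sites, density_table$site)]
    if (any(is.na(dens))) abort("density table does not cover all occupied sites")
    os_bundle$site_table$density <- dens
    os_bundle <- standardize(os_bundle, "density")
    os_pool <- c("density", os_pool)
  }
  os_cands <- enumerate_candidates(os_pool, stage = "observation",
                                   max_obs = max_obs)
  os_fit <- fit_occu_candidates(filter_sites(history, occupied_sites),
                                os_bundle, os_cands, fix_psi = TRUE)

  list(
    ranked = all_fit$ranked,
    os_ranked = os_fit$ranked,
    fits = all_fit$fits,
    os_fits = os_fit$fits,
    occupancy = average_component(all_fit$fits, all_fit$ranked, "psi", z),
    detection = average_component(all_fit$fits, all_fit$ranked, "p", z),
    os_detection = average_component(os_fit$fits, os_fit$ranked, "p", z)
  )
}

#' Cross-method summary table
#'
#' Builds the method-comparison summary: per method the naive occupancy (with
#' a +/-1 SE Wald band), the model-averaged detection probability, and the
#' model-averaged occupancy probability, plus the g-test of independence on
#' the site-level cross-classification of the two methods.
#'
#' @param ves_history the VES detection history.
#' @param edna_history the eDNA detection history, or `NULL` for a VES-only
#'   summary.
#' @param ves_stage result of [run_ves_stage()].
#' @param edna_stage result of [run_edna_stage()] (or `NULL`).
#' @return list with `summary` (tibble: `method`, `quantity`, `estimate`,
#'   `lower`, `upper`) and, when both methods are present, `independence`
#'   (the [g_test()] row) and `cross_table`.
#' @export
summarize_methods <- function(ves_history, edna_history = NULL,
                              ves_stage, edna_stage = NULL) {
  band <- function(x) x[, c("estimate", "lower", "upper")]
  naive_row <- function(h) {
    nv <- naive_occupancy(h)
    ci <- proportion_interval(nv$n_detected, nv$n_sites, z = 1)
    ci[, c("estimate", "lower", "upper")]
  }
  row <- function(method, quantity, values) {
    dplyr::bind_cols(tibble::tibble(method = method, quantity = quantity),
                     values)
  }
  summary <- dplyr::bind_rows(
    row("ves", "naive_occupancy", naive_row(ves_history)),
    row("ves", "detection", band(ves_stage$detection)),
    row("ves", "occupancy", band(ves_stage$occupancy))
  )
  if (is.null(edna_history) || is.null(edna_stage)) {
    return(list(summary = summary, independence = NULL, cross_table = NULL))
  }
  summary <- dplyr::bind_rows(
    summary,
    row("edna", "naive_occupancy", naive_row(edna_history)),
    row("edna", "detection", band(edna_stage$detection)),
    row("edna", "occupancy", band(edna_stage$occupancy))
  )
  tab <- method_cross_table(ves_history, edna_history, c("ves", "edna"))
  list(summary = summary, independence = g_test(tab), cross_table = tab)
}

#' Run the full paired VES/eDNA inference chain
#'
#' Orchestrates the four stages on aligned survey objects: (1) VES two-stage
#' occupancy selection and averaging; (2) N-mixture abundance and density at
#' VES-occupied sites; (3) eDNA all-sites and occupied-sites detection models
#' (density chained in as an OS covariate, imputed from the covariate model
#' for eDNA-only sites); (4) the cross-method summary. Covariates are
#' standardized once up front. Deterministic given its inputs.
#'
#' @param ves,edna [detection_history()] objects.
#' @param counts [count_history()].
#' @param bundle [covariate_bundle()] (raw; standardized internally).
#' @param volumes named per-site stream volumes (m^3/km).
#' @param ves_obs,ves_site VES candidate covariates.
#' @param edna_obs eDNA observation covariate candidates.
#' @param z interval multiplier.
#' @return list of class `pipeline_result`: `ves`, `abundance`, `edna`,
#'   `comparison`, `occupied_sites`.
#' @export
run_survey_pipeline <- function(ves, counts, edna, bundle, volumes,
                                ves_obs = c("clarity", "depth", "time",
                                            "temp_ves", "surveyor"),
                                ves_site = c("forest", "ag", "embed", "mf",
                                             "imperv"),
                                edna_obs = c("drain", "arain", "temp_edna",
                                             "mf"),
                                z = 1.96) {
  bundle <- standardize(bundle)
  ves_stage <- run_ves_stage(ves, bundle, ves_obs, ves_site, z = z)

  ves_occ <- detected_sites(ves)
  abundance <- run_abundance_stage(counts, bundle, ves_occ,
                                   ves_obs, ves_site, volumes, z = z)

  # best VES site covariates carried to eDNA models; occupied subset for the
  # OS model is the union of VES-confirmed and eDNA-positive sites
  best_site <- ves_stage$ranked$model[1]
  idx <- match(best_site, names(ves_stage$fits))
  best_fit <- ves_stage$fits[[idx]]
  edna_site_covs <- if (!is.null(best_fit) && length(best_fit$beta) > 1) {
    names(best_fit$beta)[-1]
  } else {
    character()
  }
  occupied <- union(ves_occ, detected_sites(edna))
  edna_stage <- run_edna_stage(edna, bundle,
                               site_covariates = edna_site_covs,
                               obs_covariates = edna_obs,
                               density_table = abundance$density_table,
                               occupied_sites = occupied, z = z)

  comparison <- summarize_methods(ves, edna, ves_stage, edna_stage)
  structure(
    list(ves = ves_stage, abundance = abundance, edna = edna_stage,
         comparison = comparison, occupied_sites = occupied),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$comparison$summary, n = Inf)
  cat(sprintf("method independence: G = %.3f, df = %d, p = %.3f\n",
              x$comparison$independence$statistic,
              x$comparison$independence$df,
              x$comparison$independence$p.value))
  invisible(x)
}
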