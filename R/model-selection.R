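#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 LL + 2K + 2K(K + 1) / (n - K - 1)`, where `LL` is the maximized
#' log-likelihood, `K` the number of estimated parameters, and `n` the
#' effective sample size (the number of sites for occupancy and N-mixture
#' models). Requires `n > K + 1`.
#'
#' @param loglik maximized log-likelihood (vectorized).
#' @param K number of free parameters.
#' @param n effective sample size.
#' @return AICc value(s).
#' @examples
#' aicc(-26.86, K = 6, n = 37)
#' @export
aicc <- function(loglik, K, n) {
  if (any(n <= K + 1)) abort("AICc requires n > K + 1")
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike weights
#'
#' Converts a set of AICc values into model weights
#' `w_m = exp(-delta_m / 2) / sum(exp(-delta / 2))` with
#' `delta_m = AICc_m - min(AICc)`. Weights are invariant to adding a constant
#' to every AICc.
#'
#' @param aicc_values numeric vector of AICc values over a candidate set.
#' @return numeric vector of weights in (0, 1] summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  if (length(aicc_values) < 1) abort("need at least one AICc value")
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Enumerate covariate candidate sets for two-stage model selection
#'
#' Stage one (`"observation"`) evaluates every observation-covariate
#' combination of size 0 to `max_obs` with the state model held constant
#' (occupancy fixed to one, or abundance intercept-only). Stage two (`"full"`)
#' crosses every site-covariate combination of size 0 to `max_site` with the
#' fixed set of influential observation covariates carried over from stage
#' one. Intercept-only models (the empty subsets) are always included.
#'
#' @param obs_covariates observation covariate names (stage `"observation"`),
#'   or the fixed influential set (stage `"full"`).
#' @param site_covariates site covariate names (stage `"full"` only).
#' @param stage `"observation"` or `"full"`.
#' @param max_obs,max_site maximum covariates per model (defaults 3 and 2).
#' @return tibble with one row per candidate: `model` (label), `site_covs`
#'   and `obs_covs` (list-columns of character vectors).
#' @examples
#' nrow(enumerate_candidates(letters[1:5], stage = "observation")) # 26
#' @export
enumerate_candidates <- function(obs_covariates, site_covariates = character(),
                                 stage = c("observation", "full"),
                                 max_obs = 3, max_site = 2) {
  stage <- match.arg(stage)
  subsets <- function(x, kmax) {
    ks <- 0:min(kmax, length(x))
    purrr::flatten(purrr::map(ks, function(k) {
      if (k == 0) return(list(character()))
      apply(combn(x, k), 2, identity, simplify = FALSE)
    }))
  }
  if (stage == "observation") {
    obs_sets <- subsets(obs_covariates, max_obs)
    site_sets <- list(character())
  } else {
    obs_sets <- list(obs_covariates)
    site_sets <- subsets(site_covariates, max_site)
  }
  grid <- tidyr::expand_grid(site_covs = site_sets, obs_covs = obs_sets)
  lab <- function(prefix, covs) {
    sprintf("%s(%s)", prefix,
            if (length(covs)) paste(covs, collapse = " + ") else "1")
  }
  grid$model <- purrr::map2_chr(grid$site_covs, grid$obs_covs, function(s, o) {
    paste(lab("state", s), lab("p", o), sep = ", ")
  })
  grid[, c("model", "site_covs", "obs_covs")]
}

#' Rank candidate models by AICc
#'
#' Builds the standard model-selection table: AICc, delta AICc relative to the
#' best model, Akaike weights computed over the full candidate set, and the
#' log-likelihood, sorted by ascending AICc with ties broken by smaller K and
#' then model label.
#'
#' @param models tibble with columns `model`, `loglik`, `K`, and `n` (plus any
#'   extras, carried through).
#' @return tibble of class `ranked_models` with added columns `AICc`, `delta`,
#'   `weight`.
#' @export
rank_models <- function(models) {
  stopifnot(all(c("model", "loglik", "K", "n") %in% names(models)))
  out <- dplyr::mutate(tibble::as_tibble(models),
                       AICc = aicc(.data$loglik, .data$K, .data$n))
  out$delta <- out$AICc - min(out$AICc)
  out$weight <- akaike_weights(out$AICc)
  out <- dplyr::arrange(out, .data$AICc, .data$K, .data$model)
  class(out) <- c("ranked_models", class(out))
  out
}

#' Top candidate set within a delta-AICc threshold
#'
#' @param ranked a [rank_models()] table.
#' @param delta_threshold retain models with `delta <= delta_threshold`
#'   (default 4, the conventional cut for a competitive model).
#' @return the retained rows (never empty: the best model has delta 0).
#' @export
top_set <- function(ranked, delta_threshold = 4) {
  stopifnot(inherits(ranked, "ranked_models") || "delta" %in% names(ranked))
  dplyr::filter(ranked, .data$delta <= delta_threshold)
}

#' Model-averaged prediction with unconditional interval
#'
#' Averages per-model predictions on the link scale using full-candidate-set
#' Akaike weights, with the unconditional standard error of Burnham &
#' Anderson: `se = sum_m w_m * sqrt(se_m^2 + (est_m - avg)^2)`, which folds
#' model-selection uncertainty into the interval. The averaged value and its
#' interval are back-transformed through the inverse link. Models flagged as
#' unconverged (or with missing predictions) are dropped with their weight
#' renormalized over the remainder, with a warning.
#'
#' @param predictions tibble with columns `estimate` and `se` on the link
#'   scale, `weight`, and optionally `converged`.
#' @param link `"logit"`, `"log"`, or `"identity"` back-transform.
#' @param z interval multiplier on the link scale (default 1.96).
#' @return one-row tibble: `estimate`, `lower`, `upper` on the response scale,
#'   `link_estimate`, `link_se`, `n_models`.
#' @export
model_average <- function(predictions, link = c("logit", "log", "identity"),
                          z = 1.96) {
  link <- match.arg(link)
  linkinv <- switch(link, logit = plogis, log = exp, identity = identity)
  p <- tibble::as_tibble(predictions)
  stopifnot(all(c("estimate", "se", "weight") %in% names(p)))
  ok <- is.finite(p$estimate)
  if ("converged" %in% names(p)) ok <- ok & p$converged
  if (!any(ok)) abort("no usable model predictions to average")
  if (!all(ok)) {
    warn(sprintf("%d model(s) dropped from the average (unconverged or missing); weights renormalized",
                 sum(!ok)))
    p <- p[ok, ]
  }
  w <- p$weight / sum(p$weight)
  est <- sum(w * p$estimate)
  se2 <- ifelse(is.finite(p$se), p$se^2, 0)
  se <- sum(w * sqrt(se2 + (p$estimate - est)^2))
  dplyr::bind_cols(
    link_interval(est, se, z, linkinv),
    tibble::tibble(link_estimate = est, link_se = se, n_models = nrow(p))
  )
}

#' @export
print.ranked_models <- function(x, digits = 2, ...) {
  n_lab <- if ("n" %in% names(x)) paste(unique(x$n), collapse = "/") else "?"
  cat(sprintf("<ranked_models: %d candidates, effective n = %s>\n",
              nrow(x), n_lab))
  cols <- intersect(c("model", "K", "AICc", "delta", "weight", "loglik"),
                    names(x))
  shown <- dplyr::mutate(
    tibble::as_tibble(x)[, cols],
    dplyr::across(dplyr::where(is.numeric), ~ round(.x, digits))
  )
  print(shown, n = 10)
  invisible(x)
}
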