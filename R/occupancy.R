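#' Specify a single-season occupancy model
#'
#' Occupancy probability `psi` is modelled on the logit scale from site
#' covariates; detection probability `p` on the logit scale from site- or
#' observation-level covariates. With `fix_psi = TRUE` occupancy is held at
#' one ("occupied sites" variant), so only detection parameters are
#' estimated — used for stage-one observation-covariate screening and for the
#' eDNA occupied-sites model.
#'
#' @param psi character vector of site covariate names on occupancy (empty =
#'   intercept only).
#' @param p character vector of covariate names on detection.
#' @param fix_psi hold occupancy at 1?
#' @return an `occu_spec` object.
#' @export
occu_spec <- function(psi = character(), p = character(), fix_psi = FALSE) {
  if (anyDuplicated(psi) || anyDuplicated(p)) {
    abort("duplicated covariate names in model specification")
  }
  if (fix_psi && length(psi)) {
    abort("cannot put covariates on occupancy when it is fixed to one")
  }
  structure(list(psi = psi, p = p, fix_psi = fix_psi), class = "occu_spec")
}

#' @export
print.occu_spec <- function(x, ...) {
  lab <- function(covs) if (length(covs)) paste(covs, collapse = " + ") else "1"
  cat(sprintf("psi(%s), p(%s)\n", if (x$fix_psi) "=1" else lab(x$psi), lab(x$p)))
  invisible(x)
}

# design pieces: site matrix for psi, per-occasion linear predictor for p
occu_design <- function(spec, history, bundle) {
  y <- history$y
  n <- nrow(y)
  J <- ncol(y)
  X_psi <- NULL
  if (!spec$fix_psi) {
    X_psi <- cbind(`(Intercept)` = rep(1, n))
    for (nm in spec$psi) {
      v <- bundle$site_table[[nm]]
      if (is.null(v)) abort(sprintf("site covariate `%s` not found", nm))
      X_psi <- cbind(X_psi, v)
      colnames(X_psi)[ncol(X_psi)] <- nm
    }
  }
  p_mats <- purrr::map(spec$p, ~ covariate_matrix(bundle, .x, J))
  names(p_mats) <- spec$p
  list(y = y, n = n, J = J, X_psi = X_psi, p_mats = p_mats)
}

occu_eta_p <- function(alpha, design) {
  eta <- matrix(alpha[1], design$n, design$J)
  for (k in seq_along(design$p_mats)) {
    eta <- eta + alpha[k + 1] * design$p_mats[[k]]
  }
  eta
}

occu_npar <- function(spec) {
  (if (spec$fix_psi) 0L else length(spec$psi) + 1L) + length(spec$p) + 1L
}

# closure precomputing the design, missingness mask, and all-zero indicator
occu_nll_factory <- function(spec, history, bundle) {
  design <- occu_design(spec, history, bundle)
  y <- design$y
  obs_mask <- !is.na(y)
  all_zero <- as.numeric(apply(y, 1, function(r) all(r[!is.na(r)] == 0)))
  kb <- if (spec$fix_psi) 0L else ncol(design$X_psi)

  function(params) {
    if (spec$fix_psi) {
      psi <- rep(1, design$n)
      alpha <- params
    } else {
      psi <- plogis(drop(design$X_psi %*% params[seq_len(kb)]))
      alpha <- params[-seq_len(kb)]
    }
    eta <- occu_eta_p(alpha, design)
    # y log p + (1 - y) log(1 - p) = y * eta + log(1 - p), summed over
    # observed occasions
    log1mp <- plogis(eta, lower.tail = FALSE, log.p = TRUE)
    ll_det <- rowSums(ifelse(obs_mask, y * eta + log1mp, 0))
    L <- psi * exp(ll_det) + (1 - psi) * all_zero
    -sum(log(pmax(L, .Machine$double.xmin)))
  }
}

#' Negative log-likelihood of the single-season occupancy model
#'
#' Per site `i`, the likelihood mixes the two latent states:
#' `L_i = psi_i * prod_j p_ij^y_ij (1 - p_ij)^(1 - y_ij) + (1 - psi_i) * I[all y_ij = 0]`,
#' with the product over non-missing occasions only; a site with every
#' occasion missing contributes a factor of 1. With occupancy fixed to one
#' the first term alone remains.
#'
#' @param params coefficient vector: occupancy coefficients (intercept first,
#'   absent when `fix_psi`), then detection coefficients (intercept first),
#'   all on the logit scale.
#' @param spec an [occu_spec()].
#' @param history a [detection_history()].
#' @param bundle a [covariate_bundle()] (may be `NULL` for intercept-only
#'   models).
#' @return the negative log-likelihood (scalar).
#' @export
occupancy_negloglik <- function(params, spec, history, bundle = NULL) {
  if (length(params) != occu_npar(spec)) {
    abort(sprintf("expected %d parameters, got %d", occu_npar(spec), length(params)))
  }
  occu_nll_factory(spec, history, bundle)(params)
}

#' Fit a single-season occupancy model by maximum likelihood
#'
#' Quasi-Newton (BFGS) optimization from five deterministic start points
#' (all-zero coefficients plus +/-1 shifts of each intercept), retaining the
#' best optimum. The coefficient covariance is the inverse of the numerically
#' differentiated observed information; when that matrix is singular the
#' covariance (and any interval built from it) is reported as unavailable
#' rather than fabricated. The effective sample size recorded for AICc is the
#' number of sites.
#'
#' @inheritParams occupancy_negloglik
#' @param history a [detection_history()].
#' @return an `occu_fit` with fields `beta` (occupancy, logit scale), `alpha`
#'   (detection, logit scale), `loglik`, `K`, `n_sites`, `vcov`, `converged`,
#'   `boundary`, and the spec.
#' @examples
#' set.seed(1)
#' sim <- simulate_occupancy_data(n_sites = 200, n_occasions = 3,
#'                                psi = 0.6, p = 0.7)
#' fit <- fit_occupancy(sim$history)
#' glance(fit)
#' @export
fit_occupancy <- function(history, bundle = NULL, spec = occu_spec()) {
  stopifnot(inherits(history, "detection_history"))
  npar <- occu_npar(spec)
  intercepts <- if (spec$fix_psi) 1L else c(1L, length(spec$psi) + 2L)
  res <- ml_multistart(occu_nll_factory(spec, history, bundle), npar, intercepts)
  if (spec$fix_psi) {
    beta <- numeric(0)
    alpha <- res$par
  } else {
    kb <- length(spec$psi) + 1L
    beta <- res$par[seq_len(kb)]
    alpha <- res$par[-seq_len(kb)]
  }
  names(beta) <- if (length(beta)) c("(Intercept)", spec$psi)
  names(alpha) <- c("(Intercept)", spec$p)
  boundary <- any(abs(c(beta[1], alpha[1])) > 10, na.rm = TRUE)
  if (boundary) {
    warn("fit is at or near the parameter boundary; estimates and intervals are unreliable")
  }
  structure(
    list(
      beta = beta, alpha = alpha,
      loglik = -res$value,
      K = npar,
      n_sites = nrow(history$y),
      vcov = res$vcov,
      converged = res$converged,
      boundary = boundary,
      spec = spec
    ),
    class = "occu_fit"
  )
}

#' @export
print.occu_fit <- function(x, ...) {
  cat("Single-season occupancy fit: ")
  print(x$spec)
  print(tidy(x), n = Inf)
  cat(sprintf("logLik %.3f, K = %d, n = %d sites, AICc = %.2f\n",
              x$loglik, x$K, x$n_sites, aicc(x$loglik, x$K, x$n_sites)))
  invisible(x)
}

#' @export
tidy.occu_fit <- function(x, ...) {
  est <- c(x$beta, x$alpha)
  se <- rep(NA_real_, length(est))
  if (!is.null(x$vcov)) {
    d <- diag(x$vcov)
    se <- ifelse(d >= 0, sqrt(d), NA_real_)
  }
  tibble::tibble(
    component = c(rep("psi", length(x$beta)), rep("p", length(x$alpha))),
    term = names(est),
    estimate = unname(est),
    std.error = se
  )
}

#' @export
glance.occu_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    K = x$K,
    AICc = aicc(x$loglik, x$K, x$n_sites),
    n_sites = x$n_sites,
    converged = x$converged,
    boundary = x$boundary
  )
}

# linear predictor + delta-method se at one covariate setting
fit_link_prediction <- function(fit, component, values) {
  if (component == "psi") {
    terms <- names(fit$beta)
    coefs <- fit$beta
    offset <- 0L
  } else {
    terms <- names(fit$alpha)
    coefs <- fit$alpha
    offset <- length(fit$beta)
  }
  x <- c(1, purrr::map_dbl(terms[-1], function(nm) {
    v <- values[[nm]]
    if (is.null(v)) 0 else v  # standardized covariates default to their mean
  }))
  eta <- sum(x * coefs)
  se <- NA_real_
  if (!is.null(fit$vcov)) {
    idx <- offset + seq_along(coefs)
    v <- drop(t(x) %*% fit$vcov[idx, idx, drop = FALSE] %*% x)
    if (is.finite(v) && v >= 0) se <- sqrt(v)
  }
  c(eta = eta, se = se)
}

#' Predicted occupancy probability at given covariate values
#'
#' Point estimate and delta-method interval, computed on the logit scale and
#' back-transformed, so endpoints always lie inside (0, 1). Covariates not
#' named in `newdata` are set to 0, i.e. their mean after standardization.
#'
#' @param fit an `occu_fit`.
#' @param newdata named list/one-row data frame of covariate values on the
#'   standardized scale; default all means.
#' @param z interval multiplier on the link scale (default 1.96, ~95%).
#' @return one-row tibble `estimate`, `lower`, `upper`.
#' @export
predict_occupancy <- function(fit, newdata = list(), z = 1.96) {
  stopifnot(inherits(fit, "occu_fit"))
  if (fit$spec$fix_psi) {
    return(tibble::tibble(estimate = 1, lower = 1, upper = 1))
  }
  pr <- fit_link_prediction(fit, "psi", as.list(newdata))
  link_interval(pr[["eta"]], pr[["se"]], z, plogis)
}

#' Predicted detection probability over a covariate grid
#'
#' Evaluates the detection curve over a grid in which one covariate varies
#' and the others sit at their (standardized) means, with a delta-method band
#' back-transformed from the logit scale — the machinery behind
#' detection-versus-density or detection-versus-temperature curves.
#'
#' @param fit an `occu_fit`.
#' @param newdata data frame; each row is one covariate setting (unnamed
#'   covariates default to 0 = mean).
#' @param z interval multiplier (default 1.96).
#' @return tibble of class `detection_curve`: `newdata` columns plus
#'   `estimate`, `lower`, `upper`.
#' @export
predict_detection <- function(fit, newdata = tibble::tibble(.rows = 1), z = 1.96) {
  stopifnot(inherits(fit, "occu_fit"))
  newdata <- tibble::as_tibble(newdata)
  rows <- purrr::map(seq_len(nrow(newdata)), function(i) {
    pr <- fit_link_prediction(fit, "p", as.list(newdata[i, , drop = FALSE]))
    link_interval(pr[["eta"]], pr[["se"]], z, plogis)
  })
  out <- dplyr::bind_cols(newdata, dplyr::bind_rows(rows))
  class(out) <- c("detection_curve", class(out))
  out
}

#' @rdname predict_detection
#' @param object a `detection_curve`.
#' @param x_var covariate to place on the x axis (default: the first varying
#'   column).
#' @param ... unused.
#' @export
autoplot.detection_curve <- function(object, x_var = NULL, ...) {
  covs <- setdiff(names(object), c("estimate", "lower", "upper"))
  if (is.null(x_var)) {
    varying <- covs[purrr::map_lgl(covs, ~ dplyr::n_distinct(object[[.x]]) > 1)]
    x_var <- if (length(varying)) varying[[1]] else covs[[1]]
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[x_var]], y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = x_var, y = "Detection probability") +
    ggplot2::theme_minimal()
}
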