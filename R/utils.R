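# internal helpers shared across modules

inv_logit <- function(x) plogis(x)

# numerically safe log(a*exp(la) + b) used nowhere hot; likelihoods work on
# natural scale because site likelihood terms are bounded in (0, 1]

assert_scalar_prob <- function(x, name, open_left = TRUE, open_right = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_left) x > 0 else x >= 0) &&
    (if (open_right) x < 1 else x <= 1)
  if (!ok) {
    abort(sprintf("`%s` must be a single probability in %s0, 1%s",
                  name, if (open_left) "(" else "[",
                  if (open_right) ")" else "]"))
  }
  invisible(x)
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

# deterministic multistart points: zeros plus +/-1 shifts of each intercept
multistart_points <- function(n_par, intercept_idx) {
  starts <- list(rep(0, n_par))
  for (i in intercept_idx) {
    for (s in c(1, -1)) {
      pt <- rep(0, n_par)
      pt[i] <- s
      starts[[length(starts) + 1L]] <- pt
    }
  }
  unique(starts)
}

# quasi-Newton fit from multiple deterministic starts: a coarse BFGS pass
# from every start, then a tight polish from the best coarse optimum.
# Returns the polished result plus the numerically differentiated Hessian.
ml_multistart <- function(negloglik, n_par, intercept_idx,
                          maxit = 500L, reltol = 1e-10,
                          coarse_negloglik = negloglik) {
  starts <- multistart_points(n_par, intercept_idx)
  best <- NULL
  for (start in starts) {
    res <- tryCatch(
      optim(start, coarse_negloglik, method = "BFGS",
            control = list(maxit = maxit, reltol = 1e-6)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    abort("optimization failed from every start point")
  }
  best$value <- negloglik(best$par)  # coarse objective may differ
  polished <- tryCatch(
    optim(best$par, negloglik, method = "BFGS",
          control = list(maxit = maxit, reltol = reltol)),
    error = function(e) NULL
  )
  if (!is.null(polished) && is.finite(polished$value) &&
      polished$value <= best$value) {
    best <- polished
  }
  hess <- tryCatch(optimHess(best$par, negloglik), error = function(e) NULL)
  vcov <- NULL
  if (!is.null(hess)) {
    vcov <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vcov) && any(!is.finite(vcov))) vcov <- NULL
  }
  list(
    par = best$par,
    value = best$value,
    converged = best$convergence == 0L,
    vcov = vcov
  )
}

# delta-method interval on an inverse-link scale
link_interval <- function(eta, se, z, linkinv) {
  if (!is.finite(se)) {
    return(tibble::tibble(estimate = linkinv(eta),
                          lower = NA_real_, upper = NA_real_))
  }
  tibble::tibble(
    estimate = linkinv(eta),
    lower = linkinv(eta - z * se),
    upper = linkinv(eta + z * se)
  )
}
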