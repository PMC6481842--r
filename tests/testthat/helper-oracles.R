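# Independent brute-force oracles used to validate the likelihood code.
# They enumerate latent states directly and share no code with the package
# implementations they check.

# occupancy likelihood by explicit enumeration of the latent state per site
oracle_occupancy_negloglik <- function(params, psi_covs, p_covs, y,
                                       X_site = NULL, p_mats = NULL,
                                       fix_psi = FALSE) {
  n <- nrow(y)
  J <- ncol(y)
  n_beta <- if (fix_psi) 0 else length(psi_covs) + 1
  ll <- 0
  for (i in seq_len(n)) {
    if (fix_psi) {
      psi_i <- 1
      alpha <- params
    } else {
      x <- c(1, if (length(psi_covs)) X_site[i, psi_covs])
      psi_i <- plogis(sum(x * params[seq_len(n_beta)]))
      alpha <- params[-seq_len(n_beta)]
    }
    L_i <- 0
    for (z in c(0, 1)) {
      pz <- if (z == 1) psi_i else 1 - psi_i
      cond <- 1
      for (j in seq_len(J)) {
        if (is.na(y[i, j])) next
        eta <- alpha[1]
        for (k in seq_along(p_covs)) {
          eta <- eta + alpha[k + 1] * p_mats[[p_covs[k]]][i, j]
        }
        p_ij <- z * plogis(eta)
        cond <- cond * (if (y[i, j] == 1) p_ij else 1 - p_ij)
      }
      L_i <- L_i + pz * cond
    }
    ll <- ll + log(L_i)
  }
  -ll
}

# zero-inflated N-mixture likelihood by explicit latent-abundance enumeration
oracle_nmixture_negloglik <- function(log_lambda, logit_p, logit_phi, cm,
                                      N_big = 300) {
  lambda <- exp(log_lambda)
  p <- plogis(logit_p)
  phi <- plogis(logit_phi)
  ll <- 0
  for (i in seq_len(nrow(cm))) {
    L_i <- 0
    for (N in 0:N_big) {
      pN <- (1 - phi) * dpois(N, lambda) + if (N == 0) phi else 0
      f <- pN
      for (j in seq_len(ncol(cm))) {
        if (is.na(cm[i, j])) next
        f <- f * dbinom(cm[i, j], N, p)
      }
      L_i <- L_i + f
    }
    ll <- ll + log(L_i)
  }
  -ll
}

# expected counts from margins, computed cell by cell
oracle_g_statistic <- function(O) {
  total <- sum(O)
  G <- 0
  for (r in seq_len(nrow(O))) {
    for (c in seq_len(ncol(O))) {
      E <- sum(O[r, ]) * sum(O[, c]) / total
      if (O[r, c] > 0) G <- G + 2 * O[r, c] * log(O[r, c] / E)
    }
  }
  G
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "ednaoccu", mustWork = TRUE)
}

read_fixture_history <- function(name) {
  detection_history(utils::read.csv(fixture_path(name)))
}
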