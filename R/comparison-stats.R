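#' Likelihood-ratio g-test of independence
#'
#' Tests independence of the rows and columns of a contingency table with the
#' statistic `G = 2 * sum(O * log(O / E))`, expected counts `E` from the row
#' and column margins, `df = (r - 1)(c - 1)`, and a chi-square reference
#' distribution. Cells with zero observed count contribute zero; no continuity
#' correction is applied. As all expected counts grow, G converges to the
#' Pearson chi-square statistic.
#'
#' @param counts an r-by-c matrix (or data frame) of non-negative integer
#'   counts, e.g. the cross-classification of sites by VES detection and eDNA
#'   detection.
#' @return one-row tibble with `statistic` (G), `df`, `p.value`, `method`.
#' @examples
#' g_test(matrix(c(13, 3, 4, 17), 2)) # VES x eDNA site cross-classification
#' @export
g_test <- function(counts) {
  O <- as.matrix(counts)
  if (any(!is.finite(O)) || any(O < 0) || any(!is_wholenumber(O))) {
    abort("counts must be non-negative integers")
  }
  if (sum(O) == 0) abort("table total must be positive")
  rs <- rowSums(O)
  cs <- colSums(O)
  if (any(rs == 0) || any(cs == 0)) {
    abort("degenerate table: a row or column margin is zero")
  }
  E <- outer(rs, cs) / sum(O)
  terms <- ifelse(O > 0, O * log(O / E), 0)
  G <- 2 * sum(terms)
  df <- (nrow(O) - 1) * (ncol(O) - 1)
  tibble::tibble(
    statistic = G,
    df = df,
    p.value = pchisq(G, df = df, lower.tail = FALSE),
    method = "likelihood-ratio g-test of independence"
  )
}

#' Binomial proportion with a Wald interval
#'
#' Point estimate `k / n` with the Wald interval
#' `p +/- z * sqrt(p(1 - p)/n)`, truncated to `[0, 1]`. The default `z = 1`
#' gives a +/-1-standard-error band — note this is a ~68% interval, not a 95%
#' one; use `z = 1.96` for the conventional 95% Wald interval.
#'
#' @param successes number of successes (e.g. sites with a detection).
#' @param n number of trials (e.g. sites surveyed).
#' @param z interval half-width in standard errors (default 1).
#' @return one-row tibble: `successes`, `n`, `estimate`, `lower`, `upper`, `z`.
#' @examples
#' proportion_interval(17, 37, z = 1)
#' @export
proportion_interval <- function(successes, n, z = 1) {
  if (!is_wholenumber(successes) || !is_wholenumber(n) ||
      successes < 0 || n < 1 || successes > n) {
    abort("need integer 0 <= successes <= n with n >= 1")
  }
  if (!is.finite(z) || z < 0) abort("`z` must be a non-negative number")
  p <- successes / n
  se <- sqrt(p * (1 - p) / n)
  tibble::tibble(
    successes = successes,
    n = n,
    estimate = p,
    lower = max(0, p - z * se),
    upper = min(1, p + z * se),
    z = z
  )
}

#' Cross-classify two detection histories at the site level
#'
#' Builds the 2x2 site-level contingency table (detected / not detected by
#' each method) used to compare survey methods, e.g. VES versus eDNA.
#'
#' @param history_a,history_b [detection_history()] objects over the same
#'   sites.
#' @param labels length-2 character vector naming the methods.
#' @return 2x2 integer matrix with dimnames
#'   `list(<a> = c("detected","not detected"), <b> = ...)`.
#' @export
method_cross_table <- function(history_a, history_b,
                               labels = c("method_a", "method_b")) {
  stopifnot(inherits(history_a, "detection_history"),
            inherits(history_b, "detection_history"))
  if (!setequal(history_a$site_ids, history_b$site_ids)) {
    abort("the two histories must cover the same sites")
  }
  ord <- match(history_a$site_ids, history_b$site_ids)
  da <- apply(history_a$y, 1, function(r) any(r == 1, na.rm = TRUE))
  db <- apply(history_b$y[ord, , drop = FALSE], 1,
              function(r) any(r == 1, na.rm = TRUE))
  tab <- table(factor(!da, levels = c(FALSE, TRUE),
                      labels = c("detected", "not detected")),
               factor(!db, levels = c(FALSE, TRUE),
                      labels = c("detected", "not detected")))
  tab <- unclass(tab)
  names(dimnames(tab)) <- labels
  tab
}
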