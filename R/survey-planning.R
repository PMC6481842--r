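#' Cumulative detection probability over repeated replicates
#'
#' For a species present at a site, the probability of at least one detection
#' in `n` independent replicates each with single-replicate detection
#' probability `p` is `p* = 1 - (1 - p)^n` (McArdle's equation). Strictly
#' increasing in both `p` and `n` for `p < 1`.
#'
#' @param p single-replicate detection probability in (0, 1].
#' @param n number of replicates (positive integer, vectorized).
#' @return cumulative detection probability `p*`.
#' @examples
#' cumulative_detection(0.57, 3) # ~0.92
#' @export
cumulative_detection <- function(p, n) {
  if (!all(is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("`p` must lie in (0, 1]")
  }
  if (any(!is_wholenumber(n)) || any(n < 1)) {
    abort("`n` must be a positive integer")
  }
  1 - (1 - p)^n
}

#' Minimum replicates for a target cumulative detection probability
#'
#' Smallest integer `n` with `1 - (1 - p)^n >= target`, i.e.
#' `ceiling(log(1 - target) / log(1 - p))`, floored at 1. With `p = 1` a
#' single replicate suffices.
#'
#' @param p single-replicate detection probability in (0, 1].
#' @param target desired cumulative detection probability in (0, 1).
#' @return integer number of replicates.
#' @examples
#' min_replicates(0.57, 0.95) # 4 filter replicates
#' min_replicates(0.84, 0.95) # 2 surveys
#' @export
min_replicates <- function(p, target) {
  assert_scalar_prob(p, "p")
  assert_scalar_prob(target, "target", open_right = TRUE)
  if (p == 1) return(1L)
  # tolerance keeps an exactly attained target (ratio on an integer) from
  # being pushed up a replicate by floating-point error
  ratio <- log1p(-target) / log1p(-p)
  max(1L, as.integer(ceiling(ratio - 1e-9)))
}

#' Cumulative detection curve with interval band
#'
#' Applies the cumulative detection map to a point estimate and its interval
#' endpoints over `n = 1, ..., n_max` replicates. Because the map is monotone
#' in `p`, transforming the endpoints gives the band for `p*` directly.
#'
#' @param p single-replicate detection probability.
#' @param lower,upper optional interval endpoints for `p` in (0, 1).
#' @param n_max largest replicate count tabulated (default 10).
#' @return tibble of class `cumulative_curve` with columns `n`, `p_star`, and
#'   (when endpoints supplied) `lower`, `upper`.
#' @examples
#' cumulative_curve(0.57, lower = 0.39, upper = 0.72, n_max = 6)
#' @export
cumulative_curve <- function(p, lower = NULL, upper = NULL, n_max = 10) {
  assert_scalar_prob(p, "p")
  n <- seq_len(n_max)
  out <- tibble::tibble(n = n, p_star = cumulative_detection(p, n))
  if (!is.null(lower) || !is.null(upper)) {
    if (is.null(lower) || is.null(upper)) {
      abort("supply both `lower` and `upper`, or neither")
    }
    assert_scalar_prob(lower, "lower", open_right = TRUE)
    assert_scalar_prob(upper, "upper", open_right = TRUE)
    if (!(lower <= p && p <= upper)) abort("need lower <= p <= upper")
    out$lower <- cumulative_detection(lower, n)
    out$upper <- cumulative_detection(upper, n)
  }
  class(out) <- c("cumulative_curve", class(out))
  out
}

#' @rdname cumulative_curve
#' @param object a `cumulative_curve`.
#' @param target optional horizontal reference line (e.g. 0.95).
#' @param ... unused.
#' @export
autoplot.cumulative_curve <- function(object, target = 0.95, ...) {
  gg <- ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data$p_star))
  if ("lower" %in% names(object)) {
    gg <- gg + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper), width = 0.15
    )
  }
  gg +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = target, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = object$n) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Number of replicates",
                  y = "Cumulative detection probability") +
    ggplot2::theme_minimal()
}
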