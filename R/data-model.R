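#' Detection and count histories
#'
#' A detection history is a site-by-occasion matrix of binary outcomes (1 =
#' species or its eDNA detected on that occasion, 0 = not detected, `NA` =
#' occasion not surveyed). A count history holds non-negative integer counts
#' of individuals instead. Both accept either a matrix with row names, a wide
#' data frame (one `site` column plus one column per occasion), or a long data
#' frame with `site`, `occasion`, and value columns.
#'
#' Missing observations are always encoded as `NA`, never 0: a 0 is a real
#' survey outcome. Each site must have at least one non-missing occasion.
#'
#' @param x matrix, wide data frame, or long data frame of outcomes.
#' @param site,occasion,value column names used when `x` is a long data frame.
#' @return An object of class `detection_history` (or `count_history`) with
#'   fields `site_ids` and the outcome matrix `y` (or `c`).
#' @examples
#' df <- tibble::tibble(site = rep(c("a", "b"), each = 2),
#'                      occasion = rep(1:2, 2), y = c(1, 0, 0, 0))
#' detection_history(df, value = "y")
#' @export
detection_history <- function(x, site = "site", occasion = "occasion",
                              value = "value") {
  m <- coerce_history_matrix(x, site, occasion, value)
  bad <- !is.na(m) & !(m %in% c(0, 1))
  if (any(bad)) {
    abort("detection values must be 0, 1, or missing")
  }
  validate_history(m)
  structure(list(site_ids = rownames(m), y = m), class = "detection_history")
}

#' @rdname detection_history
#' @export
count_history <- function(x, site = "site", occasion = "occasion",
                          value = "value") {
  m <- coerce_history_matrix(x, site, occasion, value)
  bad <- !is.na(m) & (m < 0 | !is_wholenumber(m))
  if (any(bad)) {
    abort("counts must be non-negative integers or missing")
  }
  validate_history(m)
  structure(list(site_ids = rownames(m), c = m), class = "count_history")
}

coerce_history_matrix <- function(x, site, occasion, value) {
  if (is.matrix(x)) {
    m <- x
    storage.mode(m) <- "double"
    if (is.null(rownames(m))) rownames(m) <- paste0("site_", seq_len(nrow(m)))
    colnames(m) <- paste0("occ_", seq_len(ncol(m)))
    return(m)
  }
  if (!is.data.frame(x)) {
    abort("history input must be a matrix or data frame")
  }
  x <- tibble::as_tibble(x)
  if (!site %in% names(x)) {
    abort(sprintf("column `%s` not found in history table", site))
  }
  long <- all(c(occasion, value) %in% names(x)) && ncol(x) >= 3
  if (long && !occasion %in% names(x)) long <- FALSE
  if (all(c(occasion, value) %in% names(x))) {
    wide <- tidyr::pivot_wider(
      x[, c(site, occasion, value)],
      names_from = dplyr::all_of(occasion),
      values_from = dplyr::all_of(value)
    )
  } else {
    wide <- x
  }
  ids <- as.character(wide[[site]])
  if (anyDuplicated(ids)) abort("site identifiers must be unique")
  m <- as.matrix(wide[, setdiff(names(wide), site), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  colnames(m) <- paste0("occ_", seq_len(ncol(m)))
  m
}

validate_history <- function(m) {
  if (nrow(m) < 1 || ncol(m) < 1) abort("history must have >= 1 site and occasion")
  if (anyDuplicated(rownames(m))) abort("site identifiers must be unique")
  if (any(rowSums(!is.na(m)) == 0)) {
    abort("every site needs at least one non-missing occasion")
  }
  invisible(m)
}

#' @export
print.detection_history <- function(x, ...) {
  cat(sprintf("<detection_history: %d sites x %d occasions>\n",
              nrow(x$y), ncol(x$y)))
  print(head(x$y, 6))
  invisible(x)
}

#' @export
print.count_history <- function(x, ...) {
  cat(sprintf("<count_history: %d sites x %d occasions>\n",
              nrow(x$c), ncol(x$c)))
  print(head(x$c, 6))
  invisible(x)
}

#' @export
dim.detection_history <- function(x) dim(x$y)

#' @export
dim.count_history <- function(x) dim(x$c)

#' @export
as_tibble.detection_history <- function(x, ...) history_to_long(x$y, "y")

#' @export
as_tibble.count_history <- function(x, ...) history_to_long(x$c, "count")

history_to_long <- function(m, value_name) {
  tibble::tibble(
    site = rep(rownames(m), times = ncol(m)),
    occasion = rep(seq_len(ncol(m)), each = nrow(m)),
    !!value_name := as.vector(m)
  )
}

#' Bundle site-level and observation-level covariates
#'
#' Site covariates are one value per site (land cover, stream geometry);
#' observation covariates vary by site and occasion (water clarity, survey
#' time, days since rain). Observation covariates are stored as site-by-
#' occasion matrices aligned with the detection history.
#'
#' @param site_covariates data frame with a `site` column plus numeric
#'   covariate columns.
#' @param obs_covariates named list of site-by-occasion matrices or wide data
#'   frames (a `site` column plus one column per occasion).
#' @param site name of the site identifier column.
#' @return An object of class `covariate_bundle` with fields `site_table`
#'   (tibble), `obs_tables` (list of matrices), and `scaling` (tibble of
#'   stored centering/scaling constants, empty until [standardize()] is used).
#' @export
covariate_bundle <- function(site_covariates, obs_covariates = list(),
                             site = "site") {
  st <- tibble::as_tibble(site_covariates)
  if (!site %in% names(st)) abort(sprintf("column `%s` not found", site))
  names(st)[names(st) == site] <- "site"
  st$site <- as.character(st$site)
  if (anyDuplicated(st$site)) abort("site identifiers must be unique")
  obs <- purrr::imap(obs_covariates, function(tab, nm) {
    m <- coerce_history_matrix(tab, site, "occasion", "value")
    if (!setequal(rownames(m), st$site)) {
      abort(sprintf("observation covariate `%s` covers a different site set", nm))
    }
    m[match(st$site, rownames(m)), , drop = FALSE]
  })
  structure(
    list(site_table = st, obs_tables = obs,
         scaling = tibble::tibble(covariate = character(),
                                  mean = double(), sd = double())),
    class = "covariate_bundle"
  )
}

#' @export
print.covariate_bundle <- function(x, ...) {
  cat(sprintf("<covariate_bundle: %d sites, %d site covariates, %d observation covariates>\n",
              nrow(x$site_table), ncol(x$site_table) - 1L, length(x$obs_tables)))
  if (nrow(x$scaling) > 0) {
    cat("standardized:", paste(x$scaling$covariate, collapse = ", "), "\n")
  }
  invisible(x)
}

covariate_names <- function(bundle) {
  c(setdiff(names(bundle$site_table), "site"), names(bundle$obs_tables))
}

# site x occasion matrix for any covariate (site covariates recycled)
covariate_matrix <- function(bundle, name, n_occasions) {
  if (name %in% names(bundle$obs_tables)) {
    return(bundle$obs_tables[[name]])
  }
  if (name %in% names(bundle$site_table)) {
    v <- bundle$site_table[[name]]
    return(matrix(v, nrow = length(v), ncol = n_occasions))
  }
  abort(sprintf("covariate `%s` not found in bundle", name))
}

#' Standardize covariates to mean zero, unit standard deviation
#'
#' Centers each named covariate on its sample mean and scales by its sample
#' standard deviation, the usual preprocessing before occupancy or N-mixture
#' fitting so that coefficients are comparable and optimization is well
#' conditioned. The (mean, sd) pair is stored in the bundle so the transform
#' can be inverted with [unstandardize()].
#'
#' @param bundle a [covariate_bundle()].
#' @param columns covariate names to standardize; default all numeric
#'   covariates.
#' @return The bundle with selected covariates standardized and `scaling`
#'   filled in.
#' @export
standardize <- function(bundle, columns = covariate_names(bundle)) {
  stopifnot(inherits(bundle, "covariate_bundle"))
  for (nm in columns) {
    if (nm %in% bundle$scaling$covariate) next
    if (nm %in% names(bundle$obs_tables)) {
      v <- as.vector(bundle$obs_tables[[nm]])
      mu <- mean(v, na.rm = TRUE)
      sg <- sd(v, na.rm = TRUE)
      if (!is.finite(sg) || sg <= 0) {
        abort(sprintf("covariate `%s` has zero variance", nm))
      }
      bundle$obs_tables[[nm]] <- (bundle$obs_tables[[nm]] - mu) / sg
    } else if (nm %in% names(bundle$site_table)) {
      v <- bundle$site_table[[nm]]
      mu <- mean(v, na.rm = TRUE)
      sg <- sd(v, na.rm = TRUE)
      if (!is.finite(sg) || sg <= 0) {
        abort(sprintf("covariate `%s` has zero variance", nm))
      }
      bundle$site_table[[nm]] <- (v - mu) / sg
    } else {
      abort(sprintf("covariate `%s` not found in bundle", nm))
    }
    bundle$scaling <- dplyr::bind_rows(
      bundle$scaling,
      tibble::tibble(covariate = nm, mean = mu, sd = sg)
    )
  }
  bundle
}

#' @rdname standardize
#' @export
unstandardize <- function(bundle) {
  stopifnot(inherits(bundle, "covariate_bundle"))
  for (i in seq_len(nrow(bundle$scaling))) {
    nm <- bundle$scaling$covariate[i]
    mu <- bundle$scaling$mean[i]
    sg <- bundle$scaling$sd[i]
    if (nm %in% names(bundle$obs_tables)) {
      bundle$obs_tables[[nm]] <- bundle$obs_tables[[nm]] * sg + mu
    } else {
      bundle$site_table[[nm]] <- bundle$site_table[[nm]] * sg + mu
    }
  }
  bundle$scaling <- bundle$scaling[0, ]
  bundle
}

#' Screen covariate pairs for rank correlation
#'
#' Computes Spearman's rank correlation (average ranks for ties) between every
#' pair of covariates and returns the pairs whose absolute correlation meets
#' the threshold. Site covariates are expanded across occasions when paired
#' with observation covariates so all pairs are comparable. Flagged pairs are
#' reported with a warning; nothing is dropped automatically — which covariate
#' to retain is an analyst decision.
#'
#' @param bundle a [covariate_bundle()].
#' @param threshold flag pairs with `|rho| >= threshold` (default 0.7).
#' @param n_occasions number of occasions used to expand site covariates when
#'   observation covariates are present; inferred from the bundle otherwise.
#' @return tibble with columns `covariate_1`, `covariate_2`, `rho`, one row
#'   per flagged pair (zero rows when none flagged).
#' @export
spearman_screen <- function(bundle, threshold = 0.7, n_occasions = NULL) {
  stopifnot(inherits(bundle, "covariate_bundle"))
  nms <- covariate_names(bundle)
  if (length(nms) < 2) {
    return(tibble::tibble(covariate_1 = character(), covariate_2 = character(),
                          rho = double()))
  }
  J <- n_occasions %||%
    (if (length(bundle$obs_tables)) ncol(bundle$obs_tables[[1]]) else 1L)
  if (nrow(bundle$site_table) < 3) abort("need at least 3 sites to screen")
  cols <- purrr::map(nms, function(nm) as.vector(covariate_matrix(bundle, nm, J)))
  X <- do.call(cbind, cols)
  colnames(X) <- nms
  R <- suppressWarnings(cor(X, method = "spearman", use = "pairwise.complete.obs"))
  out <- tibble::as_tibble(as.data.frame.table(R, stringsAsFactors = FALSE))
  names(out) <- c("covariate_1", "covariate_2", "rho")
  out <- dplyr::filter(
    out,
    .data$covariate_1 < .data$covariate_2,
    is.finite(.data$rho),
    abs(.data$rho) >= threshold
  )
  out <- dplyr::arrange(out, dplyr::desc(abs(.data$rho)))
  if (nrow(out) > 0) {
    warn(sprintf("%d covariate pair(s) with |rho| >= %.2f; consider dropping one of each pair",
                 nrow(out), threshold))
  }
  out
}

#' Naive occupancy: fraction of sites with at least one detection
#'
#' The uncorrected occupancy estimate: a site counts as occupied if any
#' non-missing occasion recorded a detection. Invariant to occasion order and
#' to all-missing occasions.
#'
#' @param history a [detection_history()] (or coercible input).
#' @return one-row tibble with `n_detected`, `n_sites`, `proportion`.
#' @examples
#' m <- rbind(c(1, 0, 0), c(0, 0, 0))
#' naive_occupancy(detection_history(m))
#' @export
naive_occupancy <- function(history) {
  if (!inherits(history, "detection_history")) {
    history <- detection_history(history)
  }
  detected <- apply(history$y, 1, function(r) any(r == 1, na.rm = TRUE))
  tibble::tibble(
    n_detected = sum(detected),
    n_sites = length(detected),
    proportion = sum(detected) / length(detected)
  )
}

#' Read aligned survey tables from delimited text
#'
#' Reads a detection table, an optional count table, a site covariate table,
#' and optional observation covariates from CSV files and aligns them by site
#' identifier. Detection and count files are wide (one `site` column plus one
#' column per occasion). Observation covariates may be given either as a named
#' vector of wide per-covariate files or as a single long file with columns
#' `site`, `occasion`, `covariate`, `value`. Site ordering after load follows
#' the detection file; alignment is always by identifier, never row order.
#'
#' @param detection_path CSV of the detection history.
#' @param covariates_path CSV of site covariates.
#' @param counts_path optional CSV of the count history.
#' @param obs_covariates_path optional: named character vector of wide CSVs
#'   (names become covariate names) or a single long-format CSV.
#' @return list with elements `detection`, `counts` (may be `NULL`), and
#'   `covariates`.
#' @export
read_survey_tables <- function(detection_path, covariates_path,
                               counts_path = NULL, obs_covariates_path = NULL) {
  read_csv_quiet <- function(path) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    na = c("", "NA"))
  }
  det <- detection_history(read_csv_quiet(detection_path))
  ids <- det$site_ids

  cov_tbl <- read_csv_quiet(covariates_path)
  if (!"site" %in% names(cov_tbl)) abort("covariate file needs a `site` column")
  cov_tbl$site <- as.character(cov_tbl$site)
  if (!setequal(cov_tbl$site, ids)) {
    abort("site sets differ between detection and covariate files")
  }
  cov_tbl <- cov_tbl[match(ids, cov_tbl$site), ]

  counts <- NULL
  if (!is.null(counts_path)) {
    counts <- count_history(read_csv_quiet(counts_path))
    if (!setequal(counts$site_ids, ids)) {
      abort("site sets differ between detection and count files")
    }
    counts$c <- counts$c[match(ids, counts$site_ids), , drop = FALSE]
    counts$site_ids <- ids
  }

  obs <- list()
  if (!is.null(obs_covariates_path)) {
    if (length(obs_covariates_path) == 1L && is.null(names(obs_covariates_path))) {
      long <- read_csv_quiet(obs_covariates_path)
      need <- c("site", "occasion", "covariate", "value")
      if (!all(need %in% names(long))) {
        abort("long observation-covariate file needs columns site, occasion, covariate, value")
      }
      long$site <- as.character(long$site)
      obs <- purrr::map(split(long, long$covariate), function(d) {
        coerce_history_matrix(d[, c("site", "occasion", "value")],
                              "site", "occasion", "value")
      })
    } else {
      obs <- purrr::map(obs_covariates_path, function(p) {
        coerce_history_matrix(read_csv_quiet(p), "site", "occasion", "value")
      })
    }
    obs <- purrr::map(obs, function(m) {
      if (!setequal(rownames(m), ids)) {
        abort("site sets differ between detection and observation-covariate files")
      }
      m[match(ids, rownames(m)), , drop = FALSE]
    })
  }

  list(
    detection = det,
    counts = counts,
    covariates = covariate_bundle(cov_tbl, obs)
  )
}

#' Write survey tables as CSV
#'
#' Inverse of [read_survey_tables()]: writes the detection history, optional
#' count history, site covariates, and observation covariates (long format) so
#' a dataset round-trips through text unchanged.
#'
#' @param detection a [detection_history()].
#' @param covariates a [covariate_bundle()].
#' @param dir output directory (created if needed).
#' @param counts optional [count_history()].
#' @return invisibly, a named character vector of the files written.
#' @export
write_survey_tables <- function(detection, covariates, dir, counts = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(detection = file.path(dir, "detection.csv"),
             covariates = file.path(dir, "site_covariates.csv"))
  wide <- function(m) {
    out <- tibble::as_tibble(m, .name_repair = "minimal")
    names(out) <- paste0("occ_", seq_len(ncol(m)))
    dplyr::bind_cols(tibble::tibble(site = rownames(m)), out)
  }
  readr::write_csv(wide(detection$y), paths[["detection"]])
  readr::write_csv(covariates$site_table, paths[["covariates"]])
  if (!is.null(counts)) {
    paths[["counts"]] <- file.path(dir, "counts.csv")
    readr::write_csv(wide(counts$c), paths[["counts"]])
  }
  if (length(covariates$obs_tables)) {
    long <- purrr::imap(covariates$obs_tables, function(m, nm) {
      d <- history_to_long(m, "value")
      d$covariate <- nm
      d
    })
    long <- dplyr::bind_rows(long)[, c("site", "occasion", "covariate", "value")]
    paths[["obs_covariates"]] <- file.path(dir, "obs_covariates.csv")
    readr::write_csv(long, paths[["obs_covariates"]])
  }
  invisible(paths)
}
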