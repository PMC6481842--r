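#' Itemized survey cost ledger
#'
#' A cost ledger collects itemized cost lines for a monitoring design and the
#' design constants needed to amortize them. Each line has a unit cost in USD
#' and a set of multiplier counts (e.g. \eqn{\$55} per trip x 2 trips x 40
#' sites); its total is the unit cost times the product of the counts. Lines
#' are classified as `startup` (equipment, training) or `recurring` (fuel,
#' survey effort, laboratory work), and belong to a method arm: `ves`,
#' `edna_field`, or `edna_lab`. Laboratory overhead is computed once, as a
#' rate applied to the lab lines flagged `overhead_base` (supplies and
#' technician time), and folded into eDNA totals.
#'
#' @param label description of the line.
#' @param unit_cost unit cost in USD (non-negative).
#' @param counts numeric vector of multiplier counts (default 1).
#' @param category `"startup"` or `"recurring"`.
#' @param method `"ves"`, `"edna_field"`, or `"edna_lab"`.
#' @param overhead_base should this line enter the overhead base?
#' @return `cost_item()`: a one-row tibble. `cost_ledger()`: a tibble of class
#'   `cost_ledger` carrying the design as attributes.
#' @examples
#' fuel <- cost_item("Fuel cost", 55, counts = c(trips = 2, sites = 40),
#'                   category = "recurring", method = "ves")
#' line_total(fuel) # 4400
#' @export
cost_item <- function(label, unit_cost, counts = 1,
                      category = c("recurring", "startup"),
                      method = c("ves", "edna_field", "edna_lab"),
                      overhead_base = FALSE) {
  category <- match.arg(category)
  method <- match.arg(method)
  if (!is.finite(unit_cost) || unit_cost < 0) abort("unit_cost must be >= 0")
  if (any(!is.finite(counts)) || any(counts < 0)) abort("counts must be >= 0")
  tibble::tibble(
    label = label,
    unit_cost = unit_cost,
    counts = list(counts),
    category = category,
    method = method,
    overhead_base = overhead_base
  )
}

#' @rdname cost_item
#' @param items tibble of cost lines (rows from [cost_item()]).
#' @param n_sites number of sites in the design.
#' @param samples_per_site named numeric: replicates per site per method arm,
#'   e.g. `c(ves = 2, edna = 6)`.
#' @param overhead_rate overhead fraction applied to the overhead base.
#' @export
cost_ledger <- function(items, n_sites, samples_per_site,
                        overhead_rate = 0.33) {
  stopifnot(is.data.frame(items))
  if (n_sites <= 0 || any(samples_per_site <= 0)) {
    abort("design counts must be positive")
  }
  structure(
    tibble::as_tibble(items),
    n_sites = n_sites,
    samples_per_site = samples_per_site,
    overhead_rate = overhead_rate,
    class = c("cost_ledger", class(tibble::tibble()))
  )
}

#' Line totals of a cost ledger
#'
#' @param items a [cost_ledger()] or any tibble of cost lines.
#' @return numeric vector: `unit_cost * prod(counts)` per line.
#' @export
line_total <- function(items) {
  purrr::map2_dbl(items$unit_cost, items$counts, function(u, k) u * prod(k))
}

#' Laboratory overhead charge
#'
#' @param items ledger or tibble of cost lines; only rows with
#'   `overhead_base = TRUE` enter the base.
#' @param rate overhead fraction; defaults to the ledger's stored rate.
#' @return overhead charge in USD.
#' @export
overhead <- function(items, rate = NULL) {
  rate <- rate %||% attr(items, "overhead_rate") %||%
    abort("no overhead rate supplied or stored")
  if (rate < 0) abort("overhead rate must be >= 0")
  base <- items[items$overhead_base, , drop = FALSE]
  rate * sum(line_total(base))
}

#' Amortize ledger totals per study, site, and sample
#'
#' Sums the applicable line totals per method arm (`ves`, and `edna` =
#' field + laboratory + overhead), then divides by the number of sites and by
#' the number of samples (`n_sites * samples_per_site`). Startup lines
#' (equipment, training) are excluded unless `include_startup = TRUE`.
#'
#' @param ledger a [cost_ledger()].
#' @param include_startup include startup lines in the totals?
#' @return tibble with columns `method`, `per_study`, `per_site`,
#'   `per_sample`.
#' @examples
#' amortize(wood_turtle_cost_ledger())
#' @export
amortize <- function(ledger, include_startup = FALSE) {
  stopifnot(inherits(ledger, "cost_ledger"))
  n_sites <- attr(ledger, "n_sites")
  sps <- attr(ledger, "samples_per_site")
  rows <- if (include_startup) ledger else
    ledger[ledger$category == "recurring", , drop = FALSE]
  totals <- tibble::tibble(method = rows$method, total = line_total(rows))
  arm_total <- function(methods) {
    sum(totals$total[totals$method %in% methods])
  }
  oh <- overhead(ledger[ledger$category == "recurring", , drop = FALSE],
                 attr(ledger, "overhead_rate"))
  per_study <- c(
    ves = arm_total("ves"),
    edna = arm_total(c("edna_field", "edna_lab")) + oh
  )
  out <- tibble::tibble(
    method = names(per_study),
    per_study = unname(per_study),
    per_site = unname(per_study) / n_sites
  )
  out$per_sample <- out$per_study / (n_sites * unname(sps[out$method]))
  out
}

#' Built-in wood turtle monitoring cost ledger
#'
#' The itemized cost comparison for a 40-site wood turtle monitoring design:
#' visual encounter surveys (two surveys per site) versus eDNA sampling (six
#' filters per site: four samples plus two field blanks), with 33% laboratory
#' overhead on eDNA lab supplies and technician time. Unit costs are in USD.
#'
#' @return a [cost_ledger()].
#' @export
wood_turtle_cost_ledger <- function() {
  items <- dplyr::bind_rows(
    cost_item("Equipment: waders, nets, etc.", 740.0,
              category = "startup", method = "ves"),
    cost_item("Fuel cost per trip", 55.0, counts = c(trips_per_site = 2, sites = 40),
              method = "ves"),
    cost_item("Survey cost per survey", 220.32, counts = c(surveys_per_site = 2, sites = 40),
              method = "ves"),
    cost_item("Training: to develop observers", 6183.2,
              category = "startup", method = "ves"),
    cost_item("Field equipment & supplies", 1983.4,
              category = "startup", method = "edna_field"),
    cost_item("Fuel cost per trip", 55.0, counts = c(sites = 40),
              method = "edna_field"),
    cost_item("Survey cost per survey", 73.44, counts = c(sites = 40),
              method = "edna_field"),
    cost_item("Training: to develop field techniques", 128.4,
              category = "startup", method = "edna_field"),
    cost_item("Laboratory supplies", 2817.2,
              method = "edna_lab", overhead_base = TRUE),
    cost_item("Laboratory technician time", 1000.3,
              method = "edna_lab", overhead_base = TRUE)
  )
  cost_ledger(items, n_sites = 40,
              samples_per_site = c(ves = 2, edna = 6),
              overhead_rate = 0.33)
}
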