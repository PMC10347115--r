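#' Load the embedded 59-plot field table (vegetative stage)
#'
#' Returns the destructive-sampling ground truth for the 59 rice plots:
#' fresh weight, dry weight, water percentage, SPAD chlorophyll reading and
#' plant height, measured 90 days after sowing. Weights are grams per
#' 5-plant sampling unit (0.2 m2, 5 plants per linear meter). Only six plots'
#' genotype names are known (plots 4/24 IRBB 66, 36/44 Fedearroz 67,
#' 13/31 IR 64-21); the remaining labels are synthetic placeholders
#' \code{G01..G59}.
#'
#' @param path optional override of the packaged fixture CSV (used by tests).
#' @return data.frame with one row per plot and columns \code{plot_id},
#'   \code{genotype_id}, \code{fresh_g}, \code{dry_g}, \code{water_pct},
#'   \code{spad}, \code{height_cm}, \code{stage}.
#' @export
load_field_records <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "field_plots_vegetative.csv",
                        package = "ricecanopy", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "genotype_id", "fresh_g", "dry_g", "water_pct",
            "spad", "height_cm", "stage")
  if (!all(need %in% names(d)))
    stop("corrupt field-record fixture: ", path, " (missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), ")")
  if (anyNA(d[need]))
    stop("corrupt field-record fixture: ", path, " (missing values)")
  if (any(d$dry_g <= 0) || any(d$fresh_g < d$dry_g))
    stop("corrupt field-record fixture: ", path,
         " (weights violate fresh >= dry > 0)")
  d
}

#' Plant water content from fresh and dry weight
#'
#' Percentage of water in the sampled plant material:
#' \code{100 * (fresh - dry) / fresh}.
#'
#' @param fresh_weight fresh weight, g; must be positive.
#' @param dry_weight oven-dry weight, g; must satisfy 0 <= dry <= fresh.
#' @return water content in percent, in [0, 100]. Vectorized.
#' @examples
#' water_content(940, 260)   # 72.34
#' @export
water_content <- function(fresh_weight, dry_weight) {
  if (any(fresh_weight <= 0)) stop("fresh_weight must be positive")
  if (any(dry_weight < 0) || any(dry_weight > fresh_weight))
    stop("dry_weight must lie in [0, fresh_weight]")
  100 * (fresh_weight - dry_weight) / fresh_weight
}

#' Audit the printed water percentages against the weight columns
#'
#' Recomputes water content from the fresh/dry weights of each record and
#' compares with the printed one-decimal water percentage.
#'
#' @param records data.frame as from [load_field_records()].
#' @param tol tolerance in percentage points (default 0.05, i.e. one-decimal
#'   rounding of the printed value).
#' @return data.frame with \code{plot_id}, \code{printed}, \code{computed},
#'   \code{abs_diff}, \code{within_tol}.
#' @export
audit_water_content <- function(records, tol = 0.05) {
  computed <- water_content(records$fresh_g, records$dry_g)
  data.frame(plot_id = records$plot_id,
             printed = records$water_pct,
             computed = computed,
             abs_diff = abs(computed - records$water_pct),
             within_tol = abs(computed - records$water_pct) <= tol)
}

#' Summary statistics for a measured trait
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of one
#' trait over the records of a growth stage.
#'
#' @param records data.frame as from [load_field_records()].
#' @param variable one of \code{"fresh_weight"}, \code{"dry_weight"},
#'   \code{"spad"}, \code{"height"}, \code{"water_pct"}.
#' @param stage growth stage to subset on (default \code{"vegetative"}).
#' @return list with \code{variable}, \code{stage}, \code{mean}, \code{std},
#'   \code{n}.
#' @export
summarize_trait <- function(records, variable, stage = "vegetative") {
  col <- switch(variable,
                fresh_weight = "fresh_g", dry_weight = "dry_g",
                spad = "spad", height = "height_cm", water_pct = "water_pct",
                stop("unknown variable: ", variable))
  x <- records[[col]][records$stage == stage]
  if (length(x) < 2) stop("need at least 2 records for stage '", stage, "'")
  list(variable = variable, stage = stage,
       mean = mean(x), std = stats::sd(x), n = length(x))
}

#' Yield per area from a plot's dry weight
#'
#' Scales the dry weight of the sampling unit to kg/ha:
#' \code{(dry/1000) / (area/10000) = dry/area * 10}.
#'
#' @param dry_weight dry weight of the sampling unit, g.
#' @param sampling_area area of the sampling unit, m2 (default 0.2: five
#'   plants along one linear meter).
#' @return yield in kg/ha. Vectorized.
#' @examples
#' yield_per_area(200, 0.2)   # 10000 kg/ha
#' @export
yield_per_area <- function(dry_weight, sampling_area = 0.2) {
  if (any(sampling_area <= 0)) stop("sampling_area must be positive")
  dry_weight / sampling_area * 10
}

#' Daily biomass gain between vegetative sampling and harvest
#'
#' @param dry_harvest dry weight at harvest, g.
#' @param dry_vegetative dry weight at vegetative sampling, g.
#' @param interval_days days between the two samplings; must be positive.
#' @return gain in g/day (may be negative). Vectorized.
#' @export
biomass_gain_rate <- function(dry_harvest, dry_vegetative, interval_days) {
  if (any(interval_days <= 0)) stop("interval_days must be positive")
  (dry_harvest - dry_vegetative) / interval_days
}

#' Recompute all in-table statistics and the water-content audit
#'
#' Convenience driver over the embedded field table: trait summaries for
#' fresh weight, dry weight and SPAD, plus the per-plot water-content audit.
#'
#' @return list with \code{summaries} (data.frame) and \code{water_audit}
#'   (data.frame from [audit_water_content()]).
#' @export
run_field_analysis <- function() {
  rec <- load_field_records()
  vars <- c("fresh_weight", "dry_weight", "spad", "height")
  summaries <- do.call(rbind, lapply(vars, function(v) {
    s <- summarize_trait(rec, v)
    data.frame(variable = v, mean = s$mean, std = s$std, n = s$n)
  }))
  list(summaries = summaries, water_audit = audit_water_content(rec))
}
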