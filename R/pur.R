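#' Upper IQR outlier fence
#'
#' Fence = Q3 + 1.5 x (Q3 - Q1) on the application-rate distribution.
#' Quartiles use linear interpolation between order statistics (quantile
#' type 7) by default; the estimator is exposed as a parameter because
#' use-report cleaning should document its quantile convention.
#'
#' @param rates numeric vector, at least 4 finite positive values.
#' @param type quantile type passed to [stats::quantile()].
#' @return the fence (same units as `rates`).
#' @export
iqr_upper_fence <- function(rates, type = 7) {
  rates <- rates[is.finite(rates)]
  if (length(rates) < 4L || any(rates <= 0)) {
    stop("beescreen_fence_error: need >= 4 finite positive rates")
  }
  q <- stats::quantile(rates, c(0.25, 0.75), type = type, names = FALSE)
  q[2] + 1.5 * (q[2] - q[1])
}

#' Flag use records as outliers or likely entry errors
#'
#' A record is an `outlier` iff its rate is strictly above the IQR fence,
#' and a `likely_error` iff strictly above 10 x the highest commercial
#' label rate (more than one order of magnitude above any labeled use).
#' Both flags may co-occur; removal accounting treats outliers first and
#' reviews the remainder for errors (see [clean_use_records()]).
#'
#' @param records data.frame with a numeric `rate` column.
#' @param fence IQR upper fence, > 0.
#' @param max_label_rate highest label rate, > 0, same units as `rate`.
#' @return `records` with logical columns `outlier` and `likely_error`.
#' @export
flag_records <- function(records, fence, max_label_rate) {
  stopifnot(is.data.frame(records), "rate" %in% names(records))
  if (!is.finite(fence) || fence <= 0 ||
      !is.finite(max_label_rate) || max_label_rate <= 0) {
    stop("beescreen_flag_error: fence and max_label_rate must be > 0")
  }
  records$outlier <- records$rate > fence
  records$likely_error <- records$rate > 10 * max_label_rate
  records
}

#' Select the exposure application rate for a chemical
#'
#' If any records are flagged as neat-product uses, the maximum neat rate
#' is taken (the chemical alone, undiluted by blend ingredients). When no
#' neat products can be identified, the 90th percentile of all (mixture)
#' rates is used as a conservative stand-in for a neat-material maximum.
#'
#' @param records cleaned data.frame with `rate` and logical `neat` columns.
#' @param type quantile type for the 90th percentile.
#' @return list with `selected_rate`, `provenance` (`"neat_max"` or
#'   `"p90_mixture"`), `max_rate_neat` (NA when no neat records) and
#'   `p90_rate`.
#' @export
select_exposure_rate <- function(records, type = 7) {
  stopifnot(is.data.frame(records), "rate" %in% names(records))
  if (nrow(records) == 0L) {
    stop("beescreen_select_error: no records to select a rate from")
  }
  neat <- if ("neat" %in% names(records)) records$neat else
    rep(FALSE, nrow(records))
  p90 <- stats::quantile(records$rate, 0.9, type = type, names = FALSE)
  if (any(neat)) {
    list(selected_rate = max(records$rate[neat]), provenance = "neat_max",
         max_rate_neat = max(records$rate[neat]), p90_rate = p90)
  } else {
    list(selected_rate = p90, provenance = "p90_mixture",
         max_rate_neat = NA_real_, p90_rate = p90)
  }
}

#' Clean raw use-report records for one or more chemicals
#'
#' Two-pass cleaning mirroring the screening workflow: (1) harmonize units
#' to kg/ha, dropping (and counting) records with unparseable units;
#' (2) per group (chemical by default), compute the IQR fence and remove
#' outliers; (3) review the remainder and remove likely entry errors
#' (> 10 x the highest label rate); (4) select the exposure rate (neat max
#' or mixture 90th percentile).
#'
#' @param records data.frame with columns `chemical_id`, `rate`, `unit`,
#'   optionally `product_id`, `crop`, `month`, `neat`.
#' @param max_label_rate highest commercial label rate in kg/ha; a single
#'   value or named vector by chemical.
#' @param quantile_type quantile estimator type.
#' @param group_by `"chemical"` (fence per chemical over pooled crops) or
#'   `"chemical_crop"`.
#' @return list with `records` (cleaned, flags retained) and `summary`
#'   (one row per group: `n_total`, `n_unparseable`, `n_outliers`,
#'   `n_errors`, `upper_fence`, `max_rate_neat`, `p90_rate`,
#'   `selected_rate`, `provenance`).
#' @export
clean_use_records <- function(records, max_label_rate, quantile_type = 7,
                              group_by = c("chemical", "chemical_crop")) {
  group_by <- match.arg(group_by)
  stopifnot(is.data.frame(records),
            all(c("chemical_id", "rate", "unit") %in% names(records)))
  harm <- .harmonize_units(records)
  records <- harm$records
  key <- if (group_by == "chemical") records$chemical_id else
    paste(records$chemical_id, records$crop, sep = "\r")

  out_records <- list()
  out_summary <- list()
  for (g in unique(key)) {
    rec <- records[key == g, , drop = FALSE]
    lmax <- if (length(max_label_rate) > 1L) {
      max_label_rate[[rec$chemical_id[1L]]]
    } else max_label_rate
    fence <- iqr_upper_fence(rec$rate, type = quantile_type)
    rec <- flag_records(rec, fence, lmax)
    n_out <- sum(rec$outlier)
    keep1 <- rec[!rec$outlier, , drop = FALSE]
    n_err <- sum(keep1$likely_error)
    keep <- keep1[!keep1$likely_error, , drop = FALSE]
    if (nrow(keep) == 0L) {
      stop("beescreen_clean_error: all records removed for group ",
           rec$chemical_id[1L])
    }
    sel <- select_exposure_rate(keep, type = quantile_type)
    out_records[[g]] <- keep
    out_summary[[g]] <- data.frame(
      chemical_id = rec$chemical_id[1L],
      n_total = nrow(rec), n_unparseable = harm$n_dropped,
      n_outliers = n_out, n_errors = n_err,
      upper_fence = fence, max_rate_neat = sel$max_rate_neat,
      p90_rate = sel$p90_rate, selected_rate = sel$selected_rate,
      provenance = sel$provenance, stringsAsFactors = FALSE
    )
  }
  list(records = do.call(rbind, c(out_records, list(make.row.names = FALSE))),
       summary = do.call(rbind, c(out_summary, list(make.row.names = FALSE))))
}

# Convert supported unit spellings to kg/ha; unknown units are dropped.
.harmonize_units <- function(records) {
  u <- tolower(gsub("[ .]", "", records$unit))
  kg <- u %in% c("kg/ha", "kgperha", "kg_per_ha", "kgha")
  lb <- u %in% c("lb/acre", "lbperacre", "lb_per_acre", "lbacre", "lbs/acre")
  rate <- rep(NA_real_, nrow(records))
  rate[kg] <- records$rate[kg]
  rate[lb] <- convert_rate(records$rate[lb], "lb_per_acre", "kg_per_ha")
  keep <- !is.na(rate) & rate > 0
  records$rate <- rate
  records$unit <- "kg/ha"
  list(records = records[keep, , drop = FALSE], n_dropped = sum(!keep))
}
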