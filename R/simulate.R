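#' Configuration for the synthetic input generators
#'
#' Defaults define the study conditions the generators emulate:
#' \itemize{
#'   \item Use reports: label-compliant application rates follow a
#'     log-normal truncated at the highest label rate (growers report uses
#'     within the label), with a small fraction of gross entry errors —
#'     injected outliers well above the interquartile fence, and unit-entry
#'     mistakes that inflate a plausible rate by a fixed factor (x100,
#'     e.g. total pounds recorded in a per-acre field).
#'   \item Residue study: per-matrix first-order decay from an initial
#'     concentration with log-normal replicate noise, triplicate samples
#'     per day; values below the minimum detectable limit are emitted as
#'     censored.
#'   \item Acute bioassay: binomial deaths on a log-logistic
#'     dose-mortality curve.
#' }
#'
#' @param n_records number of use-report rows (>= 10).
#' @param rate_meanlog,rate_sdlog log-normal parameters of rates in kg/ha.
#' @param label_max highest label rate (kg/ha); clean rates are truncated
#'   here.
#' @param outlier_fraction,outlier_range fraction of injected outliers and
#'   the range (as multiples of the analytic fence) they are drawn from.
#' @param unit_error_fraction,unit_error_factor fraction and factor of
#'   injected unit-entry errors.
#' @param residue_matrices data.frame of per-matrix decay parameters
#'   (`matrix`, `c0`, `k`, `cv`, `loq`, `mdl`).
#' @param residue_days sampling days.
#' @param n_replicates replicate samples per matrix and day.
#' @param ld50,slope log-logistic dose-mortality parameters.
#' @param doses,n_per_dose acute bioassay design.
#' @param control_mortality background mortality rate for null bioassays.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_records = 1000,
                       rate_meanlog = 0, rate_sdlog = 0.6,
                       label_max = 2.0,
                       outlier_fraction = 0.01, outlier_range = c(2, 4),
                       unit_error_fraction = 0.005, unit_error_factor = 100,
                       residue_matrices = default_residue_matrices(),
                       residue_days = c(0, 1, 4, 7, 10),
                       n_replicates = 3,
                       ld50 = 50, slope = 4,
                       doses = c(12.5, 25, 50, 100, 200), n_per_dose = 10,
                       control_mortality = 0.1) {
  stopifnot(n_records >= 10, rate_sdlog >= 0, label_max > 0,
            outlier_fraction >= 0, outlier_fraction <= 1,
            unit_error_fraction >= 0, unit_error_fraction <= 1,
            unit_error_factor > 1, ld50 > 0, slope > 0,
            all(doses > 0), all(diff(doses) > 0), n_per_dose >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Per-matrix residue decay defaults
#'
#' Emulates the shape of an orchard residue study: pollen peaks near day
#' 0-1 far above nectar, larvae (jelly surrogate) lowest, with first-order
#' decline and modest replicate noise; limits of quantitation and minimum
#' detectable limits in the range of the analytical method.
#'
#' @return data.frame of matrix parameters.
#' @export
default_residue_matrices <- function() {
  data.frame(
    matrix = c("forager_pollen", "bee_bread", "forager_nectar",
               "stored_nectar", "larvae"),
    c0 = c(75, 40, 2.0, 0.2, 0.8),
    k = c(0.3, 0.15, 0.2, 0.1, 0.25),
    cv = c(0.2, 0.2, 0.2, 0.2, 0.2),
    loq = c(0.1, 0.1, 0.1, 0.1, 0.1),
    mdl = c(0.015, 0.010, 0.014, 0.014, 0.020),
    stringsAsFactors = FALSE
  )
}

# Analytic IQR fence of the label-truncated log-normal rate distribution.
.analytic_fence <- function(cfg) {
  if (cfg$rate_sdlog == 0) {
    stop("beescreen_sim_error: degenerate rate distribution (sd 0) has a ",
         "point-mass fence")
  }
  pmax <- stats::plnorm(cfg$label_max, cfg$rate_meanlog, cfg$rate_sdlog)
  q <- stats::qlnorm(c(0.25, 0.75) * pmax, cfg$rate_meanlog, cfg$rate_sdlog)
  q[2] + 1.5 * (q[2] - q[1])
}

#' Generate synthetic use-report records with truth labels
#'
#' Clean rates are label-truncated log-normal draws; `outlier_fraction` of
#' rows are replaced by rates drawn strictly above the analytic fence of
#' the clean distribution, and `unit_error_fraction` by a clean rate times
#' `unit_error_factor`. Truth labels (`true_outlier`, `true_unit_error`)
#' are returned for recovery testing.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; identical seeds give identical tables.
#' @return data.frame with `chemical_id`, `product_id`, `crop`, `rate`
#'   (kg/ha), `unit`, `month`, `neat`, `true_outlier`, `true_unit_error`.
#' @export
gen_use_records <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$rate_sdlog == 0 && cfg$outlier_fraction > 0) {
    stop("beescreen_sim_error: degenerate rate distribution (sd 0) has a ",
         "point-mass fence")
  }
  set.seed(seed)
  n <- cfg$n_records
  fence <- .analytic_fence(cfg)
  pmax <- stats::plnorm(cfg$label_max, cfg$rate_meanlog, cfg$rate_sdlog)
  rate <- stats::qlnorm(stats::runif(n, 0, pmax),
                        cfg$rate_meanlog, cfg$rate_sdlog)
  n_out <- round(cfg$outlier_fraction * n)
  n_err <- round(cfg$unit_error_fraction * n)
  idx <- sample.int(n, n_out + n_err)
  out_idx <- idx[seq_len(n_out)]
  err_idx <- idx[n_out + seq_len(n_err)]
  rate[out_idx] <- stats::runif(n_out, cfg$outlier_range[1] * fence,
                                cfg$outlier_range[2] * fence)
  # unit errors corrupt routine (upper three quartiles) applications: a
  # transcription mistake on a trace-level rate would be indistinguishable
  # from a legitimate use and is not part of the emulated error process
  base <- stats::qlnorm(stats::runif(n_err, 0.25 * pmax, pmax),
                        cfg$rate_meanlog, cfg$rate_sdlog)
  rate[err_idx] <- base * cfg$unit_error_factor
  crops <- c("almond", "grape", "citrus", "lettuce", "tomato")
  data.frame(
    chemical_id = "chem_a",
    product_id = sprintf("prod_%02d", sample.int(20, n, replace = TRUE)),
    crop = sample(crops, n, replace = TRUE),
    rate = rate, unit = "kg/ha",
    month = sample(1:12, n, replace = TRUE),
    neat = stats::runif(n) < 0.2,
    true_outlier = seq_len(n) %in% out_idx,
    true_unit_error = seq_len(n) %in% err_idx,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic residue study
#'
#' Per matrix, replicate concentrations follow first-order decay
#' `c0 * exp(-k * day)` with log-normal replicate noise of the configured
#' coefficient of variation; values below the matrix MDL are emitted as
#' censored at the MDL. Triplicate samples per matrix and day by default.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @param chemical_id label for the generated chemical.
#' @return parsed residue-sample data.frame compatible with
#'   [peak_by_group()].
#' @export
gen_residue_study <- function(cfg, seed = 1, chemical_id = "chem_a") {
  stopifnot(inherits(cfg, "sim_config"))
  m <- cfg$residue_matrices
  stopifnot(all(m$k >= 0), all(m$c0 >= 0))
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(m))) {
    for (d in cfg$residue_days) {
      mu <- m$c0[i] * exp(-m$k[i] * d)
      cv <- m$cv[i]
      if (cv > 0) {
        sdl <- sqrt(log(1 + cv^2))
        conc <- mu * stats::rlnorm(cfg$n_replicates, -sdl^2 / 2, sdl)
      } else {
        conc <- rep(mu, cfg$n_replicates)
      }
      cens <- conc < m$mdl[i]
      rows[[length(rows) + 1L]] <- data.frame(
        chemical_id = chemical_id, matrix = m$matrix[i], day = d,
        replicate = seq_len(cfg$n_replicates),
        conc = ifelse(cens, NA_real_, conc),
        censored = cens,
        censor_bound = ifelse(cens, m$mdl[i], NA_real_),
        loq = m$loq[i], mdl = m$mdl[i],
        plot_type = "treated", valid = TRUE,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic acute bioassay
#'
#' Deaths are binomial with log-logistic mortality
#' `p(d) = 1 / (1 + (LD50/d)^slope)`.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return a [quantal_dose_response()] with a clean negative control.
#' @export
gen_dose_response <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  p <- 1 / (1 + (cfg$ld50 / cfg$doses)^cfg$slope)
  dead <- stats::rbinom(length(cfg$doses), cfg$n_per_dose, p)
  quantal_dose_response(cfg$doses, rep(cfg$n_per_dose, length(cfg$doses)),
                        dead, control = list(n = cfg$n_per_dose, dead = 0L))
}
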