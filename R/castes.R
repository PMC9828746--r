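#' Honey bee caste diet table
#'
#' Daily food consumption by caste and life stage used to turn matrix
#' concentrations (mg/kg in nectar, pollen, royal jelly) into per-bee daily
#' doses (ug/bee/day). The three in-scope rows — the nectar forager, the
#' nurse (brood- and queen-tending) bee, and the 5-day-old worker larva —
#' are the castes whose maxima drive the reported adult and larval risk
#' quotients in the tier-1 model. The remaining rows are carried from the
#' public BeeREX v1.0 workbook for completeness and sensitivity work but are
#' flagged out of RQ scope by default: the queen's jelly-only diet is
#' computed and reported separately and never governs the reported adult RQ.
#'
#' @param in_scope_only if `TRUE`, return only the castes that participate
#'   in the reported risk-quotient maxima.
#' @return data.frame with columns `caste_id`, `life_stage` (`adult` or
#'   `larva`), `nectar_mg_per_day`, `pollen_mg_per_day`, `jelly_mg_per_day`,
#'   `in_rq_scope`.
#' @export
beerex_castes <- function(in_scope_only = FALSE) {
  tbl <- data.frame(
    caste_id = c(
      "nectar_forager", "nurse", "worker_larva_d5",
      "cell_cleaning_capping", "comb_building", "pollen_forager",
      "drone", "queen"
    ),
    life_stage = c(
      "adult", "adult", "larva",
      "adult", "adult", "adult",
      "adult", "adult"
    ),
    nectar_mg_per_day = c(292, 140, 120, 60, 60, 43.5, 235, 0),
    pollen_mg_per_day = c(0.041, 9.6, 3.6, 6.65, 1.7, 0.041, 0.0002, 0),
    jelly_mg_per_day = c(0, 0, 0, 0, 0, 0, 0, 525),
    in_rq_scope = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  if (in_scope_only) tbl <- tbl[tbl$in_rq_scope, , drop = FALSE]
  .validate_castes(tbl)
  tbl
}

.validate_castes <- function(castes) {
  need <- c("caste_id", "life_stage", "nectar_mg_per_day",
            "pollen_mg_per_day", "jelly_mg_per_day", "in_rq_scope")
  if (!all(need %in% names(castes))) {
    stop("beescreen_caste_error: caste table missing columns: ",
         paste(setdiff(need, names(castes)), collapse = ", "))
  }
  cons <- as.matrix(castes[, c("nectar_mg_per_day", "pollen_mg_per_day",
                               "jelly_mg_per_day")])
  if (any(!is.finite(cons)) || any(cons < 0)) {
    stop("beescreen_caste_error: consumptions must be finite and >= 0")
  }
  scope <- castes[castes$in_rq_scope, ]
  if (!any(scope$life_stage == "adult") || !any(scope$life_stage == "larva")) {
    stop("beescreen_caste_error: need at least one in-scope adult and larval caste")
  }
  invisible(castes)
}
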