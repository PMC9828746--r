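#' Define an application scenario
#'
#' Bundles a chemical's application rate with the exposure mode used to
#' derive food-matrix concentrations. In `default_rud` mode, nectar and
#' pollen concentrations are the residue unit dose (default 110 mg/kg per
#' lb a.i./acre, the tall-grass upper bound of the Kenaga nomogram) times
#' the application rate in lb a.i./acre. In `empirical` mode, measured peak
#' residues supplied via [empirical_residues()] are used instead. Contact
#' exposure always derives from the application rate through the contact
#' unit dose (default 2.7 ug/bee per lb a.i./acre).
#'
#' @param chemical_id character label.
#' @param rate application rate, >= 0 (total of all applications).
#' @param rate_unit `"kg_per_ha"` or `"lb_per_acre"`.
#' @param mode `"default_rud"` or `"empirical"`.
#' @param rud residue unit dose, mg/kg per lb a.i./acre; > 0.
#' @param contact_unit_dose ug/bee per lb a.i./acre; > 0.
#' @param residues an [empirical_residues()] object; required when
#'   `mode = "empirical"`.
#' @return an `application_scenario` object.
#' @export
application_scenario <- function(chemical_id, rate,
                                 rate_unit = c("kg_per_ha", "lb_per_acre"),
                                 mode = c("default_rud", "empirical"),
                                 rud = 110, contact_unit_dose = 2.7,
                                 residues = NULL) {
  rate_unit <- match.arg(rate_unit)
  mode <- match.arg(mode)
  stopifnot(is.character(chemical_id), length(chemical_id) == 1L,
            is.numeric(rate), length(rate) == 1L)
  if (!is.finite(rate) || rate < 0) {
    stop("beescreen_scenario_error: rate must be finite and >= 0")
  }
  if (!is.finite(rud) || rud <= 0) {
    stop("beescreen_scenario_error: rud must be > 0")
  }
  if (!is.finite(contact_unit_dose) || contact_unit_dose <= 0) {
    stop("beescreen_scenario_error: contact_unit_dose must be > 0")
  }
  if (mode == "empirical") {
    if (!inherits(residues, "empirical_residues")) {
      stop("beescreen_scenario_error: empirical mode requires an ",
           "empirical_residues record")
    }
  }
  structure(
    list(chemical_id = chemical_id, rate = rate, rate_unit = rate_unit,
         mode = mode, rud = rud, contact_unit_dose = contact_unit_dose,
         residues = residues),
    class = "application_scenario"
  )
}

#' Empirical residue concentrations for the exposure model
#'
#' Peak measured concentrations in the three food matrices, each with a
#' censoring provenance: `"measured"` when the peak is a quantified value,
#' `"loq_substituted"` when every sample in the matrix group was censored
#' and the limit of quantitation was used as a conservative stand-in.
#'
#' @param pollen_conc,nectar_conc,jelly_conc concentrations in mg/kg, >= 0.
#' @param provenance character vector of length 3 (pollen, nectar, jelly),
#'   values in `c("measured", "loq_substituted")`.
#' @return an `empirical_residues` object.
#' @export
empirical_residues <- function(pollen_conc, nectar_conc, jelly_conc,
                               provenance = rep("measured", 3)) {
  conc <- c(pollen = pollen_conc, nectar = nectar_conc, jelly = jelly_conc)
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("beescreen_residue_error: concentrations must be finite and >= 0")
  }
  provenance <- rep_len(provenance, 3L)
  if (!all(provenance %in% c("measured", "loq_substituted"))) {
    stop("beescreen_residue_error: unknown provenance value")
  }
  structure(list(pollen_conc = unname(pollen_conc),
                 nectar_conc = unname(nectar_conc),
                 jelly_conc = unname(jelly_conc),
                 provenance = stats::setNames(provenance,
                                              c("pollen", "nectar", "jelly"))),
            class = "empirical_residues")
}

#' Toxicity endpoints consumed by the risk characterization
#'
#' Acute endpoints in ug/bee, chronic in ug/bee/day; all must be > 0 when
#' present. Endpoints estimated only as "greater than the highest dose
#' tested" are used at face value (a conservative convention) with the
#' `is_greater_than` flag propagated into reports.
#'
#' @param adult_contact_ld50,adult_oral_ld50,larval_acute_ld50 acute
#'   endpoints, ug/bee (NA when unavailable).
#' @param adult_chronic_noed,larval_chronic_noed chronic no-observed-effect
#'   doses, ug/bee/day.
#' @param is_greater_than named logical vector flagging unbounded endpoints;
#'   names among the five endpoint arguments.
#' @param method optional named character vector recording the statistical
#'   provenance of each endpoint.
#' @return a `toxicity_profile` object.
#' @export
toxicity_profile <- function(adult_contact_ld50 = NA_real_,
                             adult_oral_ld50 = NA_real_,
                             adult_chronic_noed = NA_real_,
                             larval_acute_ld50 = NA_real_,
                             larval_chronic_noed = NA_real_,
                             is_greater_than = logical(),
                             method = character()) {
  vals <- c(adult_contact_ld50 = adult_contact_ld50,
            adult_oral_ld50 = adult_oral_ld50,
            adult_chronic_noed = adult_chronic_noed,
            larval_acute_ld50 = larval_acute_ld50,
            larval_chronic_noed = larval_chronic_noed)
  bad <- !is.na(vals) & (!is.finite(vals) | vals <= 0)
  if (any(bad)) {
    stop("beescreen_tox_error: endpoints must be > 0: ",
         paste(names(vals)[bad], collapse = ", "))
  }
  gt <- stats::setNames(rep(FALSE, 5L), names(vals))
  gt[names(is_greater_than)] <- is_greater_than
  structure(list(values = vals, is_greater_than = gt, method = method),
            class = "toxicity_profile")
}

#' Default-mode estimated environmental concentration
#'
#' EEC (mg/kg) in nectar and pollen under the default residue-unit-dose
#' model: `EEC = RUD x application rate` with the rate expressed in
#' lb a.i./acre.
#'
#' @param scenario an [application_scenario()] in `default_rud` mode.
#' @return concentration in mg/kg (applies to both nectar and pollen).
#' @export
default_eec <- function(scenario) {
  stopifnot(inherits(scenario, "application_scenario"))
  if (scenario$mode != "default_rud") {
    stop("beescreen_mode_error: default_eec requires default_rud mode")
  }
  scenario$rud * convert_rate(scenario$rate, scenario$rate_unit, "lb_per_acre")
}

#' Acute contact dose
#'
#' Per-bee contact dose (ug/bee) from direct spray: contact unit dose times
#' the application rate in lb a.i./acre. Applies in both exposure modes.
#'
#' @param scenario an [application_scenario()].
#' @return dose in ug/bee.
#' @export
contact_dose <- function(scenario) {
  stopifnot(inherits(scenario, "application_scenario"))
  scenario$contact_unit_dose *
    convert_rate(scenario$rate, scenario$rate_unit, "lb_per_acre")
}

#' Daily dietary dose for a caste
#'
#' Sum over food matrices of daily consumption (mg food) times matrix
#' concentration (mg/kg = ug/g), divided by 1000 to yield ug/bee/day.
#'
#' @param caste one row of the caste table (see [beerex_castes()]).
#' @param nectar_conc,pollen_conc,jelly_conc concentrations in mg/kg.
#' @return dose in ug/bee/day.
#' @export
dietary_dose <- function(caste, nectar_conc, pollen_conc, jelly_conc = 0) {
  conc <- c(nectar_conc, pollen_conc, jelly_conc)
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("beescreen_dose_error: concentrations must be finite and >= 0")
  }
  (caste$nectar_mg_per_day * nectar_conc +
     caste$pollen_mg_per_day * pollen_conc +
     caste$jelly_mg_per_day * jelly_conc) / 1000
}

#' Compute the tier-1 risk-quotient report for one chemical
#'
#' Derives nectar/pollen/jelly concentrations from the scenario (default
#' residue-unit-dose or empirical residues), computes per-caste daily doses,
#' and reports one row per life stage x exposure route:
#' \itemize{
#'   \item adult `acute_contact`: contact dose / adult contact LD50;
#'   \item adult `acute_dietary`: max in-scope adult daily dose / adult oral
#'     LD50 (the single-day dietary intake is the acute oral dose);
#'   \item adult `chronic_dietary`: same dose / adult chronic NOED;
#'   \item larval `acute_dietary` and `chronic_dietary` analogously over
#'     in-scope larval castes.
#' }
#' Verdicts compare each RQ with its level of concern: `below_loc` iff
#' RQ < LOC. Acute contact is not defined for larvae (in-cell larvae are
#' assessed through diet). Out-of-scope castes (queen, drone, ...) never
#' govern the reported maxima.
#'
#' @param scenario an [application_scenario()].
#' @param tox a [toxicity_profile()].
#' @param castes caste diet table, default [beerex_castes()].
#' @param locs named numeric, levels of concern `c(acute = 0.4, chronic = 1)`.
#' @return data.frame of class `rq_report` with columns `chemical_id`,
#'   `life_stage`, `route`, `eec_nectar`, `eec_pollen`, `eec_jelly`, `dose`,
#'   `endpoint`, `endpoint_is_greater_than`, `rq`, `governing_caste`, `loc`,
#'   `verdict`.
#' @export
compute_rq_report <- function(scenario, tox, castes = beerex_castes(),
                              locs = c(acute = 0.4, chronic = 1.0)) {
  stopifnot(inherits(scenario, "application_scenario"),
            inherits(tox, "toxicity_profile"))
  .validate_castes(castes)
  stopifnot(all(c("acute", "chronic") %in% names(locs)))

  if (scenario$mode == "default_rud") {
    eec <- default_eec(scenario)
    conc <- c(nectar = eec, pollen = eec, jelly = eec)
  } else {
    r <- scenario$residues
    conc <- c(nectar = r$nectar_conc, pollen = r$pollen_conc,
              jelly = r$jelly_conc)
  }

  scope <- castes[castes$in_rq_scope, , drop = FALSE]
  dose_of <- function(rows) {
    vapply(seq_len(nrow(rows)), function(i) {
      dietary_dose(rows[i, ], conc[["nectar"]], conc[["pollen"]],
                   conc[["jelly"]])
    }, 0)
  }
  adults <- scope[scope$life_stage == "adult", , drop = FALSE]
  larvae <- scope[scope$life_stage == "larva", , drop = FALSE]
  ad_dose <- dose_of(adults)
  la_dose <- dose_of(larvae)
  ad_gov <- adults$caste_id[which.max(ad_dose)]
  la_gov <- larvae$caste_id[which.max(la_dose)]

  need <- function(name, route) {
    v <- tox$values[[name]]
    if (is.na(v)) {
      stop("beescreen_endpoint_error: missing endpoint '", name,
           "' for route ", route)
    }
    v
  }
  cdose <- contact_dose(scenario)

  row <- function(stage, route, dose, ep_name, gov, loc_kind) {
    ep <- need(ep_name, paste(stage, route, sep = "/"))
    rq <- dose / ep
    data.frame(
      chemical_id = scenario$chemical_id, life_stage = stage, route = route,
      eec_nectar = conc[["nectar"]], eec_pollen = conc[["pollen"]],
      eec_jelly = conc[["jelly"]], dose = dose, endpoint = ep,
      endpoint_is_greater_than = unname(tox$is_greater_than[[ep_name]]),
      rq = rq, governing_caste = gov, loc = unname(locs[[loc_kind]]),
      verdict = if (rq < locs[[loc_kind]]) "below_loc" else "at_or_above_loc",
      stringsAsFactors = FALSE
    )
  }

  out <- rbind(
    row("adult", "acute_contact", cdose, "adult_contact_ld50", NA_character_,
        "acute"),
    row("adult", "acute_dietary", max(ad_dose), "adult_oral_ld50", ad_gov,
        "acute"),
    row("adult", "chronic_dietary", max(ad_dose), "adult_chronic_noed",
        ad_gov, "chronic"),
    row("larva", "acute_dietary", max(la_dose), "larval_acute_ld50", la_gov,
        "acute"),
    row("larva", "chronic_dietary", max(la_dose), "larval_chronic_noed",
        la_gov, "chronic")
  )
  class(out) <- c("rq_report", class(out))
  out
}

#' Presentation rounding for risk quotients
#'
#' Internal arithmetic is kept at full precision; for reporting, dietary
#' RQs are rounded to 2 significant figures and acute-contact RQs to 3,
#' mirroring regulatory report formatting.
#'
#' @param report an `rq_report` data.frame.
#' @return the report with an added `rq_display` column.
#' @export
format_rq_report <- function(report) {
  digits <- ifelse(report$route == "acute_contact", 3L, 2L)
  report$rq_display <- signif(report$rq, digits)
  report
}
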