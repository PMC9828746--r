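#' Packaged trisiloxane surfactant assessment inputs
#'
#' Loads the packaged inputs for the three trisiloxane polyether
#' surfactants: cleaned maximum use-report application rates and almond
#' orchard study application rates, laboratory toxicity endpoints (with
#' their statistical provenance and unbounded flags), and the replicate
#' residue-study table.
#'
#' @return list with `rates` (data.frame), `tox` (named list of
#'   [toxicity_profile()] objects), `residues` (parsed sample data.frame).
#' @export
surfactant_assessment_inputs <- function() {
  p <- function(f) system.file("extdata", f, package = "beescreen",
                               mustWork = TRUE)
  rates <- utils::read.csv(p("application_rates.csv"),
                           stringsAsFactors = FALSE)
  toxraw <- utils::read.csv(p("toxicity_endpoints.csv"),
                            stringsAsFactors = FALSE)
  tox <- lapply(split(toxraw, toxraw$chemical_id), function(d) {
    v <- stats::setNames(d$value, d$endpoint)
    gt <- stats::setNames(d$is_greater_than, d$endpoint)
    toxicity_profile(
      adult_contact_ld50 = v[["adult_contact_ld50"]],
      adult_oral_ld50 = v[["adult_oral_ld50"]],
      adult_chronic_noed = v[["adult_chronic_noed"]],
      larval_acute_ld50 = v[["larval_acute_ld50"]],
      larval_chronic_noed = v[["larval_chronic_noed"]],
      is_greater_than = gt[gt],
      method = stats::setNames(d$method, d$endpoint)
    )
  })
  residues <- read_residue_samples(p("residue_study.csv"))
  list(rates = rates, tox = tox, residues = residues)
}

#' Run the assessment in default residue-unit-dose mode
#'
#' One scenario per chemical at its cleaned maximum use-report application
#' rate, nectar/pollen concentrations from the default residue unit dose.
#'
#' @param inputs output of [surfactant_assessment_inputs()] (or a list with
#'   the same shape).
#' @param castes caste diet table.
#' @param locs levels of concern.
#' @param rud,contact_unit_dose exposure-model constants.
#' @return combined `rq_report` data.frame across chemicals.
#' @export
run_default_mode <- function(inputs = surfactant_assessment_inputs(),
                             castes = beerex_castes(),
                             locs = c(acute = 0.4, chronic = 1.0),
                             rud = 110, contact_unit_dose = 2.7) {
  out <- lapply(seq_len(nrow(inputs$rates)), function(i) {
    chem <- inputs$rates$chemical_id[i]
    sc <- application_scenario(chem, inputs$rates$pur_rate_kg_ha[i],
                               "kg_per_ha", "default_rud", rud = rud,
                               contact_unit_dose = contact_unit_dose)
    compute_rq_report(sc, inputs$tox[[chem]], castes, locs)
  })
  res <- do.call(rbind, out)
  class(res) <- c("rq_report", "data.frame")
  res
}

#' Run the assessment in empirical-residue mode
#'
#' One scenario per chemical at the orchard-study total application rate;
#' dietary concentrations are the residue-study peaks by matrix group
#' (pollen group, nectar group, larvae as jelly surrogate) with LOQ
#' substitution for fully censored groups. The contact route still uses
#' the application rate.
#'
#' @inheritParams run_default_mode
#' @param rule censoring substitution rule for fully censored groups.
#' @return combined `rq_report` data.frame across chemicals.
#' @export
run_empirical_mode <- function(inputs = surfactant_assessment_inputs(),
                               castes = beerex_castes(),
                               locs = c(acute = 0.4, chronic = 1.0),
                               contact_unit_dose = 2.7, rule = "loq") {
  out <- lapply(seq_len(nrow(inputs$rates)), function(i) {
    chem <- inputs$rates$chemical_id[i]
    samples <- inputs$residues[inputs$residues$chemical_id == chem, ,
                               drop = FALSE]
    peaks <- peak_by_group(samples, rule = rule)
    sc <- application_scenario(chem, inputs$rates$orchard_rate_kg_ha[i],
                               "kg_per_ha", "empirical",
                               contact_unit_dose = contact_unit_dose,
                               residues = peaks_to_residues(peaks))
    compute_rq_report(sc, inputs$tox[[chem]], castes, locs)
  })
  res <- do.call(rbind, out)
  class(res) <- c("rq_report", "data.frame")
  res
}

#' Render assessment outputs
#'
#' Writes, per mode, a CSV of the full-precision report, a JSON twin, and
#' a markdown summary with presentation-rounded values, the governing
#' caste per cell, level-of-concern verdicts, and a header logging every
#' constant used (residue unit dose, contact unit dose, caste table,
#' unit-conversion factor). The summary line states that no acute or
#' chronic risk is indicated only when every cell is below its level of
#' concern.
#'
#' @param reports named list of `rq_report` data.frames (e.g.
#'   `list(default = ..., empirical = ...)`); must be non-empty.
#' @param dir output directory (created if needed).
#' @param constants named list of model constants to log.
#' @return invisibly, the paths written.
#' @export
render_report <- function(reports, dir,
                          constants = list(rud = 110,
                                           contact_unit_dose = 2.7,
                                           lb_acre_per_kg_ha =
                                             .lb_acre_per_kg_ha)) {
  if (!is.list(reports) || length(reports) == 0L ||
      is.data.frame(reports)) {
    stop("beescreen_report_error: 'reports' must be a non-empty named list")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  md <- c("# Tier-1 pollinator risk assessment report", "",
          "## Constants",
          paste0("- ", names(constants), ": ",
                 vapply(constants, function(x) paste(format(x), collapse = " "),
                        "")),
          paste0("- caste table: ",
                 paste(beerex_castes(TRUE)$caste_id, collapse = ", ")), "")
  for (nm in names(reports)) {
    rep_i <- format_rq_report(reports[[nm]])
    csv <- file.path(dir, paste0("rq_", nm, ".csv"))
    utils::write.csv(rep_i, csv, row.names = FALSE)
    paths <- c(paths, csv)
    md <- c(md, paste0("## Mode: ", nm), "",
            "chemical | life stage | route | RQ | governing caste | LOC | verdict",
            "--- | --- | --- | --- | --- | --- | ---",
            sprintf("%s | %s | %s | %s | %s | %s | %s",
                    rep_i$chemical_id, rep_i$life_stage, rep_i$route,
                    format(rep_i$rq_display),
                    ifelse(is.na(rep_i$governing_caste), "-",
                           rep_i$governing_caste),
                    format(rep_i$loc), rep_i$verdict), "")
  }
  all_cells <- do.call(rbind, unname(reports))
  summary_line <- if (all(all_cells$verdict == "below_loc")) {
    "No acute or chronic risk indicated: all risk quotients are below their levels of concern."
  } else {
    "LEVEL OF CONCERN EXCEEDED for at least one life stage and route; higher-tier assessment indicated."
  }
  md <- c(md, "## Summary", "", summary_line)
  mdp <- file.path(dir, "report.md")
  writeLines(md, mdp)
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(constants = constants,
         reports = lapply(reports, format_rq_report),
         summary = summary_line),
    jp, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(paths, mdp, jp))
}

#' Read an assessment configuration file
#'
#' YAML (or JSON) configuration with keys `chemical`, `rate`, `rate_unit`,
#' `mode`, optional `rud`, `contact_unit_dose`, `residues`
#' (`pollen`/`nectar`/`jelly`), `tox` (five endpoint names), and `locs`
#' (`acute`/`chronic`).
#'
#' @param path configuration file.
#' @return list with an `application_scenario`, a `toxicity_profile` and
#'   `locs`, ready for [compute_rq_report()].
#' @export
read_assessment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  residues <- NULL
  if (!is.null(cfg$residues)) {
    residues <- empirical_residues(cfg$residues$pollen, cfg$residues$nectar,
                                   cfg$residues$jelly)
  }
  scenario <- application_scenario(
    cfg$chemical, cfg$rate, cfg$rate_unit,
    mode = if (is.null(cfg$mode)) "default_rud" else cfg$mode,
    rud = if (is.null(cfg$rud)) 110 else cfg$rud,
    contact_unit_dose = if (is.null(cfg$contact_unit_dose)) 2.7 else
      cfg$contact_unit_dose,
    residues = residues
  )
  tox <- do.call(toxicity_profile, cfg$tox)
  locs <- if (is.null(cfg$locs)) c(acute = 0.4, chronic = 1.0) else
    c(acute = cfg$locs$acute, chronic = cfg$locs$chronic)
  list(scenario = scenario, tox = tox, locs = locs)
}
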