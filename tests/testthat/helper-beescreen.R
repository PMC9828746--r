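# Shared fixtures built in code.

# A simple default-mode scenario.
make_scenario <- function(rate = 1, unit = "kg_per_ha", mode = "default_rud",
                          ...) {
  application_scenario("chem_x", rate, unit, mode, ...)
}

full_tox <- function(contact = 100, oral = 100, ad_noed = 10,
                     la_ld50 = 100, la_noed = 10) {
  toxicity_profile(adult_contact_ld50 = contact, adult_oral_ld50 = oral,
                   adult_chronic_noed = ad_noed, larval_acute_ld50 = la_ld50,
                   larval_chronic_noed = la_noed)
}

# Independent brute-force RQ recomputation: plain arithmetic over the
# caste table, no reuse of the package's dose helpers.
brute_force_rqs <- function(rate_kg_ha, rud, cud, nectar, pollen, tox_vals,
                            default_mode = TRUE) {
  lb <- rate_kg_ha * 0.892179
  if (default_mode) nectar <- pollen <- rud * lb
  forager <- (292 * nectar + 0.041 * pollen) / 1000
  nurse <- (140 * nectar + 9.6 * pollen) / 1000
  larva <- (120 * nectar + 3.6 * pollen) / 1000
  adult <- max(forager, nurse)
  c(acute_contact = cud * lb / tox_vals[["adult_contact_ld50"]],
    adult_acute = adult / tox_vals[["adult_oral_ld50"]],
    adult_chronic = adult / tox_vals[["adult_chronic_noed"]],
    larva_acute = larva / tox_vals[["larval_acute_ld50"]],
    larva_chronic = larva / tox_vals[["larval_chronic_noed"]])
}

get_rq <- function(report, chem, stage, route) {
  report$rq[report$chemical_id == chem & report$life_stage == stage &
              report$route == route]
}

get_caste <- function(report, stage, route) {
  report$governing_caste[report$life_stage == stage & report$route == route]
}
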