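test_that("default EEC follows RUD x rate in lb/acre", {
  expect_equal(default_eec(make_scenario(1, "lb_per_acre")), 110)
  expect_equal(default_eec(make_scenario(0)), 0)
  expect_equal(default_eec(make_scenario(1.42)), 139.4, tolerance = 5e-4)
  emp <- make_scenario(1, mode = "empirical",
                       residues = empirical_residues(1, 1, 1))
  expect_error(default_eec(emp), "beescreen_mode_error")
})

test_that("contact dose scales the rate by the contact unit dose", {
  expect_equal(contact_dose(make_scenario(0)), 0)
  d317 <- contact_dose(make_scenario(2.056))
  expect_equal(d317, 4.953, tolerance = 1e-3)
  # back-calculation oracle: printed contact RQ for the most toxic chemical
  expect_equal(d317 / 43.67, 0.113, tolerance = 5e-3)
  expect_equal(contact_dose(make_scenario(0.380)) / 100, 0.0092,
               tolerance = 2e-2)
})

test_that("dietary dose sums consumption x concentration over matrices", {
  castes <- beerex_castes()
  forager <- castes[castes$caste_id == "nectar_forager", ]
  nurse <- castes[castes$caste_id == "nurse", ]
  expect_equal(dietary_dose(forager, 139.4, 139.4), 40.71, tolerance = 1e-3)
  expect_equal(dietary_dose(nurse, 2.12, 76.2), 1.028, tolerance = 1e-3)
  expect_equal(dietary_dose(nurse, 0, 0, 0), 0)
  expect_error(dietary_dose(nurse, -1, 0), "beescreen_dose_error")
})

test_that("rq report reproduces printed chronic and larval cells", {
  loh <- compute_rq_report(make_scenario(0.404),
                           full_tox(contact = 100, oral = 100,
                                    ad_noed = 12.8, la_noed = 40))
  rq <- get_rq(loh, "chem_x", "adult", "chronic_dietary")
  expect_equal(rq, 0.90, tolerance = 6e-3)
  expect_equal(loh$verdict[loh$route == "chronic_dietary" &
                             loh$life_stage == "adult"], "below_loc")
  lac <- compute_rq_report(make_scenario(0.688), full_tox(la_ld50 = 100))
  expect_equal(get_rq(lac, "chem_x", "larva", "acute_dietary"), 0.084,
               tolerance = 1e-2)
})

test_that("zero rate gives all-zero RQs and below-LOC verdicts", {
  rep0 <- compute_rq_report(make_scenario(0), full_tox())
  expect_true(all(rep0$rq == 0))
  expect_true(all(rep0$verdict == "below_loc"))
})

test_that("missing endpoints are rejected with the route named", {
  tox <- toxicity_profile(adult_contact_ld50 = 100, adult_oral_ld50 = 100,
                          adult_chronic_noed = 10, larval_acute_ld50 = 100)
  expect_error(compute_rq_report(make_scenario(1), tox),
               "larval_chronic_noed.*larva/chronic_dietary")
})

test_that("default-mode RQs are linear in application rate", {
  tox <- full_tox()
  r1 <- compute_rq_report(make_scenario(0.7), tox)
  r2 <- compute_rq_report(make_scenario(1.4), tox)
  expect_equal(r2$rq, 2 * r1$rq, tolerance = 1e-12)
})

test_that("governing adult caste switches with the pollen/nectar balance", {
  tox <- full_tox()
  # equal concentrations (default RUD): the nectar forager dominates
  eq <- compute_rq_report(make_scenario(1), tox)
  expect_equal(get_caste(eq, "adult", "acute_dietary"), "nectar_forager")
  # pollen-dominated empirical residues: the nurse takes over
  po <- compute_rq_report(
    make_scenario(1, mode = "empirical",
                  residues = empirical_residues(100, 1, 0)), tox)
  expect_equal(get_caste(po, "adult", "acute_dietary"), "nurse")
  # consumption-ratio threshold: pollen/nectar exceeding
  # (292 - 140) / (9.6 - 0.041) ~ 15.9 flips the governing caste
  thr <- (292 - 140) / (9.6 - 0.041)
  below <- compute_rq_report(
    make_scenario(1, mode = "empirical",
                  residues = empirical_residues(thr * 0.95, 1, 0)), tox)
  above <- compute_rq_report(
    make_scenario(1, mode = "empirical",
                  residues = empirical_residues(thr * 1.05, 1, 0)), tox)
  expect_equal(get_caste(below, "adult", "acute_dietary"), "nectar_forager")
  expect_equal(get_caste(above, "adult", "acute_dietary"), "nurse")
})

test_that("rq report matches a brute-force recomputation on random scenarios", {
  set.seed(11)
  worst <- 0
  for (i in seq_len(1000)) {
    rate <- runif(1, 0, 3)
    nectar <- runif(1, 0, 100); pollen <- runif(1, 0, 100)
    tox_vals <- c(adult_contact_ld50 = runif(1, 10, 300),
                  adult_oral_ld50 = runif(1, 10, 300),
                  adult_chronic_noed = runif(1, 1, 100),
                  larval_acute_ld50 = runif(1, 10, 300),
                  larval_chronic_noed = runif(1, 1, 100))
    tox <- toxicity_profile(tox_vals[[1]], tox_vals[[2]], tox_vals[[3]],
                            tox_vals[[4]], tox_vals[[5]])
    default <- i %% 2 == 0
    sc <- if (default) make_scenario(rate) else
      make_scenario(rate, mode = "empirical",
                    residues = empirical_residues(pollen, nectar, 0))
    rep_i <- compute_rq_report(sc, tox)
    oracle <- brute_force_rqs(rate, 110, 2.7, nectar, pollen, tox_vals,
                              default_mode = default)
    got <- c(get_rq(rep_i, "chem_x", "adult", "acute_contact"),
             get_rq(rep_i, "chem_x", "adult", "acute_dietary"),
             get_rq(rep_i, "chem_x", "adult", "chronic_dietary"),
             get_rq(rep_i, "chem_x", "larva", "acute_dietary"),
             get_rq(rep_i, "chem_x", "larva", "chronic_dietary"))
    worst <- max(worst, max(abs(got - unname(oracle)) /
                              pmax(abs(oracle), 1e-12)))
  }
  expect_lt(worst, 1e-9)
})

test_that("scenario invariants are enforced", {
  expect_error(make_scenario(-1), "beescreen_scenario_error")
  expect_error(make_scenario(1, rud = 0), "beescreen_scenario_error")
  expect_error(make_scenario(1, mode = "empirical"),
               "beescreen_scenario_error")
  expect_error(toxicity_profile(adult_contact_ld50 = -5),
               "beescreen_tox_error")
})

test_that("presentation rounding keeps 2 sig figs (3 for contact)", {
  rep1 <- format_rq_report(compute_rq_report(make_scenario(2.056),
                                             full_tox(contact = 43.67)))
  expect_equal(rep1$rq_display[rep1$route == "acute_contact"], 0.113)
  expect_equal(signif(rep1$rq[rep1$route == "acute_dietary" &
                                rep1$life_stage == "adult"], 2),
               rep1$rq_display[rep1$route == "acute_dietary" &
                                 rep1$life_stage == "adult"])
})
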