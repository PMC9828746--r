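test_that("the <X censoring convention parses", {
  d <- parse_conc(data.frame(conc = c("2.12", "<0.0119"), loq = 0.1,
                             mdl = 0.0119, stringsAsFactors = FALSE))
  expect_equal(d$conc, c(2.12, NA))
  expect_equal(d$censored, c(FALSE, TRUE))
  expect_equal(d$censor_bound, c(NA, 0.0119))
  expect_error(parse_conc(data.frame(conc = "abc", loq = 1, mdl = 0.5)),
               "beescreen_residue_error")
  expect_error(parse_conc(data.frame(conc = "1", loq = 0.1, mdl = 0.2)),
               "MDL")
})

test_that("censoring substitution follows the rule and caps at LOQ", {
  d <- parse_conc(data.frame(conc = c("2.12", "<0.0119"), loq = 0.1,
                             mdl = 0.0119, stringsAsFactors = FALSE))
  expect_equal(substitute_censored(d, "loq")$conc_sub, c(2.12, 0.1))
  expect_equal(substitute_censored(d, "mdl")$conc_sub, c(2.12, 0.0119))
  expect_equal(substitute_censored(d, "half_loq")$conc_sub, c(2.12, 0.05))
  expect_equal(substitute_censored(d, "zero")$conc_sub, c(2.12, 0))
  expect_error(substitute_censored(d, "q95"))
  for (rule in c("loq", "mdl", "half_loq", "zero")) {
    s <- substitute_censored(d, rule)
    expect_true(all(s$conc_sub[s$censored] <= s$loq[s$censored]))
  }
})

test_that("orchard study fixture reduces to the exposure-model inputs", {
  inp <- surfactant_assessment_inputs()
  s317 <- inp$residues[inp$residues$chemical_id == "trisiloxane_317", ]
  p <- peak_by_group(s317)
  expect_equal(p$conc[p$input == "pollen"], 76.2)
  expect_equal(p$source_matrix[p$input == "pollen"], "forager_pollen")
  expect_equal(p$conc[p$input == "nectar"], 2.12)
  expect_equal(p$source_matrix[p$input == "nectar"], "forager_nectar")
  expect_equal(p$conc[p$input == "jelly"], 0.768)
  expect_true(all(p$provenance == "measured_peak"))

  sace <- inp$residues[inp$residues$chemical_id == "trisiloxane_acetoxy", ]
  pa <- peak_by_group(sace)
  expect_equal(pa$conc[pa$input == "nectar"], 0.1)
  expect_equal(pa$provenance[pa$input == "nectar"], "loq_substituted")
  expect_equal(pa$conc[pa$input == "jelly"], 0.1)
})

test_that("fully censored groups substitute the LOQ", {
  d <- parse_conc(data.frame(
    chemical_id = "x", matrix = c("forager_nectar", "stored_nectar",
                                  "forager_pollen", "larvae"),
    day = 0, conc = c("<0.05", "<0.05", "1.5", "<0.02"),
    loq = 0.1, mdl = c(0.05, 0.05, 0.02, 0.02), stringsAsFactors = FALSE))
  p <- peak_by_group(d)
  expect_equal(p$conc[p$input == "nectar"], 0.1)
  expect_equal(p$provenance[p$input == "nectar"], "loq_substituted")
  expect_equal(p$conc[p$input == "pollen"], 1.5)
  expect_error(peak_by_group(d[d$matrix != "larvae", ]),
               "beescreen_residue_error")
})

test_that("adding a sample can only raise or preserve group peaks", {
  cfg <- sim_config()
  d <- gen_residue_study(cfg, seed = 9)
  p0 <- peak_by_group(d)
  extra <- d[1, ]
  extra$conc <- max(d$conc, na.rm = TRUE) * 2
  extra$censored <- FALSE
  p1 <- peak_by_group(rbind(d, extra))
  expect_true(all(p1$conc >= p0$conc))
})

test_that("substitution rules order inputs by conservatism", {
  d <- parse_conc(data.frame(
    chemical_id = "x",
    matrix = c("forager_nectar", "forager_pollen", "larvae"),
    day = 0, conc = c("<0.05", "2.0", "<0.02"),
    loq = 0.1, mdl = c(0.05, 0.02, 0.02), stringsAsFactors = FALSE))
  v <- sapply(c("loq", "half_loq", "zero"), function(rule) {
    out <- tryCatch(peak_by_group(d, rule)$conc, error = function(e) NULL)
    if (is.null(out)) rep(0, 3) else out
  })
  # loq >= half_loq >= zero elementwise (zero rule errors: inputs must be > 0)
  expect_true(all(v[, "loq"] >= v[, "half_loq"]))
  expect_true(all(v[, "half_loq"] >= v[, "zero"]))
})

test_that("control residues above detection trigger a warning", {
  d <- parse_conc(data.frame(
    chemical_id = "x",
    matrix = c("forager_nectar", "forager_pollen", "larvae",
               "forager_pollen"),
    day = 0, conc = c("0.5", "2.0", "0.1", "0.9"),
    loq = 0.1, mdl = 0.02,
    plot_type = c("treated", "treated", "treated", "control"),
    stringsAsFactors = FALSE))
  expect_warning(peak_by_group(d), "control")
})

test_that("invalid and non-dietary matrices never feed the inputs", {
  d <- parse_conc(data.frame(
    chemical_id = "x",
    matrix = c("forager_nectar", "forager_pollen", "larvae", "wax",
               "whole_bees", "forager_pollen"),
    day = 0, conc = c("0.5", "2.0", "0.1", "99", "99", "50"),
    loq = 0.1, mdl = 0.02,
    valid = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE))
  p <- peak_by_group(d)
  expect_equal(p$conc[p$input == "pollen"], 2.0)  # wax/bees/invalid ignored
})
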