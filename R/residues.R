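#' Read replicate residue samples from CSV
#'
#' Expected columns: `chemical_id`, `matrix` (one of `forager_pollen`,
#' `bee_bread`, `forager_nectar`, `stored_nectar`, `larvae`, `wax`,
#' `whole_bees`), `day` (days after application), `conc` (mg/kg; the string
#' convention `"<X"` marks a value censored below the bound X, typically
#' the minimum detectable limit), `loq`, `mdl` (mg/kg). Optional columns:
#' `plot_type` (`treated`/`control`) and logical `valid` (matrices
#' invalidated e.g. by storage instability are excluded from peaks).
#'
#' @param path CSV file path.
#' @return data.frame with numeric `conc` (NA when censored), logical
#'   `censored`, and `censor_bound` (the bound a censored value was
#'   reported at).
#' @export
read_residue_samples <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(conc = "character"))
  parse_conc(raw)
}

#' Parse the `<X` censoring convention
#'
#' @param samples data.frame whose `conc` column may hold numbers or
#'   `"<X"` strings.
#' @return the data.frame with `conc` numeric, plus `censored` and
#'   `censor_bound` columns.
#' @export
parse_conc <- function(samples) {
  conc_chr <- trimws(as.character(samples$conc))
  cens <- startsWith(conc_chr, "<")
  val <- suppressWarnings(as.numeric(sub("^<", "", conc_chr)))
  if (any(is.na(val) & nzchar(conc_chr))) {
    stop("beescreen_residue_error: unparseable concentration values")
  }
  samples$conc <- ifelse(cens, NA_real_, val)
  samples$censored <- cens
  samples$censor_bound <- ifelse(cens, val, NA_real_)
  if (!"valid" %in% names(samples)) samples$valid <- TRUE
  if (!"plot_type" %in% names(samples)) samples$plot_type <- "treated"
  mdl_ok <- is.na(samples$mdl) | is.na(samples$loq) | samples$mdl <= samples$loq
  if (!all(mdl_ok)) {
    stop("beescreen_residue_error: MDL must not exceed LOQ")
  }
  samples
}

#' Substitute censored residue values
#'
#' Replaces censored entries with a value determined by `rule` for
#' downstream peak extraction; measured entries are never touched and no
#' substitution exceeds the LOQ.
#'
#' @param samples parsed residue samples (see [read_residue_samples()]).
#' @param rule one of `"loq"` (the conservative default used for the
#'   exposure inputs), `"mdl"`, `"half_loq"`, `"zero"`.
#' @return samples with a `conc_sub` column (measured value, or the
#'   substituted value for censored entries).
#' @export
substitute_censored <- function(samples, rule = c("loq", "mdl", "half_loq",
                                                  "zero")) {
  rule <- match.arg(rule)
  sub <- switch(rule,
    loq = samples$loq,
    mdl = samples$mdl,
    half_loq = samples$loq / 2,
    zero = 0
  )
  samples$conc_sub <- ifelse(samples$censored, sub, samples$conc)
  samples
}

#' Matrix groups feeding the three exposure-model inputs
#' @keywords internal
.residue_groups <- list(
  pollen = c("forager_pollen", "bee_bread"),
  nectar = c("forager_nectar", "stored_nectar"),
  jelly = "larvae"
)

#' Reduce a residue study to the three exposure-model inputs
#'
#' Pollen input = peak measured concentration over forager pollen and bee
#' bread across all sampling days; nectar input = peak over forager and
#' stored nectar; the jelly input uses larvae as a surrogate matrix. When
#' every sample in a group is censored, the matrix LOQ is substituted as a
#' conservative estimate (provenance `loq_substituted`). Control-plot
#' samples are checked to be fully censored (a warning is raised otherwise)
#' and excluded, as are matrices flagged invalid. Wax and whole-bee samples
#' never feed the dietary inputs.
#'
#' @param samples parsed residue samples for one chemical.
#' @param rule censoring substitution rule for fully-censored groups.
#' @return data.frame with one row per input (`pollen`, `nectar`, `jelly`):
#'   `conc` (mg/kg), `provenance`, `source_matrix`, `peak_day`.
#' @export
peak_by_group <- function(samples, rule = "loq") {
  stopifnot(is.data.frame(samples))
  ctrl <- samples[samples$plot_type == "control", , drop = FALSE]
  if (nrow(ctrl) > 0L && any(!ctrl$censored)) {
    warning("beescreen_residue_warning: control-plot samples with ",
            "quantified residues; excluded from peaks but worth review")
  }
  use <- samples[samples$plot_type != "control" & samples$valid, ,
                 drop = FALSE]
  out <- lapply(names(.residue_groups), function(gname) {
    grp <- use[use$matrix %in% .residue_groups[[gname]], , drop = FALSE]
    if (nrow(grp) == 0L) {
      stop("beescreen_residue_error: no samples in group '", gname, "'")
    }
    meas <- grp[!grp$censored, , drop = FALSE]
    if (nrow(meas) > 0L) {
      i <- which.max(meas$conc)
      data.frame(input = gname, conc = meas$conc[i],
                 provenance = "measured_peak",
                 source_matrix = meas$matrix[i], peak_day = meas$day[i],
                 stringsAsFactors = FALSE)
    } else {
      grp <- substitute_censored(grp, rule)
      i <- which.max(grp$conc_sub)
      data.frame(input = gname, conc = grp$conc_sub[i],
                 provenance = "loq_substituted",
                 source_matrix = grp$matrix[i], peak_day = NA_integer_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  if (any(out$conc <= 0)) {
    stop("beescreen_residue_error: exposure inputs must be > 0 after ",
         "substitution")
  }
  out
}

#' Convert grouped peaks to an [empirical_residues()] record
#'
#' @param peaks output of [peak_by_group()].
#' @return an `empirical_residues` object.
#' @export
peaks_to_residues <- function(peaks) {
  stopifnot(all(c("pollen", "nectar", "jelly") %in% peaks$input))
  get <- function(w) peaks[peaks$input == w, , drop = FALSE]
  empirical_residues(
    pollen_conc = get("pollen")$conc,
    nectar_conc = get("nectar")$conc,
    jelly_conc = get("jelly")$conc,
    provenance = c(
      ifelse(get("pollen")$provenance == "measured_peak", "measured",
             "loq_substituted"),
      ifelse(get("nectar")$provenance == "measured_peak", "measured",
             "loq_substituted"),
      ifelse(get("jelly")$provenance == "measured_peak", "measured",
             "loq_substituted")
    )
  )
}
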