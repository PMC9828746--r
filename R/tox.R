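#' Quantal dose-response data
#'
#' @param dose strictly increasing positive doses (ug/bee or ug/bee/day).
#' @param n_exposed,n_dead integer vectors per dose, 0 <= dead <= exposed.
#' @param control list with `n` and `dead` for the negative control.
#' @param solvent optional list with `n` and `dead` for a solvent control.
#' @return a `quantal_dose_response` object.
#' @export
quantal_dose_response <- function(dose, n_exposed, n_dead,
                                  control = NULL, solvent = NULL) {
  stopifnot(length(dose) == length(n_exposed),
            length(dose) == length(n_dead))
  if (any(dose <= 0) || any(diff(dose) <= 0)) {
    stop("beescreen_dr_error: doses must be positive and strictly increasing")
  }
  if (any(n_dead < 0) || any(n_dead > n_exposed)) {
    stop("beescreen_dr_error: need 0 <= n_dead <= n_exposed")
  }
  structure(list(dose = dose, n_exposed = n_exposed, n_dead = n_dead,
                 control = control, solvent = solvent),
            class = "quantal_dose_response")
}

# Weighted pool-adjacent-violators (non-decreasing fit).
.pava <- function(y, w) {
  n <- length(y)
  yb <- y; wb <- w; idx <- as.list(seq_len(n))
  k <- 1L
  while (k < length(yb)) {
    if (yb[k] > yb[k + 1L] + 1e-15) {
      nw <- wb[k] + wb[k + 1L]
      yb[k] <- (yb[k] * wb[k] + yb[k + 1L] * wb[k + 1L]) / nw
      wb[k] <- nw
      idx[[k]] <- c(idx[[k]], idx[[k + 1L]])
      yb <- yb[-(k + 1L)]; wb <- wb[-(k + 1L)]; idx <- idx[-(k + 1L)]
      if (k > 1L) k <- k - 1L
    } else k <- k + 1L
  }
  out <- numeric(n)
  for (b in seq_along(yb)) out[idx[[b]]] <- yb[b]
  out
}

# Trimmed Spearman-Karber mean of log10 dose over the monotonized
# piecewise-linear tolerance distribution. The curve is extended one
# dose-spacing beyond each end when it does not reach 0 or 1.
.tsk_point <- function(x, p, trim) {
  k <- length(x)
  if (p[1L] > 0) { x <- c(2 * x[1L] - x[2L], x); p <- c(0, p) }
  k <- length(x)
  if (p[k] < 1) { x <- c(x, 2 * x[k] - x[k - 1L]); p <- c(p, 1) }
  pL <- trim; pU <- 1 - trim
  tot <- 0
  for (i in seq_len(length(x) - 1L)) {
    a <- max(p[i], pL); b <- min(p[i + 1L], pU)
    if (b <= a) next
    dp <- p[i + 1L] - p[i]
    xa <- x[i] + (x[i + 1L] - x[i]) * (a - p[i]) / dp
    xb <- x[i] + (x[i + 1L] - x[i]) * (b - p[i]) / dp
    tot <- tot + (b - a) * (xa + xb) / 2
  }
  tot / (pU - pL)
}

#' Trimmed Spearman-Karber LD50 with 95% confidence limits
#'
#' Nonparametric LD50 estimator: observed mortality proportions are
#' monotonized by pool-adjacent-violators, the resulting empirical
#' tolerance distribution on log10 dose is (optionally) trimmed
#' symmetrically, and the LD50 is the mean of log dose over the trimmed
#' distribution. The variance of the estimate is obtained by the delta
#' method — a numeric gradient of the full monotonize-trim-average pipeline
#' with binomial variances p(1-p)/(n-1) at the adjusted proportions — and
#' confidence limits are back-transformed from the log scale. When no dose
#' reaches 50% mortality the estimate is reported as unbounded at the
#' highest dose tested, the convention used for screening endpoints.
#'
#' @param data a [quantal_dose_response()] object.
#' @param trim trimming fraction in `[0, 0.5)`; default 0 (untrimmed).
#' @param conf confidence level for the interval.
#' @return list of class `endpoint_estimate`: `kind = "ld50"`, `value`,
#'   `ci_low`, `ci_high`, `se_log10`, `method = "tsk"`, `unbounded`, `trim`.
#' @export
tsk_ld50 <- function(data, trim = 0, conf = 0.95) {
  stopifnot(inherits(data, "quantal_dose_response"))
  if (trim < 0 || trim >= 0.5) {
    stop("beescreen_tsk_error: trim must be in [0, 0.5)")
  }
  x <- log10(data$dose)
  n <- data$n_exposed
  praw <- data$n_dead / n
  pm <- .pava(praw, n)
  if (max(pm) < 0.5) {
    return(structure(list(kind = "ld50", value = max(data$dose),
                          ci_low = NA_real_, ci_high = NA_real_,
                          se_log10 = NA_real_, method = "tsk",
                          unbounded = TRUE, trim = trim),
                     class = "endpoint_estimate"))
  }
  if (min(pm) >= 1 - trim || max(pm) <= trim) {
    stop("beescreen_tsk_error: trimmed curve is empty")
  }
  est <- function(pr) .tsk_point(x, .pava(pr, n), trim)
  m <- est(praw)
  h <- 1e-5
  g <- vapply(seq_along(praw), function(i) {
    up <- praw; up[i] <- min(1, up[i] + h)
    dn <- praw; dn[i] <- max(0, dn[i] - h)
    (est(up) - est(dn)) / (up[i] - dn[i])
  }, 0)
  v <- sum(g^2 * pm * (1 - pm) / pmax(n - 1, 1))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  structure(list(kind = "ld50", value = 10^m,
                 ci_low = 10^(m - z * sqrt(v)),
                 ci_high = 10^(m + z * sqrt(v)),
                 se_log10 = sqrt(v), method = "tsk",
                 unbounded = FALSE, trim = trim),
            class = "endpoint_estimate")
}

# Williams-type amalgamated dose means: isotonic fit over dose-group means
# only (controls excluded from the amalgamation), adverse direction "up".
.williams_tstats <- function(group_means, group_n, ctrl_mean, ctrl_n, s2) {
  mu <- .pava(group_means, group_n)
  se <- sqrt(s2 * (1 / group_n + 1 / ctrl_n))
  (mu - ctrl_mean) / se
}

# Monte-Carlo null critical values for the Williams statistic at each dose
# position; cached per configuration. Group means are simulated directly
# (mean of n normals) and the pooled variance as a scaled chi-square.
.williams_cache <- new.env(parent = emptyenv())

williams_crit <- function(group_n, ctrl_n, alpha = 0.05, nsim = 10000,
                          seed = 1) {
  key <- paste(c(group_n, ctrl_n, alpha, nsim, seed), collapse = "_")
  if (!is.null(.williams_cache[[key]])) return(.williams_cache[[key]])
  k <- length(group_n)
  df <- sum(group_n - 1L) + (ctrl_n - 1L)
  tmat <- matrix(NA_real_, nsim, k)
  set.seed(seed)
  for (s in seq_len(nsim)) {
    gm <- stats::rnorm(k, 0, 1 / sqrt(group_n))
    cm <- stats::rnorm(1, 0, 1 / sqrt(ctrl_n))
    s2 <- stats::rchisq(1, df) / df
    tmat[s, ] <- .williams_tstats(gm, group_n, cm, ctrl_n, s2)
  }
  crit <- apply(tmat, 2, stats::quantile, probs = 1 - alpha, names = FALSE)
  .williams_cache[[key]] <- crit
  crit
}

#' Williams' test no-observed-effect dose
#'
#' Sequential comparison of amalgamated (isotonic) dose-group means against
#' the pooled control mean, from the highest dose downward, at one-sided
#' `alpha`. The NOED is the highest dose with no significant effect.
#' Critical values for the amalgamated t-type statistic are obtained by
#' seeded Monte-Carlo simulation of the null for the given design, rather
#' than transcribed tables.
#'
#' @param dose dose per group (ascending).
#' @param response list of replicate-level numeric responses per dose.
#' @param control numeric vector of pooled control replicate responses.
#' @param direction adverse direction of the response: `"decrease"` (e.g.
#'   survival or consumption-normalized performance), `"increase"` (e.g.
#'   mortality proportion), or `"auto"` (sign of the rank correlation).
#' @param alpha one-sided significance level.
#' @param nsim,seed Monte-Carlo draws and seed for the critical values.
#' @return list of class `endpoint_estimate` with `kind = "noed"`, `value`
#'   (NA when even the lowest dose shows an effect), `method = "williams"`,
#'   `status` (`"ok"`, `"all_doses_effect"`, or `"no_effect_at_any_dose"`)
#'   and the per-dose statistics.
#' @export
williams_noed <- function(dose, response, control,
                          direction = c("auto", "decrease", "increase"),
                          alpha = 0.05, nsim = 10000, seed = 1) {
  direction <- match.arg(direction)
  stopifnot(length(dose) >= 2L, length(response) == length(dose))
  reps <- lengths(response)
  if (any(reps < 2L) || length(control) < 2L) {
    stop("beescreen_williams_error: need >= 2 replicates per group")
  }
  means <- vapply(response, mean, 0)
  if (direction == "auto") {
    rho <- suppressWarnings(stats::cor(dose, means, method = "spearman"))
    direction <- if (!is.na(rho) && rho > 0) "increase" else "decrease"
  }
  flip <- if (direction == "decrease") -1 else 1
  ymeans <- flip * means
  ctrl_mean <- flip * mean(control)
  allv <- c(unlist(response), control)
  groups <- rep(seq_len(length(dose) + 1L), c(reps, length(control)))
  s2 <- sum(tapply(allv, groups, function(v) sum((v - mean(v))^2))) /
    (length(allv) - length(dose) - 1L)
  tstat <- if (s2 > 0) {
    .williams_tstats(ymeans, reps, ctrl_mean, length(control), s2)
  } else {
    ifelse(.pava(ymeans, reps) > ctrl_mean, Inf, 0)
  }
  crit <- williams_crit(reps, length(control), alpha, nsim, seed)
  sig <- tstat > crit
  k <- length(dose)
  noed <- NA_real_
  status <- "all_doses_effect"
  for (i in rev(seq_len(k))) {
    if (!sig[i]) { noed <- dose[i]; status <- "ok"; break }
  }
  if (status == "ok" && noed == dose[k]) status <- "no_effect_at_any_dose"
  structure(list(kind = "noed", value = noed, method = "williams",
                 status = status, statistic = tstat, critical = crit,
                 direction = direction, alpha = alpha),
            class = "endpoint_estimate")
}

#' Cochran-Armitage trend test (one-sided)
#'
#' Trend in mortality proportions across ordered groups (control plus
#' doses), one-sided toward increasing mortality with dose. Scores default
#' to the group order; the statistic is the standard normal deviate of the
#' score-weighted excess mortality.
#'
#' @param n,dead per-group totals (including the control as first group).
#' @param scores numeric scores, default `0:(k-1)`.
#' @return list with `z` and one-sided `p` (`greater`).
#' @export
ca_trend_test <- function(n, dead, scores = seq_along(n) - 1) {
  stopifnot(length(n) == length(dead), length(n) >= 2L)
  N <- sum(n); D <- sum(dead)
  pbar <- D / N
  if (pbar == 0 || pbar == 1) return(list(z = 0, p = 1))
  num <- sum(scores * (dead - n * pbar))
  den <- sqrt(pbar * (1 - pbar) *
                (sum(n * scores^2) - (sum(n * scores))^2 / N))
  z <- num / den
  list(z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

#' Step-down trend NOED (Cochran-Armitage)
#'
#' For monotone quantal data: test for trend over control plus all doses;
#' if significant at one-sided `alpha`, drop the highest dose and repeat.
#' The NOED is the highest dose in the first non-significant configuration.
#'
#' @param data a [quantal_dose_response()] with a negative control.
#' @param alpha one-sided significance level.
#' @return `endpoint_estimate` with `kind = "noed"`,
#'   `method = "cochran_armitage_stepdown"`, `value` (NA when the trend
#'   stays significant down to the lowest dose) and the per-step p-values.
#' @export
stepdown_trend_noed <- function(data, alpha = 0.05) {
  stopifnot(inherits(data, "quantal_dose_response"))
  if (length(data$dose) < 2L) {
    stop("beescreen_trend_error: need at least two dose groups")
  }
  if (is.null(data$control)) {
    stop("beescreen_trend_error: negative control required")
  }
  k <- length(data$dose)
  pvals <- rep(NA_real_, k)
  noed <- NA_real_
  status <- "all_doses_effect"
  for (top in rev(seq_len(k))) {
    idx <- seq_len(top)
    tt <- ca_trend_test(c(data$control$n, data$n_exposed[idx]),
                        c(data$control$dead, data$n_dead[idx]))
    pvals[top] <- tt$p
    if (tt$p >= alpha) { noed <- data$dose[top]; status <- "ok"; break }
  }
  if (status == "ok" && noed == data$dose[k]) status <- "no_effect_at_any_dose"
  structure(list(kind = "noed", value = noed,
                 method = "cochran_armitage_stepdown", status = status,
                 p_values = pvals, alpha = alpha),
            class = "endpoint_estimate")
}

# One-sided Fisher exact p for excess mortality in treatment vs control:
# hypergeometric upper tail (identical to fisher.test alternative "greater"
# on the dead/alive 2x2 table).
.fisher_one_sided <- function(dead_t, n_t, dead_c, n_c) {
  stats::phyper(dead_t - 1L, dead_t + dead_c,
                (n_t - dead_t) + (n_c - dead_c), n_t,
                lower.tail = FALSE)
}

#' Fisher-exact / Holm NOED
#'
#' For non-monotone quantal data: each dose is compared with the negative
#' control by a one-sided Fisher's exact test (excess mortality), p-values
#' are adjusted by the Holm step-down procedure across doses, and the NOED
#' is the highest dose with adjusted p >= `alpha` and no significant dose
#' below it.
#'
#' @param data a [quantal_dose_response()] with a negative control.
#' @param alpha significance level on adjusted p-values.
#' @return `endpoint_estimate` with `kind = "noed"`,
#'   `method = "fisher_holm"`, raw and adjusted p-values.
#' @export
fisher_holm_noed <- function(data, alpha = 0.05) {
  stopifnot(inherits(data, "quantal_dose_response"))
  if (is.null(data$control) || data$control$n == 0) {
    stop("beescreen_fisher_error: negative control required")
  }
  praw <- vapply(seq_along(data$dose), function(i) {
    .fisher_one_sided(data$n_dead[i], data$n_exposed[i],
                      data$control$dead, data$control$n)
  }, 0)
  padj <- stats::p.adjust(praw, method = "holm")
  sig <- padj < alpha
  k <- length(data$dose)
  noed <- NA_real_
  status <- "all_doses_effect"
  for (i in rev(seq_len(k))) {
    if (!sig[i] && !any(sig[seq_len(i)])) {
      noed <- data$dose[i]; status <- "ok"; break
    }
  }
  if (status == "ok" && noed == data$dose[k]) status <- "no_effect_at_any_dose"
  structure(list(kind = "noed", value = noed, method = "fisher_holm",
                 status = status, p_raw = praw, p_adjusted = padj,
                 alpha = alpha),
            class = "endpoint_estimate")
}

#' Choose the NOED procedure from the data's shape
#'
#' Continuous replicate-level data (with pooled controls) go to Williams'
#' test. Quantal data are screened for monotonicity: Spearman rank
#' correlation of mortality proportion against dose, requiring sign
#' consistency of all adjacent non-zero differences; monotone data go to
#' the Cochran-Armitage step-down, non-monotone to Fisher/Holm. The screen
#' is a documented operational rule, not a formal test.
#'
#' @param data a [quantal_dose_response()] or a list with `dose` and
#'   replicate-level `response` (continuous).
#' @return one of `"williams"`, `"cochran_armitage_stepdown"`,
#'   `"fisher_holm"`.
#' @export
decide_test <- function(data) {
  if (!inherits(data, "quantal_dose_response")) return("williams")
  p <- data$n_dead / data$n_exposed
  d <- diff(p)
  d <- d[d != 0]
  consistent <- length(d) == 0L || all(d > 0) || all(d < 0)
  rho <- suppressWarnings(stats::cor(data$dose, p, method = "spearman"))
  monotone <- consistent && (is.na(rho) || abs(rho) == 1)
  if (monotone) "cochran_armitage_stepdown" else "fisher_holm"
}

#' Compare negative and solvent controls
#'
#' Quantal controls are compared by a two-sided Fisher's exact test,
#' continuous ones by a two-sample t-test, at `alpha`. With no significant
#' difference (or no solvent control at all) the negative control is used
#' downstream; otherwise the solvent control is selected and flagged for
#' review.
#'
#' @param negative,solvent either lists with `n`/`dead` (quantal) or
#'   numeric replicate vectors (continuous); `solvent` may be NULL.
#' @param alpha significance level.
#' @return list with `choice` (`"pool_with_negative"` or `"use_solvent"`),
#'   `p_value`, `flagged`.
#' @export
compare_controls <- function(negative, solvent = NULL, alpha = 0.05) {
  if (is.null(solvent)) {
    return(list(choice = "pool_with_negative", p_value = NA_real_,
                flagged = FALSE))
  }
  p <- if (is.list(negative)) {
    tab <- matrix(c(solvent$dead, solvent$n - solvent$dead,
                    negative$dead, negative$n - negative$dead), nrow = 2)
    stats::fisher.test(tab)$p.value
  } else {
    if (stats::sd(negative) == 0 && stats::sd(solvent) == 0) {
      if (mean(negative) == mean(solvent)) 1 else 0
    } else stats::t.test(solvent, negative)$p.value
  }
  if (p < alpha) {
    list(choice = "use_solvent", p_value = p, flagged = TRUE)
  } else {
    list(choice = "pool_with_negative", p_value = p, flagged = FALSE)
  }
}
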