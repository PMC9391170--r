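#' Generate plausible reference ranges
#'
#' Draws `m` synthetic laboratory indicators: the lower bound uniform on
#' (0.5, 50) and the range width between 20% and 150% of the lower bound,
#' rounded to two decimals — the scale of common clinical analytes. Grid
#' policy follows the [reference_range()] defaults.
#'
#' @param m Number of indicators (at least 1).
#' @param seed Integer seed.
#' @return A list of `m` [reference_range()] objects named `ind01`, `ind02`,
#'   ...
#' @export
gen_ranges <- function(m, seed = 1L) {
  if (m < 1) stop("m must be at least 1", call. = FALSE)
  set.seed(seed)
  lows <- round(stats::runif(m, 0.5, 50), 2)
  widths <- round(lows * stats::runif(m, 0.2, 1.5), 2)
  widths <- pmax(widths, 0.1)
  lapply(seq_len(m), function(j) {
    reference_range(sprintf("ind%02d", j), lows[j], lows[j] + widths[j],
                    units = "U/L")
  })
}

#' Specification of a synthetic patient cohort
#'
#' The cohort emulates the structure of a hospital physical-examination
#' dataset: `m` continuous indicators with reference ranges, heavy class
#' imbalance (default one diabetic per nine nondiabetics), missing values,
#' and a disease label driven by how far values deviate from their normal
#' ranges. A latent disease state shifts the causal indicators above their
#' reference intervals; the label is Bernoulli with logit
#' `beta0 + sum_j beta_j * s_j`, where `s_j` in `-3..3` is the signed
#' severity band of indicator `j` (the same band rule the knowledge graph
#' uses).
#'
#' @param m Number of indicators.
#' @param n Number of patients.
#' @param causal_set Indicator positions with nonzero effect (default first
#'   three).
#' @param beta Effect size per severity step for causal indicators.
#' @param beta0 Intercept; `NULL` (default) calibrates it so the expected
#'   positive fraction matches `positive_fraction`.
#' @param positive_fraction Target fraction of diseased patients (default
#'   0.1, matching roughly 1:9 imbalance).
#' @param missing_rate Fraction of cells masked as missing, in [0, 1).
#' @param seed Integer seed.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(m = 11, n = 4000, causal_set = 1:3, beta = 1.5,
                        beta0 = NULL, positive_fraction = 0.1,
                        missing_rate = 0.05, seed = 1L) {
  stopifnot(m >= 1, n >= 1, all(causal_set >= 1), all(causal_set <= m),
            missing_rate >= 0, missing_rate < 1,
            positive_fraction > 0, positive_fraction < 1)
  betas <- rep(0, m)
  betas[causal_set] <- beta
  structure(list(m = as.integer(m), n = as.integer(n),
                 causal_set = as.integer(causal_set), betas = betas,
                 beta0 = beta0, positive_fraction = positive_fraction,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Strong-signal recovery cohort
#'
#' The benchmark condition for end-to-end parameter recovery: 4000 patients,
#' 11 indicators, 3 causal indicators with a saturating effect size (so
#' labels are deterministic given the values), balanced classes, and no
#' missingness (so the trained model sees the same information as the
#' generating rule it is measured against).
#'
#' @param seed Integer seed.
#' @param n Number of patients.
#' @return A `"cohort_spec"`.
#' @export
strong_signal_spec <- function(seed = 7L, n = 4000) {
  cohort_spec(m = 11, n = n, causal_set = 1:3, beta = 8,
              positive_fraction = 0.5, missing_rate = 0, seed = seed)
}

#' Generate a synthetic patient cohort
#'
#' Draws a latent disease state per patient at the target prevalence; causal
#' indicators of diseased patients are shifted 0.3-1.5 range-widths above the
#' upper normal bound (the generally/severely elevated bands), causal
#' indicators of healthy patients stay near mid-range, and non-causal
#' indicators scatter across bands independently of disease. Labels follow
#' the logistic band model of [cohort_spec()]; cells are then masked missing
#' at `missing_rate`. The latent truth (severities, probabilities) is
#' returned for oracle checks. Deterministic given `spec$seed`.
#'
#' @param ranges List of [reference_range()] objects, one per indicator.
#' @param spec A [cohort_spec()].
#' @return A list with `patients` (data frame of indicator columns plus
#'   `label`), `truth` (list with `z`, `severity`, `logit`, `prob`, `beta0`,
#'   `values` — the unmasked measurements), and `spec`.
#' @export
gen_cohort <- function(ranges, spec) {
  stopifnot(inherits(spec, "cohort_spec"), length(ranges) == spec$m)
  set.seed(spec$seed)
  n <- spec$n; m <- spec$m
  z <- stats::rbinom(n, 1, spec$positive_fraction)
  vals <- matrix(0, n, m)
  for (j in seq_len(m)) {
    r <- ranges[[j]]
    w <- r$high - r$low
    mid <- (r$low + r$high) / 2
    if (j %in% spec$causal_set) {
      v <- mid + stats::rnorm(n, 0, w / 4)
      shift <- r$high + stats::runif(n, 0.3, 1.5) * w
      v[z == 1] <- shift[z == 1]
    } else {
      v <- mid + stats::rnorm(n, 0, w / 2)
    }
    vals[, j] <- pmax(round(v, 4), 0)
  }
  sev <- vapply(seq_len(m),
                function(j) band_index(vals[, j], ranges[[j]]),
                integer(n))
  lin <- drop(sev %*% spec$betas)
  beta0 <- spec$beta0
  if (is.null(beta0)) {
    beta0 <- calibrate_intercept(lin, spec$positive_fraction)
  }
  logit <- beta0 + lin
  prob <- stats::plogis(logit)
  y <- stats::rbinom(n, 1, prob)

  masked <- vals
  if (spec$missing_rate > 0) {
    miss <- matrix(stats::runif(n * m) < spec$missing_rate, n, m)
    masked[miss] <- NA_real_
  }
  patients <- as.data.frame(masked)
  names(patients) <- vapply(ranges, `[[`, "", "indicator")
  patients$label <- y
  list(patients = patients,
       truth = list(z = z, severity = sev, logit = logit, prob = prob,
                    beta0 = beta0, values = vals),
       spec = spec)
}

# choose beta0 so that mean(plogis(beta0 + lin)) hits the target prevalence
calibrate_intercept <- function(lin, target) {
  f <- function(b0) mean(stats::plogis(b0 + lin)) - target
  lo <- -80; hi <- 80
  if (f(lo) > 0 || f(hi) < 0) return(stats::qlogis(target) - mean(lin))
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Bayes-optimal accuracy of a generated cohort
#'
#' The accuracy of the oracle rule that thresholds the true label
#' probability at 0.5 — the ceiling against which a trained model's accuracy
#' is judged.
#'
#' @param cohort Output of [gen_cohort()] (must retain `truth`).
#' @return Fraction in [0, 1].
#' @export
expected_bayes_accuracy <- function(cohort) {
  if (is.null(cohort$truth) || is.null(cohort$truth$prob)) {
    stop("cohort has no retained latent truth", call. = FALSE)
  }
  mean((cohort$truth$prob > 0.5) == cohort$patients$label)
}
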