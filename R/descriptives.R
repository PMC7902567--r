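# Cohort descriptives around the main model: relative dose intensity,
# adverse-event relative risks with Katz log-normal intervals, and
# age-probability curves from spline logistic regression.

#' Relative dose intensity
#'
#' Delivered dose intensity (mg/m2 per week) as a percentage of the planned
#' intensity. Scale-invariant to the time unit as long as numerator and
#' denominator use the same one.
#'
#' @param planned planned intensity, > 0 (mg/m2 per week).
#' @param delivered delivered intensity, >= 0 (same unit).
#' @return percentage (vectorized).
#' @examples
#' rdi(planned = 75 / 3, delivered = 75 / 4)  # 75
#' @export
rdi <- function(planned, delivered) {
  if (any(!is.finite(planned)) || any(planned <= 0))
    stop("planned intensity must be positive", call. = FALSE)
  if (any(delivered < 0))
    stop("delivered intensity must be nonnegative", call. = FALSE)
  100 * delivered / planned
}

#' Relative risk from a 2x2 table with a Katz log-normal interval
#'
#' RR = (a/n1) / (b/n2), with the 95% confidence interval from the
#' log-normal (Katz) approximation. When a zero cell makes the log-RR
#' variance undefined, 0.5 is added to every cell (continuity correction) and
#' the result is flagged.
#'
#' @param a,n1 events and total in the exposed (e.g. DPF) group.
#' @param b,n2 events and total in the reference (e.g. PF) group.
#' @return list with `rr`, `ci` (length-2), and `corrected` (logical flag
#'   for the continuity correction).
#' @examples
#' relative_risk(76, 238, 250, 1138)  # RR ~ 1.45
#' @export
relative_risk <- function(a, n1, b, n2) {
  ok <- all(is.finite(c(a, n1, b, n2))) && n1 > 0 && n2 > 0 &&
    a >= 0 && a <= n1 && b >= 0 && b <= n2
  if (!ok) stop("invalid 2x2 table", call. = FALSE)
  if (b == 0 && a == 0) stop("relative risk undefined: no events",
                             call. = FALSE)
  corrected <- a == 0 || b == 0 || a == n1 || b == n2
  if (corrected) { a <- a + 0.5; b <- b + 0.5; n1 <- n1 + 1; n2 <- n2 + 1 }
  rr <- (a / n1) / (b / n2)
  se <- sqrt(1 / a - 1 / n1 + 1 / b - 1 / n2)
  list(rr = rr, ci = rr * exp(c(-1, 1) * 1.96 * se), corrected = corrected)
}

#' Adverse-event relative-risk table
#'
#' Long-format counts (one row per adverse-event term) to a forest-plot-ready
#' table, with the doublet (PF) arm as the reference by default.
#'
#' @param counts data.frame with columns `term`, `events_dpf`, `total_dpf`,
#'   `events_pf`, `total_pf`.
#' @param reference `"PF"` (default: RR = DPF risk / PF risk) or `"DPF"`.
#' @return data.frame `term`, `rr`, `ci_lo`, `ci_hi`, `corrected`, sorted by
#'   decreasing `rr`.
#' @export
ae_relative_risks <- function(counts, reference = c("PF", "DPF")) {
  reference <- match.arg(reference)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- if (reference == "PF")
      relative_risk(counts$events_dpf[i], counts$total_dpf[i],
                    counts$events_pf[i], counts$total_pf[i])
    else
      relative_risk(counts$events_pf[i], counts$total_pf[i],
                    counts$events_dpf[i], counts$total_dpf[i])
    data.frame(term = counts$term[i], rr = r$rr, ci_lo = r$ci[1],
               ci_hi = r$ci[2], corrected = r$corrected,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$rr), , drop = FALSE]
}

#' Probability of a binary trait as a nonlinear function of age
#'
#' Logistic regression of a binary outcome on a restricted cubic spline
#' basis of age (3 knots by default), fitted by iteratively reweighted least
#' squares; returns the fitted probabilities on an age grid, reproducing the
#' age-pattern panels used to describe treatment allocation and tumor traits.
#'
#' @param outcome 0/1 vector (both classes must be present).
#' @param age numeric age vector.
#' @param grid ages at which to evaluate the curve (default: range of `age`).
#' @param knots number of spline knots, default 3.
#' @return data.frame with `age` and fitted probability `p`.
#' @export
age_probability_curve <- function(outcome, age, grid = NULL, knots = 3) {
  stopifnot(length(outcome) == length(age))
  if (length(unique(outcome)) < 2)
    stop("both outcome classes must be present", call. = FALSE)
  if (is.null(grid)) grid <- seq(min(age), max(age), length.out = 101)
  kn <- default_knots(age, knots)
  B <- rcs_basis(age, kn)
  fit <- stats::glm(outcome ~ B, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100))
  degenerate <- all(fit$fitted.values < 1e-6 | fit$fitted.values > 1 - 1e-6)
  if (!fit$converged || degenerate || any(abs(stats::coef(fit)) > 1e3))
    stop("logistic fit did not converge (possible complete separation); ",
         "consider coarser age groups", call. = FALSE)
  Bg <- rcs_basis(grid, kn)
  eta <- stats::coef(fit)[1] + drop(Bg %*% stats::coef(fit)[-1])
  data.frame(age = grid, p = stats::plogis(eta))
}
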