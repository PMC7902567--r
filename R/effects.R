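# Posterior estimands on the time-ratio scale: credible intervals,
# exceedance probabilities, region-of-practical-equivalence mass,
# profile-conditional subgroup effects, effect-by-covariate curves, and the
# individualized median-survival calculator.

summarize_coef_draws <- function(b, label, thresholds = c(1.15, 1.30),
                                 rope_halfwidth = 0.10) {
  stopifnot(is.numeric(b), length(b) > 0)
  qs <- stats::quantile(exp(b), c(0.025, 0.975), names = FALSE, type = 7)
  out <- list(
    label = label,
    tr = exp(stats::median(b)),
    cri = c(lower = qs[1], upper = qs[2]),
    p_gt_115 = mean(b > log(thresholds[1])),
    p_gt_130 = mean(b > log(thresholds[2])),
    rope_mass = mean(abs(b) <= log(1 + rope_halfwidth)),
    draws = b)
  class(out) <- "effect_summary"
  out
}

#' @export
print.effect_summary <- function(x, ...) {
  cat(sprintf("%s: TR %.3f (95%% CrI %.3f-%.3f); P(TR>1.15) %.3f; ",
              x$label, x$tr, x$cri[1], x$cri[2], x$p_gt_115),
      sprintf("P(TR>1.30) %.3f; ROPE mass %.3f\n", x$p_gt_130, x$rope_mass),
      sep = "")
  invisible(x)
}

#' Posterior effect summary on the time-ratio scale
#'
#' Summarizes the posterior draws of one coefficient as a time ratio
#' (posterior median of `exp(beta)`), its 95% equal-tailed credible interval,
#' the exceedance probabilities P(TR > 1.15) and P(TR > 1.30), and the mass
#' inside the region of practical equivalence `|beta| <= log(1 +
#' rope_halfwidth)` (effect = 0 +/- 10% by default, read on the coefficient
#' scale).
#'
#' @param draws a `posterior_draws`.
#' @param label coefficient label present in the draws.
#' @param thresholds two increasing TR exceedance thresholds,
#'   default `c(1.15, 1.30)`.
#' @param rope_halfwidth half-width of the practical-equivalence region on
#'   the TR-minus-one scale, default 0.10.
#' @return object of class `effect_summary` with fields `label`, `tr`, `cri`,
#'   `p_gt_115`, `p_gt_130`, `rope_mass` and the per-draw coefficients.
#' @export
effect_summary <- function(draws, label, thresholds = c(1.15, 1.30),
                           rope_halfwidth = 0.10) {
  summarize_coef_draws(param_draws(draws, label), label, thresholds,
                       rope_halfwidth)
}

conditional_coef_draws <- function(draws, design, profile) {
  b <- param_draws(draws, design$treatment_label)
  mult <- interaction_multipliers(design, profile)
  M <- draws_matrix(draws)
  for (lab in names(mult))
    if (mult[[lab]] != 0) b <- b + mult[[lab]] * M[, lab]
  b
}

#' Profile-conditional treatment effect
#'
#' For a patient profile, combines the main treatment coefficient with the
#' treatment-by-covariate interaction coefficients (dummy- or
#' spline-expanded, per draw) to give the conditional log time ratio, and
#' summarizes it like [effect_summary()].
#'
#' @param draws a `posterior_draws` from a fit of the interaction model.
#' @param design the [aft_design] the model was fitted on.
#' @param profile named list supplying a raw value for every interacting
#'   covariate (extra entries are ignored).
#' @param thresholds,rope_halfwidth passed to the summary.
#' @return an `effect_summary`.
#' @export
conditional_effect <- function(draws, design, profile,
                               thresholds = c(1.15, 1.30),
                               rope_halfwidth = 0.10) {
  b <- conditional_coef_draws(draws, design, profile)
  lab <- paste0(design$treatment_label, " | ",
                paste(vapply(intersect(unique(design$map$covariate[
                  design$map$class == "interaction"]), names(profile)),
                  function(v) paste0(v, "=", profile[[v]]), ""),
                  collapse = ", "))
  summarize_coef_draws(b, lab, thresholds, rope_halfwidth)
}

#' Treatment effect as a function of a continuous covariate
#'
#' Evaluates the conditional treatment effect over a grid of values of one
#' interacting continuous covariate (all other interacting covariates held at
#' the supplied profile), reusing the same posterior draws at every grid
#' point so the curve is smooth up to the spline basis.
#'
#' @param draws a `posterior_draws`.
#' @param design the [aft_design].
#' @param covariate name of the interacting continuous covariate.
#' @param grid numeric grid of raw covariate values.
#' @param profile values for any other interacting covariates.
#' @param thresholds,rope_halfwidth passed to the summaries.
#' @return data.frame with one row per grid point: `value`, `tr`, `cri_lo`,
#'   `cri_hi`, `p_gt_115`, `p_gt_130`, `rope_mass`.
#' @export
effect_curve <- function(draws, design, covariate, grid, profile = list(),
                         thresholds = c(1.15, 1.30), rope_halfwidth = 0.10) {
  int_cov <- unique(design$map$covariate[design$map$class == "interaction"])
  if (!covariate %in% int_cov)
    stop("'", covariate, "' has no declared treatment interaction",
         call. = FALSE)
  meta <- design$meta[[covariate]]
  if (!is.null(meta$knots)) {
    z <- ((if (meta$log) log(grid) else grid) - meta$center) / meta$scale
    if (any(z < meta$knots[1] | z > meta$knots[length(meta$knots)]))
      warning("grid extends beyond the boundary knots; the restricted ",
              "spline extrapolates linearly there", call. = FALSE)
  }
  rows <- lapply(grid, function(g) {
    pf <- profile
    pf[[covariate]] <- g
    s <- conditional_effect(draws, design, pf, thresholds, rope_halfwidth)
    data.frame(value = g, tr = s$tr, cri_lo = s$cri[1], cri_hi = s$cri[2],
               p_gt_115 = s$p_gt_115, p_gt_130 = s$p_gt_130,
               rope_mass = s$rope_mass)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Individualized posterior median survival
#'
#' The calculator behind individualized predictions: for a complete covariate
#' profile and arm, each posterior draw implies a lognormal median event time
#' `exp(x'beta)`; the function returns the posterior median and 95% credible
#' interval of that quantity. The per-draw DPF/PF ratio of predicted medians
#' equals the profile-conditional time-ratio draws exactly.
#'
#' @param draws a `posterior_draws`.
#' @param design the [aft_design].
#' @param profile named list with a raw value for every model covariate.
#' @param arm treatment level (one of the design's two arms).
#' @return list with `median` (posterior median, months), `cri` (95%
#'   equal-tailed interval) and the per-draw medians.
#' @export
predict_median_survival <- function(draws, design, profile,
                                    arm = design$treatment_levels[2]) {
  x <- design_row(design, profile, arm = arm)
  M <- draws_matrix(draws)[, design$labels, drop = FALSE]
  med <- exp(drop(M %*% drop(x)))
  list(arm = arm,
       median = stats::median(med),
       cri = stats::quantile(med, c(0.025, 0.975), names = FALSE, type = 7),
       draws = med)
}

#' Table of effect summaries mirroring a subgroup results table
#'
#' Builds a tidy table (one row per summary) from a list of
#' `effect_summary` objects, ready to write as CSV.
#'
#' @param summaries list of `effect_summary` objects.
#' @return data.frame with columns `label`, `tr`, `cri_lo`, `cri_hi`,
#'   `p_gt_115`, `p_gt_130`, `rope_mass`.
#' @export
effects_table <- function(summaries) {
  if (inherits(summaries, "effect_summary")) summaries <- list(summaries)
  out <- do.call(rbind, lapply(summaries, function(s)
    data.frame(label = s$label, tr = s$tr, cri_lo = s$cri[1],
               cri_hi = s$cri[2], p_gt_115 = s$p_gt_115,
               p_gt_130 = s$p_gt_130, rope_mass = s$rope_mass,
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
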