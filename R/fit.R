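# High-level fitting interface: cohort -> design -> priors -> posterior,
# with convergence reporting, multiple-imputation pooling, and persistence
# of draws as CSV.

endpoint_columns <- function(endpoint) {
  if (endpoint == "OS") c("os_time", "os_event") else c("pfs_time",
                                                        "pfs_event")
}

#' Fit the Bayesian lognormal AFT model to a cohort
#'
#' Builds the design from a [model_spec()], assembles the per-coefficient
#' priors, samples the posterior, and attaches the split-Rhat convergence
#' report (warning when any parameter is at or above the 1.1 threshold).
#'
#' @param cohort complete-case cohort data.frame (impute first if needed).
#' @param spec a [model_spec()].
#' @param endpoint `"OS"` or `"PFS"` (selects both outcome columns and the
#'   endpoint-specific informative prior).
#' @param prior_mode `"informative"`, `"weak"` or `"flat"`.
#' @param interaction_sd sd of the skeptical interaction prior.
#' @param n_chains,n_warmup,n_iter,seed sampler settings, see
#'   [sample_posterior()].
#' @return object of class `aft_fit`: list with `draws`
#'   (`posterior_draws`), `report` (`convergence_report`), `design`,
#'   `priors`, `endpoint`.
#' @export
fit_aft <- function(cohort, spec = model_spec(), endpoint = c("OS", "PFS"),
                    prior_mode = "informative", interaction_sd = 0.05,
                    n_chains = 4, n_warmup = 1000, n_iter = 1000, seed = 1) {
  endpoint <- match.arg(endpoint)
  cols <- endpoint_columns(endpoint)
  design <- build_design(spec, cohort)
  priors <- build_prior_spec(design, endpoint = endpoint, mode = prior_mode,
                             interaction_sd = interaction_sd)
  dat <- aft_data(design$X, cohort[[cols[1]]], cohort[[cols[2]]])
  draws <- sample_posterior(dat, priors, n_chains = n_chains,
                            n_warmup = n_warmup, n_iter = n_iter,
                            seed = seed)
  report <- rhat(draws)
  if (!isTRUE(attr(report, "pass")))
    warning("convergence not reached: max split-Rhat ",
            sprintf("%.3f", max(report$rhat)), " >= 1.1", call. = FALSE)
  structure(list(draws = draws, report = report, design = design,
                 priors = priors, endpoint = endpoint),
            class = "aft_fit")
}

#' @export
print.aft_fit <- function(x, ...) {
  cat("Bayesian lognormal AFT fit (", x$endpoint, "), ",
      length(x$draws$draws), " chains\n", sep = "")
  print(effect_summary(x$draws, x$design$treatment_label))
  cat(if (isTRUE(attr(x$report, "pass"))) "all split-Rhat < 1.1\n"
      else "WARNING: convergence threshold not met\n")
  invisible(x)
}

#' Fit the model on every imputed dataset and pool the posteriors
#'
#' Fits [fit_aft()] on each completed dataset of an [impute_fcs()] result,
#' collects the per-dataset convergence reports, and mixture-pools the
#' posterior draws (chain concatenation across datasets).
#'
#' @param imputed an `imputed_sets`.
#' @param ... passed to [fit_aft()] (spec, endpoint, priors, sampler
#'   settings).
#' @return object of class `aft_fit` whose `draws` are the pooled posterior;
#'   `reports` holds the per-dataset convergence reports and `design` the
#'   design of the first completed dataset.
#' @export
fit_imputed <- function(imputed, ...) {
  stopifnot(inherits(imputed, "imputed_sets"))
  fits <- lapply(imputed$datasets, function(d) fit_aft(d, ...))
  pooled <- pool_imputations(lapply(fits, function(f) f$draws))
  structure(list(draws = pooled,
                 reports = lapply(fits, `[[`, "report"),
                 report = fits[[1]]$report,
                 design = fits[[1]]$design,
                 priors = fits[[1]]$priors,
                 endpoint = fits[[1]]$endpoint),
            class = "aft_fit")
}

#' Persist posterior draws as CSV
#'
#' One row per draw with `chain` and `iter` columns followed by one column
#' per parameter; `read_draws()` restores the chain structure.
#'
#' @param draws a `posterior_draws`.
#' @param path file path.
#' @return `read_draws()` returns the `posterior_draws`.
#' @export
write_draws <- function(draws, path) {
  stopifnot(inherits(draws, "posterior_draws"))
  tabs <- lapply(seq_along(draws$draws), function(ch)
    data.frame(chain = ch, iter = seq_len(nrow(draws$draws[[ch]])),
               draws$draws[[ch]], check.names = FALSE))
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  labels <- setdiff(names(tab), c("chain", "iter"))
  chains <- lapply(split(tab, tab$chain), function(d)
    as.matrix(d[labels]))
  names(chains) <- NULL
  structure(list(draws = chains, labels = labels, seed = NA_integer_,
                 metadata = list(restored_from = path)),
            class = "posterior_draws")
}
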