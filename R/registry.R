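# Synthetic AGC registry generator: covariate marginals calibrated to a large
# Spanish first-line chemotherapy registry, confounded (age/fitness-dependent)
# treatment assignment, lognormal AFT outcomes with known ground truth,
# administrative + dropout censoring, and configurable missingness.

COHORT_SCHEMA <- c("id", "age", "sex", "ecog", "lauren", "grade", "ascites",
                   "stage", "liver_burden", "n_organs", "platin", "nlr",
                   "year", "arm", "os_time", "os_event", "pfs_time",
                   "pfs_event")
COHORT_VERSION <- "bayesaft-cohort-v1"

LEVELS <- list(
  sex = c("male", "female"),
  ecog = c("0", "1", "2+"),
  lauren = c("diffuse", "intestinal"),
  grade = c("1", "2", "3"),
  stage = c("metastatic", "locally-advanced-unresectable"),
  liver_burden = c("none", "<25%", "25-50%", "51-75%", ">75%"),
  platin = c("oxaliplatin", "cisplatin"),
  arm = c("PF", "DPF")
)

# names accepted in truth coefficient vectors (generator-internal features)
TRUTH_FEATURES <- c("arm", "ecog1", "ecog2", "intestinal", "grade2", "grade3",
                    "ascites", "stage_la", "liver", "n_organs", "cisplatin",
                    "log_nlr", "age_dec", "year_c",
                    "arm:intestinal", "arm:age_dec", "arm:year_c")

#' Configuration of the synthetic registry generator
#'
#' Returns the full generative specification of a synthetic advanced gastric
#' cancer cohort: covariate marginals, the treatment-assignment propensity,
#' the ground-truth AFT coefficients for PFS and OS, the censoring process
#' and the missingness mechanism. Defaults are calibrated to the published
#' baseline table of the reference registry (n = 1376, ~17% triplet share,
#' ECOG 0/1/2+ = 20/65/15%, 21% missing Lauren subtype, 24% missing grade,
#' median OS 10.2 and PFS 5.8 months) and to its reported effects (OS
#' treatment log time-ratio ln 1.19 with a treatment-by-intestinal-subtype
#' interaction ln(1.27/1.17); PFS treatment log time-ratio ln 1.27).
#'
#' Continuous ground-truth features are coded as: `age_dec` = (age - 65)/10,
#' `year_c` = year - 2014, `log_nlr` = log(nlr/3), `liver` = ordinal liver
#' burden score 0-4, `n_organs` = organ count. Categorical references:
#' ECOG 0, diffuse subtype, grade 1, metastatic stage, oxaliplatin, PF arm.
#'
#' @param n cohort size, default 1376.
#' @param covariate_marginals list of per-variable marginals (frequencies for
#'   categorical levels; distribution parameters for `age` and `nlr`;
#'   `year` weights over 2008-2019). Partial lists override the defaults.
#' @param propensity list with `intercept` and coefficients `age` (per decade,
#'   centred at 65), `age_late` (extra slope per decade above 65, making the
#'   age effect nonlinear), `ecog2` and `year` (per year, centred at 2014) on
#'   the log-odds of DPF.
#' @param truth list with `pfs = list(intercept, sigma, beta)` and
#'   `os = list(intercept, pps_sigma, beta)`; `beta` are named vectors over
#'   the features listed above. The OS intercept is the log of the
#'   reference-profile median OS in months.
#' @param censoring list with `cutoff` (calendar time of the administrative
#'   analysis cutoff, e.g. `2020`; `Inf` disables it) and `dropout_rate`
#'   (exponential loss-to-follow-up rate per month; 0 disables it).
#' @param missingness named list of `list(rate, mechanism)` per missable
#'   column; `mechanism` is `"MCAR"` or `"MAR"` (MAR on the fully observed
#'   age and year, younger / earlier records more often missing).
#' @param seed integer seed; the same config and seed reproduce the cohort
#'   exactly.
#' @return object of class `registry_config`.
#' @export
registry_config <- function(n = 1376, covariate_marginals = list(),
                            propensity = list(), truth = list(),
                            censoring = list(), missingness = NULL,
                            seed = 20080101) {
  def_marg <- list(
    age = list(mean = 65, sd = 11.5, min = 20, max = 89),
    sex = c(male = 0.67, female = 0.33),
    ecog = c("0" = 0.20, "1" = 0.65, "2+" = 0.15),
    lauren = c(diffuse = 0.59, intestinal = 0.41),
    grade = c("1" = 0.12, "2" = 0.32, "3" = 0.56),
    ascites = 0.25,
    stage = c(metastatic = 0.96, "locally-advanced-unresectable" = 0.04),
    liver_burden = c(none = 0.65, "<25%" = 0.10, "25-50%" = 0.08,
                     "51-75%" = 0.10, ">75%" = 0.07),
    n_organs = c("0" = 0.04, "1" = 0.40, "2" = 0.31, "3" = 0.17, "4" = 0.08),
    platin = c(oxaliplatin = 0.65, cisplatin = 0.35),
    nlr = list(meanlog = log(3), sdlog = 0.55),
    year = list(from = 2008, to = 2019, weights = (1:12)^1.5)
  )
  def_prop <- list(intercept = -1.4207, age = -0.45, age_late = -0.55,
                   ecog2 = -1.1, year = 0)
  def_truth <- list(
    pfs = list(intercept = log(5.8), sigma = 0.85,
               beta = c(arm = log(1.27), ecog1 = -0.15, ecog2 = -0.40,
                        intestinal = 0.10, grade3 = -0.15, ascites = -0.15,
                        stage_la = 0.25, liver = -0.08, n_organs = -0.10,
                        log_nlr = -0.15, age_dec = -0.03, year_c = 0.01)),
    os = list(intercept = log(10.2), pps_sigma = 0.90,
              beta = c(arm = log(1.19), "arm:intestinal" = log(1.27 / 1.17),
                       ecog1 = -0.20, ecog2 = -0.50, intestinal = 0.15,
                       grade3 = -0.20, ascites = -0.20, stage_la = 0.30,
                       liver = -0.10, n_organs = -0.12, log_nlr = -0.20,
                       age_dec = -0.05, year_c = 0.01)))
  def_cens <- list(cutoff = 2020, dropout_rate = 0.005)
  def_miss <- list(lauren = list(rate = 0.21, mechanism = "MAR"),
                   grade = list(rate = 0.24, mechanism = "MAR"))

  cfg <- list(
    n = n,
    covariate_marginals = utils::modifyList(def_marg, covariate_marginals),
    propensity = utils::modifyList(def_prop, propensity),
    truth = utils::modifyList(def_truth, truth),
    censoring = utils::modifyList(def_cens, censoring),
    missingness = if (is.null(missingness)) def_miss else missingness,
    seed = as.integer(seed))
  class(cfg) <- "registry_config"
  validate_registry_config(cfg)
  cfg
}

validate_registry_config <- function(cfg) {
  if (!is.numeric(cfg$n) || length(cfg$n) != 1 || cfg$n <= 0)
    stop("configuration error: n must be a positive count", call. = FALSE)
  m <- cfg$covariate_marginals
  for (v in c("sex", "ecog", "lauren", "grade", "stage", "liver_burden",
              "n_organs", "platin")) {
    p <- m[[v]]
    if (is.null(p) || !is.numeric(p) || any(p < 0) ||
        abs(sum(p) - 1) > 1e-6)
      stop("configuration error: marginal frequencies for '", v,
           "' must be nonnegative and sum to 1", call. = FALSE)
  }
  if (m$ascites < 0 || m$ascites > 1)
    stop("configuration error: marginal frequencies for 'ascites' must be ",
         "a probability", call. = FALSE)
  if (m$age$sd <= 0 || m$age$min >= m$age$max)
    stop("configuration error: invalid 'age' marginal", call. = FALSE)
  if (m$nlr$sdlog <= 0)
    stop("configuration error: invalid 'nlr' marginal", call. = FALSE)
  if (any(m$year$weights < 0) || sum(m$year$weights) <= 0 ||
      length(m$year$weights) != m$year$to - m$year$from + 1)
    stop("configuration error: invalid 'year' marginal", call. = FALSE)
  if (!all(vapply(cfg$propensity, function(x)
        is.numeric(x) && length(x) == 1 && is.finite(x), TRUE)))
    stop("configuration error: propensity coefficients must be finite ",
         "scalars", call. = FALSE)
  for (ep in c("pfs", "os")) {
    tr <- cfg$truth[[ep]]
    sig <- if (ep == "pfs") tr$sigma else tr$pps_sigma
    if (!is.numeric(sig) || sig <= 0)
      stop("configuration error: truth scale for '", ep,
           "' must be positive", call. = FALSE)
    bad <- setdiff(names(tr$beta), TRUTH_FEATURES)
    if (length(bad))
      stop("configuration error: unknown truth feature(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (cfg$truth$os$intercept <= cfg$truth$pfs$intercept)
    stop("configuration error: OS intercept (log median OS) must exceed ",
         "the PFS intercept", call. = FALSE)
  if (cfg$censoring$dropout_rate < 0)
    stop("configuration error: dropout_rate must be >= 0", call. = FALSE)
  validate_missingness(cfg$missingness)
  invisible(cfg)
}

validate_missingness <- function(miss) {
  if (length(miss) == 0) return(invisible(miss))
  missable <- setdiff(COHORT_SCHEMA,
                      c("id", "age", "year", "arm",
                        "os_time", "os_event", "pfs_time", "pfs_event"))
  bad <- setdiff(names(miss), missable)
  if (length(bad))
    stop("configuration error: column(s) not missable: ",
         paste(bad, collapse = ", "), call. = FALSE)
  for (v in names(miss)) {
    mv <- miss[[v]]
    if (!is.numeric(mv$rate) || mv$rate < 0 || mv$rate > 1)
      stop("configuration error: missingness rate for '", v,
           "' must lie in [0, 1]", call. = FALSE)
    if (!mv$mechanism %in% c("MCAR", "MAR"))
      stop("configuration error: mechanism for '", v,
           "' must be MCAR or MAR", call. = FALSE)
  }
  # MAR conditions on age and year, which must stay fully observed
  if (any(vapply(miss, function(m) m$mechanism == "MAR", TRUE)) &&
      any(c("age", "year") %in% names(miss)))
    stop("configuration error: MAR mechanism conditions on age/year, ",
         "which cannot themselves be missable", call. = FALSE)
  invisible(miss)
}

draw_covariates <- function(n, m) {
  draw_cat <- function(p) factor(sample(names(p), n, TRUE, prob = p),
                                 levels = names(p))
  a <- m$age
  u <- stats::runif(n, stats::pnorm(a$min, a$mean, a$sd),
                    stats::pnorm(a$max, a$mean, a$sd))
  age <- stats::qnorm(u, a$mean, a$sd)
  yr <- m$year
  year <- sample(yr$from:yr$to, n, TRUE, prob = yr$weights)
  data.frame(
    age = age,
    sex = factor(draw_cat(m$sex), levels = LEVELS$sex),
    ecog = factor(draw_cat(m$ecog), levels = LEVELS$ecog),
    lauren = factor(draw_cat(m$lauren), levels = LEVELS$lauren),
    grade = factor(draw_cat(m$grade), levels = LEVELS$grade),
    ascites = stats::rbinom(n, 1, m$ascites),
    stage = factor(draw_cat(m$stage), levels = LEVELS$stage),
    liver_burden = factor(draw_cat(m$liver_burden),
                          levels = LEVELS$liver_burden),
    n_organs = as.integer(sample(names(m$n_organs), n, TRUE,
                                 prob = m$n_organs)),
    platin = factor(draw_cat(m$platin), levels = LEVELS$platin),
    nlr = stats::rlnorm(n, m$nlr$meanlog, m$nlr$sdlog),
    year = year,
    stringsAsFactors = FALSE)
}

#' Assign treatment arm from a logistic propensity
#'
#' Draws each patient's arm (PF vs DPF) from a per-row logistic probability
#' whose log-odds depend (nonlinearly) on age, on ECOG performance status and
#' optionally on calendar year — emulating confounding by indication, where
#' younger and fitter patients preferentially receive the triplet.
#'
#' @param covariates data.frame of baseline covariates (needs `age`, `ecog`
#'   and `year`).
#' @param propensity coefficient list, see [registry_config()].
#' @return factor of levels `PF`/`DPF`, one per row.
#' @export
assign_treatment <- function(covariates, propensity) {
  pr <- utils::modifyList(list(intercept = 0, age = 0, age_late = 0,
                               ecog2 = 0, year = 0), propensity)
  if (!all(vapply(pr, function(x)
        is.numeric(x) && length(x) == 1 && is.finite(x), TRUE)))
    stop("configuration error: propensity coefficients must be finite ",
         "scalars", call. = FALSE)
  t <- (covariates$age - 65) / 10
  lin <- pr$intercept + pr$age * t + pr$age_late * pmax(t, 0) +
    pr$ecog2 * as.numeric(covariates$ecog == "2+") +
    pr$year * (covariates$year - 2014)
  p <- stats::plogis(lin)
  factor(ifelse(stats::runif(nrow(covariates)) < p, "DPF", "PF"),
         levels = LEVELS$arm)
}

truth_features <- function(covariates, arm) {
  intest <- as.numeric(covariates$lauren == "intestinal")
  intest[is.na(intest)] <- 0  # truth acts on pre-missingness data
  age_dec <- (covariates$age - 65) / 10
  year_c <- covariates$year - 2014
  armn <- as.numeric(arm == "DPF")
  X <- cbind(
    arm = armn,
    ecog1 = as.numeric(covariates$ecog == "1"),
    ecog2 = as.numeric(covariates$ecog == "2+"),
    intestinal = intest,
    grade2 = as.numeric(covariates$grade == "2"),
    grade3 = as.numeric(covariates$grade == "3"),
    ascites = as.numeric(covariates$ascites),
    stage_la = as.numeric(covariates$stage == "locally-advanced-unresectable"),
    liver = as.numeric(covariates$liver_burden) - 1,
    n_organs = covariates$n_organs,
    cisplatin = as.numeric(covariates$platin == "cisplatin"),
    log_nlr = log(covariates$nlr / 3),
    age_dec = age_dec,
    year_c = year_c,
    "arm:intestinal" = armn * intest,
    "arm:age_dec" = armn * age_dec,
    "arm:year_c" = armn * year_c)
  X
}

lin_pred <- function(X, beta) {
  if (length(beta) == 0) return(rep(0, nrow(X)))
  drop(X[, names(beta), drop = FALSE] %*% beta)
}

# deterministic solve for the post-progression scale c such that, at the
# reference profile, median(PFS0 + c * PPS0) equals exp(os intercept)
solve_pps_scale <- function(truth) {
  mu_p <- truth$pfs$intercept; s_p <- truth$pfs$sigma
  s_s <- truth$os$pps_sigma
  m <- exp(truth$os$intercept)
  cdf_sum <- function(cc) {
    stats::integrate(function(t)
      stats::dlnorm(t, mu_p, s_p) * stats::plnorm((m - t) / cc, 0, s_s),
      lower = 0, upper = m, rel.tol = 1e-9)$value
  }
  f <- function(lc) cdf_sum(exp(lc)) - 0.5
  exp(stats::uniroot(f, c(-12, 12), tol = 1e-10)$root)
}

#' Draw censored survival outcomes under the ground-truth AFT model
#'
#' Progression-free survival is drawn from the exact lognormal accelerated
#' failure time law `log PFS ~ Normal(mu_pfs + x'beta_pfs, sigma_pfs)`.
#' Overall survival is PFS plus an independent lognormal post-progression
#' time accelerated by `x'beta_os`, which enforces `pfs_time <= os_time` by
#' construction; the post-progression scale is solved so that the
#' reference-profile median OS equals `exp(os intercept)`. Censoring is the
#' minimum of the administrative follow-up implied by uniform accrual within
#' the entry year and a fixed analysis cutoff, and an exponential dropout
#' time.
#'
#' @param covariates baseline covariate data.frame (see [registry_config()]).
#' @param arm factor of `PF`/`DPF`.
#' @param truth ground-truth parameter list, see [registry_config()].
#' @param censoring censoring parameter list, see [registry_config()].
#' @return data.frame with `os_time`, `os_event`, `pfs_time`, `pfs_event`
#'   (times in months; event = 1, censored = 0).
#' @export
draw_outcomes <- function(covariates, arm, truth, censoring) {
  if (!is.numeric(truth$pfs$sigma) || truth$pfs$sigma <= 0 ||
      !is.numeric(truth$os$pps_sigma) || truth$os$pps_sigma <= 0)
    stop("configuration error: truth scale must be positive", call. = FALSE)
  n <- nrow(covariates)
  X <- truth_features(covariates, arm)
  mu_p <- truth$pfs$intercept + lin_pred(X, truth$pfs$beta)
  pfs <- exp(stats::rnorm(n, mu_p, truth$pfs$sigma))
  cc <- solve_pps_scale(truth)
  pps <- cc * exp(lin_pred(X, truth$os$beta)) *
    stats::rlnorm(n, 0, truth$os$pps_sigma)
  os <- pfs + pps

  entry <- covariates$year + stats::runif(n)
  followup <- if (is.finite(censoring$cutoff))
    pmax((censoring$cutoff - entry) * 12, 0.01) else rep(Inf, n)
  dropout <- if (censoring$dropout_rate > 0)
    stats::rexp(n, censoring$dropout_rate) else rep(Inf, n)
  cens <- pmin(followup, dropout)
  data.frame(
    os_time = pmin(os, cens),
    os_event = as.integer(os <= cens),
    pfs_time = pmin(pfs, cens),
    pfs_event = as.integer(pfs <= cens))
}

#' Inject missing values into a generated cohort
#'
#' Blanks entries of the declared missable columns, either completely at
#' random (MCAR) or at random given the fully observed age and year (MAR,
#' with younger patients and earlier calendar years more often missing, as in
#' registries whose pathology review improved over time). Under MAR the
#' intercept of the missingness model is solved so that the expected marginal
#' missing fraction equals the configured rate. The input table is not
#' modified.
#'
#' @param table cohort data.frame.
#' @param missingness named list of `list(rate, mechanism)`, see
#'   [registry_config()].
#' @return the table with `NA`s injected.
#' @export
inject_missingness <- function(table, missingness) {
  validate_missingness(missingness)
  out <- table
  n <- nrow(table)
  for (v in names(missingness)) {
    mv <- missingness[[v]]
    if (mv$rate == 0) next
    if (mv$rate == 1) { out[[v]][] <- NA; next }
    p <- if (mv$mechanism == "MCAR") rep(mv$rate, n) else {
      lin <- -0.35 * (table$age - 65) / 10 - 0.08 * (table$year - 2014)
      a <- stats::uniroot(function(a) mean(stats::plogis(a + lin)) - mv$rate,
                          c(-20, 20), tol = 1e-10)$root
      stats::plogis(a + lin)
    }
    out[[v]][stats::runif(n) < p] <- NA
  }
  out
}

#' Generate a synthetic registry cohort
#'
#' Runs the full generative pipeline — covariates, confounded treatment
#' assignment, ground-truth AFT outcomes with censoring, missingness — under
#' the config's seed. Identical config and seed give a byte-identical table.
#'
#' @param config a [registry_config()].
#' @return data.frame with one row per patient and the documented schema
#'   (`id`, covariates, `arm`, `os_time`, `os_event`, `pfs_time`,
#'   `pfs_event`).
#' @examples
#' cohort <- generate_cohort(registry_config(n = 200, seed = 1))
#' table(cohort$arm)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "registry_config"))
  validate_registry_config(config)
  set.seed(config$seed)
  cov <- draw_covariates(config$n, config$covariate_marginals)
  arm <- assign_treatment(cov, config$propensity)
  outc <- draw_outcomes(cov, arm, config$truth, config$censoring)
  tab <- cbind(id = sprintf("P%06d", seq_len(config$n)), cov,
               arm = arm, outc, stringsAsFactors = FALSE)
  tab <- tab[, COHORT_SCHEMA]
  inject_missingness(tab, config$missingness)
}

#' Read and write cohorts as versioned CSV
#'
#' The CSV carries a `# bayesaft-cohort-v1` version line, then a header with
#' the exact schema column names; missing entries are empty fields.
#'
#' @param cohort cohort data.frame.
#' @param path file path.
#' @return `read_cohort()` returns the cohort with canonical column types.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(identical(names(cohort), COHORT_SCHEMA))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", COHORT_VERSION), con)
  utils::write.table(cohort, con, sep = ",", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl(COHORT_VERSION, first, fixed = TRUE))
    stop("not a recognized cohort file (missing version header)",
         call. = FALSE)
  tab <- utils::read.csv(path, comment.char = "#", na.strings = "",
                         stringsAsFactors = FALSE)
  if (!identical(names(tab), COHORT_SCHEMA))
    stop("cohort file columns do not match the schema", call. = FALSE)
  for (v in names(LEVELS)) tab[[v]] <- factor(tab[[v]], levels = LEVELS[[v]])
  tab$n_organs <- as.integer(tab$n_organs)
  tab$year <- as.integer(tab$year)
  tab
}

#' Read and write registry configurations as YAML
#'
#' @param config a [registry_config()].
#' @param path file path.
#' @return `read_registry_config()` returns a validated `registry_config`.
#' @export
write_registry_config <- function(config, path) {
  stopifnot(inherits(config, "registry_config"))
  # yaml writes named numeric vectors as plain sequences; keep the names by
  # converting them to maps first
  prep <- function(x) {
    if (is.numeric(x) && !is.null(names(x))) as.list(x)
    else if (is.list(x)) lapply(x, prep)
    else x
  }
  yaml::write_yaml(prep(unclass(config)), path, precision = 15)
  invisible(path)
}

#' @rdname write_registry_config
#' @export
read_registry_config <- function(path) {
  raw <- yaml::read_yaml(path)
  relist <- function(x) if (is.list(x) && !is.null(names(x)) &&
                            all(vapply(x, is.numeric, TRUE)) &&
                            all(lengths(x) == 1)) unlist(x) else x
  # yaml stores named numeric vectors as maps; restore vectors where needed
  for (v in c("sex", "ecog", "lauren", "grade", "stage", "liver_burden",
              "n_organs", "platin"))
    raw$covariate_marginals[[v]] <- relist(raw$covariate_marginals[[v]])
  raw$covariate_marginals$year$weights <-
    as.numeric(unlist(raw$covariate_marginals$year$weights))
  for (ep in c("pfs", "os")) raw$truth[[ep]]$beta <- relist(raw$truth[[ep]]$beta)
  cfg <- raw
  class(cfg) <- "registry_config"
  validate_registry_config(cfg)
  cfg
}
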