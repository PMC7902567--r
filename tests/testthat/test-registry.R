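test_that("default configuration reproduces the registry's size and is deterministic", {
  cfg <- registry_config()
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 1376)
  expect_identical(co, generate_cohort(cfg))
  expect_named(co, c("id", "age", "sex", "ecog", "lauren", "grade",
                     "ascites", "stage", "liver_burden", "n_organs",
                     "platin", "nlr", "year", "arm", "os_time", "os_event",
                     "pfs_time", "pfs_event"))
  # subtype missingness calibrated to the registry's 21%
  p <- 0.21
  expect_lt(abs(mean(is.na(co$lauren)) - p), 3 * sqrt(p * (1 - p) / 1376))
  expect_true(all(co$pfs_time <= co$os_time))
  expect_true(all(co$os_time > 0))
})

test_that("categorical marginals converge to their configured frequencies", {
  cfg <- registry_config(n = 50000, seed = 99, missingness = list())
  co <- generate_cohort(cfg)
  m <- cfg$covariate_marginals
  for (v in c("sex", "ecog", "lauren", "grade", "stage", "liver_burden",
              "platin")) {
    emp <- prop.table(table(co[[v]]))
    for (lv in names(m[[v]])) {
      p <- m[[v]][[lv]]
      expect_lt(abs(emp[[lv]] - p), 3 * sqrt(p * (1 - p) / 50000))
    }
  }
  expect_lt(abs(mean(co$ascites) - 0.25), 3 * sqrt(0.25 * 0.75 / 50000))
  # age marginal: median near 65, range respected
  expect_true(all(co$age >= 20 & co$age <= 89))
  expect_lt(abs(stats::median(co$age) - 65), 0.5)

  # treatment share matches the registry's 238/1376 and decreases with age
  share <- 238 / 1376
  expect_lt(abs(mean(co$arm == "DPF") - share),
            3 * sqrt(share * (1 - share) / 50000))
  dec <- cut(co$age, stats::quantile(co$age, 0:10 / 10),
             include.lowest = TRUE)
  by_dec <- tapply(co$arm == "DPF", dec, mean)
  expect_true(all(diff(by_dec) <= 0))
})

test_that("treatment assignment follows the per-row logistic probability", {
  set.seed(5)
  cov <- data.frame(age = runif(20000, 25, 88), ecog = factor("1",
                    levels = c("0", "1", "2+")), year = 2015)
  # null propensity: fifty-fifty
  arm <- assign_treatment(cov, list(intercept = 0))
  expect_lt(abs(mean(arm == "DPF") - 0.5), 3 * sqrt(0.25 / 20000))
  # steep age slope saturates the logistic: virtually no triplets at 85
  old <- data.frame(age = rep(85, 5000),
                    ecog = factor("0", levels = c("0", "1", "2+")),
                    year = 2015)
  arm_old <- assign_treatment(old, list(intercept = 0, age = -10))
  expect_lt(mean(arm_old == "DPF"), 0.01)
})

test_that("outcome generator obeys the lognormal AFT truth", {
  # reference profile, no censoring: median OS equals exp(os intercept)
  base <- registry_config()
  cfg <- registry_config(n = 100000, seed = 7,
                         censoring = list(cutoff = Inf, dropout_rate = 0),
                         truth = list(pfs = list(beta = c(arm = 0)),
                                      os = list(beta = c(arm = 0))),
                         missingness = list())
  co <- generate_cohort(cfg)
  expect_equal(stats::median(co$os_time), exp(base$truth$os$intercept),
               tolerance = 0.02)
  expect_equal(stats::median(co$pfs_time), exp(base$truth$pfs$intercept),
               tolerance = 0.02)
  expect_true(all(co$os_event == 1) && all(co$pfs_event == 1))

  # a shared treatment coefficient ln(1.19) multiplies median event times
  cfg2 <- registry_config(n = 100000, seed = 8,
                          censoring = list(cutoff = Inf, dropout_rate = 0),
                          truth = list(pfs = list(beta = c(arm = log(1.19))),
                                       os = list(beta = c(arm = log(1.19)))),
                          propensity = list(intercept = 0, age = 0,
                                            age_late = 0, ecog2 = 0),
                          missingness = list())
  co2 <- generate_cohort(cfg2)
  ratio_os <- stats::median(co2$os_time[co2$arm == "DPF"]) /
    stats::median(co2$os_time[co2$arm == "PF"])
  ratio_pfs <- stats::median(co2$pfs_time[co2$arm == "DPF"]) /
    stats::median(co2$pfs_time[co2$arm == "PF"])
  expect_equal(ratio_os, 1.19, tolerance = 0.02)
  expect_equal(ratio_pfs, 1.19, tolerance = 0.02)
  expect_true(all(co2$pfs_time <= co2$os_time))
})

test_that("missingness injection hits configured rates and never mutates its input", {
  co <- quick_cohort(1376, seed = 10)
  co_before <- co
  out <- inject_missingness(co, list(lauren = list(rate = 0.21,
                                                   mechanism = "MCAR")))
  expect_identical(co, co_before)
  n_miss <- sum(is.na(out$lauren))
  expect_lt(abs(n_miss - 1376 * 0.21), 3 * sqrt(1376 * 0.21 * 0.79))

  expect_identical(inject_missingness(co, list()), co)
  all_gone <- inject_missingness(co, list(grade = list(rate = 1,
                                                       mechanism = "MCAR")))
  expect_true(all(is.na(all_gone$grade)))

  # MAR: expected marginal rate solved exactly; younger records more missing
  mar <- inject_missingness(co, list(lauren = list(rate = 0.3,
                                                   mechanism = "MAR")))
  expect_lt(abs(mean(is.na(mar$lauren)) - 0.3), 3 * sqrt(0.3 * 0.7 / 1376))
  young <- co$age < stats::median(co$age)
  expect_gt(mean(is.na(mar$lauren[young])), mean(is.na(mar$lauren[!young])))
})

test_that("configuration errors name the offending component", {
  expect_error(registry_config(covariate_marginals =
                                 list(ecog = c("0" = 0.5, "1" = 0.4,
                                               "2+" = 0.2))),
               "'ecog'")
  expect_error(registry_config(truth = list(pfs = list(sigma = -1))),
               "scale.*positive")
  expect_error(registry_config(missingness =
                                 list(lauren = list(rate = 1.2,
                                                    mechanism = "MCAR"))),
               "rate")
  expect_error(registry_config(missingness =
                                 list(age = list(rate = 0.1,
                                                 mechanism = "MAR"))),
               "not missable|age")
  expect_error(registry_config(n = 0), "positive")
})

test_that("cohorts and configs round-trip through their file formats", {
  cfg <- registry_config(n = 120, seed = 42)
  co <- generate_cohort(cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  expect_match(readLines(f, n = 1), "bayesaft-cohort-v1")
  co2 <- read_cohort(f)
  expect_identical(co2$lauren, co$lauren)
  expect_identical(co2$arm, co$arm)
  expect_equal(co2$os_time, co$os_time, tolerance = 1e-10)
  expect_equal(co2$pfs_event, co$pfs_event)

  y <- withr::local_tempfile(fileext = ".yaml")
  write_registry_config(cfg, y)
  cfg2 <- read_registry_config(y)
  expect_equal(generate_cohort(cfg2), co, tolerance = 1e-12)
})
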