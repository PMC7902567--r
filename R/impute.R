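# Missing-data screen and fully-conditional-specification multiple
# imputation: chained per-column conditional models (linear regression with
# noise for continuous columns, multinomial logistic regression for
# categorical ones), iterated from random starting fills.

#' Screen covariates by missing-data fraction
#'
#' Columns whose missing fraction strictly exceeds the threshold are dropped
#' (the ">" is strict: a column with exactly the threshold fraction missing
#' is retained); the rest are kept for imputation.
#'
#' @param table data.frame.
#' @param threshold maximum tolerated missing fraction, in (0, 1],
#'   default 0.25.
#' @param columns columns to screen (default all).
#' @return list with `retained` and `dropped` column names and a `report`
#'   data.frame (`column`, `n_missing`, `fraction`, `dropped`).
#' @export
screen_missingness <- function(table, threshold = 0.25,
                               columns = names(table)) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]", call. = FALSE)
  frac <- vapply(table[columns], function(x) mean(is.na(x)), 0)
  drop <- frac > threshold
  list(retained = columns[!drop],
       dropped = columns[drop],
       report = data.frame(column = columns, n_missing =
                             vapply(table[columns],
                                    function(x) sum(is.na(x)), 0L),
                           fraction = unname(frac), dropped = unname(drop),
                           stringsAsFactors = FALSE))
}

# predictor frame for the conditionals: every column except `exclude`, with
# survival times entered as log time + event flag (the standard
# recommendation when imputing covariates of a survival model)
fcs_predictors <- function(filled, exclude) {
  keep <- setdiff(names(filled), c("id", exclude))
  out <- filled[keep]
  for (v in intersect(c("os_time", "pfs_time"), keep))
    out[[v]] <- log(out[[v]])
  for (v in names(out))
    if (is.factor(out[[v]])) out[[v]] <- droplevels(out[[v]])
  # drop constant columns, which carry no information and break the fits
  const <- vapply(out, function(x) length(unique(x)) < 2, TRUE)
  out[!const]
}

draw_continuous <- function(y_obs, pred_obs, pred_mis) {
  fit <- stats::lm(y ~ ., data = cbind(y = y_obs, pred_obs))
  sig <- summary(fit)$sigma
  if (!is.finite(sig)) sig <- 0
  mu <- suppressWarnings(stats::predict(fit, newdata = pred_mis))
  mu[!is.finite(mu)] <- mean(y_obs)
  mu + stats::rnorm(length(mu), 0, sig)
}

draw_categorical <- function(y_obs, pred_obs, pred_mis) {
  lv <- levels(droplevels(y_obs))
  if (length(lv) < 2) return(factor(rep(lv, nrow(pred_mis)),
                                    levels = levels(y_obs)))
  fit <- nnet::multinom(y ~ ., data = cbind(y = droplevels(y_obs), pred_obs),
                        trace = FALSE, maxit = 200)
  pr <- stats::predict(fit, newdata = pred_mis, type = "probs")
  if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)  # binomial case
  draws <- apply(pr, 1, function(p) sample(lv, 1, prob = pmax(p, 0)))
  factor(draws, levels = levels(y_obs))
}

#' Multiple imputation by fully conditional specification
#'
#' Produces `m` completed copies of the input by chained conditional models:
#' each incompletely observed column is regressed on all other columns
#' (including log survival time and the event flag when present), a linear
#' regression with residual noise for continuous targets and multinomial
#' logistic regression for categorical targets, sweeping the columns
#' `n_iter` times from random starting fills. Observed cells are never
#' altered; the result is deterministic under a fixed seed.
#'
#' @param table data.frame after the missingness screen (every incomplete
#'   column must retain at least one observed value).
#' @param m number of completed datasets, default 20.
#' @param n_iter chained sweeps per dataset, default 10.
#' @param seed integer seed.
#' @return object of class `imputed_sets`: list with `datasets` (list of m
#'   completed data.frames), `m`, `n_iter`, `seed` and the per-column
#'   `methods` record.
#' @export
impute_fcs <- function(table, m = 20, n_iter = 10, seed = 1) {
  stopifnot(is.data.frame(table), m >= 1, n_iter >= 1)
  miss_cols <- names(table)[vapply(table, anyNA, TRUE)]
  none_obs <- miss_cols[vapply(table[miss_cols],
                               function(x) all(is.na(x)), TRUE)]
  if (length(none_obs))
    stop("cannot model column(s) with zero observed values: ",
         paste(none_obs, collapse = ", "), call. = FALSE)
  methods <- vapply(table[miss_cols], function(x)
    if (is.numeric(x) && !all(stats::na.omit(x) %in% c(0, 1)))
      "linear-regression-with-noise" else "multinomial-logistic", "")
  set.seed(seed)
  if (length(miss_cols) == 0) {
    sets <- rep(list(table), m)
  } else {
    as_cat <- function(x) if (is.numeric(x)) factor(x) else x
    sets <- vector("list", m)
    for (k in seq_len(m)) {
      filled <- table
      for (v in miss_cols) {
        na <- is.na(table[[v]])
        filled[[v]][na] <- sample(table[[v]][!na], sum(na), replace = TRUE)
      }
      for (it in seq_len(n_iter)) {
        for (v in miss_cols) {
          na <- is.na(table[[v]])
          if (!any(na)) next
          pred <- fcs_predictors(filled, v)
          if (methods[[v]] == "linear-regression-with-noise") {
            filled[[v]][na] <- draw_continuous(table[[v]][!na],
                                               pred[!na, , drop = FALSE],
                                               pred[na, , drop = FALSE])
          } else {
            y <- as_cat(table[[v]])
            d <- draw_categorical(y[!na], pred[!na, , drop = FALSE],
                                  pred[na, , drop = FALSE])
            filled[[v]][na] <- if (is.numeric(table[[v]]))
              as.numeric(as.character(d)) else d
          }
        }
      }
      sets[[k]] <- filled
    }
  }
  structure(list(datasets = sets, m = m, n_iter = n_iter, seed = seed,
                 methods = as.list(methods)),
            class = "imputed_sets")
}

#' @export
print.imputed_sets <- function(x, ...) {
  cat("imputed_sets:", x$m, "completed datasets,", x$n_iter,
      "sweeps, seed", x$seed, "\n")
  if (length(x$methods))
    cat("methods:", paste(names(x$methods), unlist(x$methods),
                          sep = ": ", collapse = "; "), "\n")
  invisible(x)
}

#' Serialize imputed datasets to a directory of CSVs plus a manifest
#'
#' @param sets an `imputed_sets`.
#' @param dir output directory (created if needed).
#' @return `read_imputed_sets()` returns the restored `imputed_sets`.
#' @export
write_imputed_sets <- function(sets, dir) {
  stopifnot(inherits(sets, "imputed_sets"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_len(sets$m))
    utils::write.csv(sets$datasets[[k]],
                     file.path(dir, sprintf("imputed_%02d.csv", k)),
                     row.names = FALSE, quote = FALSE, na = "")
  jsonlite::write_json(list(m = sets$m, n_iter = sets$n_iter,
                            seed = sets$seed, methods = sets$methods),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_imputed_sets
#' @export
read_imputed_sets <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  sets <- lapply(seq_len(man$m), function(k)
    utils::read.csv(file.path(dir, sprintf("imputed_%02d.csv", k)),
                    na.strings = "", stringsAsFactors = FALSE))
  structure(list(datasets = sets, m = man$m, n_iter = man$n_iter,
                 seed = man$seed, methods = man$methods),
            class = "imputed_sets")
}
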