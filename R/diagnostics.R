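# Convergence tooling: split-chain potential scale reduction (split-Rhat)
# and effective sample size, with the < 1.1 pass rule used for reporting.

split_chains <- function(draws) {
  halves <- list()
  for (m in draws$draws) {
    n <- nrow(m)
    h <- floor(n / 2)
    halves <- c(halves, list(m[seq_len(h), , drop = FALSE],
                             m[(n - h + 1):n, , drop = FALSE]))
  }
  halves
}

rhat_one <- function(cols) {
  n <- length(cols[[1]]); m <- length(cols)
  means <- vapply(cols, mean, 0)
  vars <- vapply(cols, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_one <- function(cols) {
  n <- length(cols[[1]]); m <- length(cols)
  means <- vapply(cols, mean, 0)
  vars <- vapply(cols, stats::var, 0)
  W <- mean(vars)
  var_plus <- (n - 1) / n * W + stats::var(means)
  if (var_plus == 0 || W == 0) return(m * n)
  lag_max <- min(n - 1, 400)
  acov <- vapply(cols, function(x)
    stats::acf(x, lag.max = lag_max, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1],
    numeric(lag_max + 1))
  rho <- 1 - (W - rowMeans(acov)) / var_plus  # rho[1] is lag 0
  # Geyer initial positive sequence on paired sums
  s <- 0; t <- 1
  while (t + 1 <= lag_max) {
    pair <- rho[t + 1] + rho[t + 2]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  # tau = -1 + 2 * (rho_0 + paired sums); rho_0 = 1 by construction
  tau <- max(-1 + 2 * (1 + s), 1e-8)
  min(m * n / tau, m * n)
}

#' Split-Rhat convergence report
#'
#' Computes the split-chain Gelman-Rubin potential scale reduction factor and
#' an effective sample size per parameter, and flags the fit as passing when
#' every Rhat is below the threshold (default 1.1, the usual reporting rule
#' for these models).
#'
#' @param draws a `posterior_draws` with at least 2 chains of at least 4
#'   draws each.
#' @param threshold pass threshold on Rhat, default 1.1.
#' @return object of class `convergence_report`: data.frame with columns
#'   `parameter`, `rhat`, `ess`; attribute `pass` is `TRUE` iff all
#'   `rhat < threshold`.
#' @export
rhat <- function(draws, threshold = 1.1) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (length(draws$draws) < 2)
    stop("need at least 2 chains for split-Rhat", call. = FALSE)
  if (nrow(draws$draws[[1]]) < 4)
    stop("need at least 4 post-warmup draws per chain", call. = FALSE)
  halves <- split_chains(draws)
  out <- data.frame(parameter = draws$labels,
                    rhat = NA_real_, ess = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(draws$labels)) {
    cols <- lapply(halves, function(h) h[, j])
    out$rhat[j] <- rhat_one(cols)
    out$ess[j] <- ess_one(cols)
  }
  structure(out, pass = all(out$rhat < threshold), threshold = threshold,
            class = c("convergence_report", "data.frame"))
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("convergence report (split-Rhat threshold ",
      attr(x, "threshold"), "):\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(if (isTRUE(attr(x, "pass"))) "PASS: all Rhat below threshold\n"
      else "WARNING: some Rhat at or above threshold\n")
  invisible(x)
}

#' Serialize a convergence report to JSON
#'
#' @param report a `convergence_report`.
#' @param path file path.
#' @export
write_convergence_report <- function(report, path) {
  jsonlite::write_json(
    list(threshold = attr(report, "threshold"),
         pass = isTRUE(attr(report, "pass")),
         parameters = as.data.frame(report)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
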