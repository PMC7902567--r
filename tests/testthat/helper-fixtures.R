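# Shared fixtures: small fully observed cohorts, hand-built draw objects, and
# a compact model specification used across the model-level tests.

quick_cohort <- function(n = 300, seed = 1, ...) {
  generate_cohort(registry_config(n = n, seed = seed, missingness = list(),
                                  ...))
}

small_spec <- function(interactions = "lauren") {
  model_spec(main = c("ecog", "lauren", "ascites", "age", "nlr"),
             splines = character(0), interactions = interactions)
}

# posterior_draws object from explicit per-chain matrices
make_draws <- function(...) {
  chains <- list(...)
  structure(list(draws = chains, labels = colnames(chains[[1]]),
                 seed = NA_integer_, metadata = list()),
            class = "posterior_draws")
}

# degenerate draws: every draw equals the given named coefficient vector
constant_draws <- function(coefs, n = 100, n_chains = 2) {
  m <- matrix(rep(coefs, each = n), nrow = n,
              dimnames = list(NULL, names(coefs)))
  do.call(make_draws, rep(list(m), n_chains))
}

# hand-built prior spec
manual_priors <- function(labels, classes, means, sds) {
  out <- data.frame(label = labels, class = classes, mean = means, sd = sds,
                    stringsAsFactors = FALSE)
  class(out) <- c("prior_spec", "data.frame")
  out
}
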