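# Model design structure: categorical encodings vs documented reference
# levels, restricted cubic spline expansions of continuous covariates, and
# treatment-by-covariate interaction columns, with a label registry mapping
# every design column to a coefficient class (intercept / treatment /
# interaction / nuisance).

#' Specify the AFT model structure
#'
#' Declares which covariates enter the model, which continuous covariates get
#' restricted cubic spline expansions, which are log-transformed first, and
#' which covariates interact with treatment. Encoding details (reference
#' levels, centering/scaling constants, knot positions) are resolved from the
#' data by [build_design()].
#'
#' @param main character vector of main-effect covariates.
#' @param treatment name of the treatment column (factor, second level =
#'   treated), default `"arm"`.
#' @param splines continuous covariates expanded with restricted cubic
#'   splines.
#' @param spline_k knots per spline, default 3.
#' @param log_transform continuous covariates log-transformed before
#'   centering (e.g. the skewed neutrophil/lymphocyte ratio).
#' @param interactions covariates interacting with treatment; each must be a
#'   declared main term.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(main = c("ecog", "lauren", "grade", "ascites", "stage",
                                "liver_burden", "n_organs", "platin", "nlr",
                                "age", "year"),
                       treatment = "arm",
                       splines = "age", spline_k = 3,
                       log_transform = "nlr",
                       interactions = "lauren") {
  if (!all(interactions %in% main))
    stop("every interaction must reference a declared main term",
         call. = FALSE)
  if (!all(splines %in% main))
    stop("spline terms must be declared main terms", call. = FALSE)
  structure(list(main = main, treatment = treatment, splines = splines,
                 spline_k = spline_k, log_transform = log_transform,
                 interactions = interactions),
            class = "model_spec")
}

cov_meta <- function(spec, name, x) {
  if (is.factor(x) || is.character(x)) {
    x <- as.factor(x)
    list(type = "factor", levels = levels(x), reference = levels(x)[1])
  } else if (is.numeric(x) && all(x %in% c(0, 1))) {
    list(type = "binary")
  } else if (is.numeric(x)) {
    z <- if (name %in% spec$log_transform) log(x) else x
    ctr <- stats::median(z)
    scl <- stats::sd(z)
    if (!is.finite(scl) || scl == 0)
      stop("covariate '", name, "' is constant", call. = FALSE)
    m <- list(type = "numeric", log = name %in% spec$log_transform,
              center = ctr, scale = scl, knots = NULL)
    if (name %in% spec$splines)
      m$knots <- default_knots((z - ctr) / scl, spec$spline_k)
    m
  } else stop("unsupported covariate type: ", name, call. = FALSE)
}

encode_block <- function(meta, name, values) {
  if (meta$type == "factor") {
    v <- factor(values, levels = meta$levels)
    if (anyNA(v)) stop("invalid or missing value for '", name, "'",
                       call. = FALSE)
    lv <- meta$levels[-1]
    out <- vapply(lv, function(l) as.numeric(v == l), numeric(length(v)))
    out <- matrix(out, nrow = length(v),
                  dimnames = list(NULL, paste0(name, "=", lv)))
    out
  } else if (meta$type == "binary") {
    matrix(as.numeric(values), ncol = 1, dimnames = list(NULL, name))
  } else {
    x <- as.numeric(values)
    if (anyNA(x) || any(!is.finite(x)))
      stop("invalid or missing value for '", name, "'", call. = FALSE)
    z <- ((if (meta$log) log(x) else x) - meta$center) / meta$scale
    if (is.null(meta$knots))
      matrix(z, ncol = 1, dimnames = list(NULL, name))
    else {
      b <- rcs_basis(z, meta$knots)
      colnames(b) <- paste0(name, "_rcs", seq_len(ncol(b)))
      b
    }
  }
}

#' Build the design matrix and coefficient registry for a cohort
#'
#' Resolves the [model_spec()] against the data: factors are dummy-coded
#' against their first (reference) level, continuous covariates are centred
#' at their median and scaled by their standard deviation (constants stored
#' for later profile prediction), splined covariates get restricted cubic
#' bases with knots at the default quantiles, and each declared interaction
#' contributes the product of the treatment indicator with the covariate's
#' main-effect block. Every column is labelled and classed (`intercept`,
#' `treatment`, `interaction`, `nuisance`) for prior assignment.
#'
#' @param spec a [model_spec()].
#' @param data complete-case data.frame holding the treatment column and all
#'   covariates (no missing values; impute first).
#' @return object of class `aft_design`: list with the design matrix `X`,
#'   `labels`, `classes`, the per-column `map` (covariate, base label), the
#'   per-covariate encoding metadata, and the treatment column label.
#' @export
build_design <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  used <- c(spec$treatment, spec$main)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols))
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyNA(data[used]))
    stop("design covariates contain missing values; impute first",
         call. = FALSE)

  trt <- as.factor(data[[spec$treatment]])
  if (nlevels(trt) != 2)
    stop("treatment must have exactly two levels", call. = FALSE)
  trt_label <- paste0(spec$treatment, "=", levels(trt)[2])
  trt_col <- matrix(as.numeric(trt == levels(trt)[2]), ncol = 1,
                    dimnames = list(NULL, trt_label))

  meta <- lapply(stats::setNames(spec$main, spec$main),
                 function(v) cov_meta(spec, v, data[[v]]))

  blocks <- list(`(Intercept)` = matrix(1, nrow(data), 1,
                                        dimnames = list(NULL, "(Intercept)")),
                 treatment = trt_col)
  classes <- c("intercept", "treatment")
  map_cov <- c(NA, spec$treatment)
  for (v in spec$main) {
    b <- encode_block(meta[[v]], v, data[[v]])
    blocks[[v]] <- b
    classes <- c(classes, rep("nuisance", ncol(b)))
    map_cov <- c(map_cov, rep(v, ncol(b)))
  }
  base_label <- rep(NA_character_, length(classes))
  for (v in spec$interactions) {
    b <- blocks[[v]]
    ib <- b * trt_col[, 1]
    colnames(ib) <- paste0(trt_label, ":", colnames(b))
    blocks[[paste0("int:", v)]] <- ib
    classes <- c(classes, rep("interaction", ncol(ib)))
    map_cov <- c(map_cov, rep(v, ncol(ib)))
    base_label <- c(base_label, colnames(b))
  }
  X <- do.call(cbind, blocks)
  labels <- colnames(X)
  if (anyDuplicated(labels))
    stop("duplicated design column labels", call. = FALSE)
  structure(list(X = X, labels = labels, classes = classes,
                 map = data.frame(label = labels, class = classes,
                                  covariate = map_cov,
                                  base_label = base_label,
                                  stringsAsFactors = FALSE),
                 meta = meta, spec = spec,
                 treatment_label = trt_label,
                 treatment_levels = levels(trt)),
            class = "aft_design")
}

#' @export
print.aft_design <- function(x, ...) {
  cat("aft_design:", nrow(x$X), "rows x", ncol(x$X), "columns\n")
  print(x$map[, c("label", "class", "covariate")], row.names = FALSE)
  invisible(x)
}

#' Encode a single patient profile as a design row
#'
#' Applies the stored encodings (reference levels, centering constants, knot
#' positions) to one patient's covariate values, producing a row conformable
#' with the fitted design.
#'
#' @param design an [aft_design] from [build_design()].
#' @param profile named list of raw covariate values (every main-effect
#'   covariate must be present).
#' @param arm treatment level for the row (default the reference arm).
#' @return numeric 1 x p matrix with the design's column labels.
#' @export
design_row <- function(design, profile, arm = design$treatment_levels[1]) {
  spec <- design$spec
  miss <- setdiff(spec$main, names(profile))
  if (length(miss))
    stop("profile lacks value(s) for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!arm %in% design$treatment_levels)
    stop("unknown treatment level: ", arm, call. = FALSE)
  trt <- as.numeric(arm == design$treatment_levels[2])
  row <- c("(Intercept)" = 1)
  row[design$treatment_label] <- trt
  for (v in spec$main) {
    b <- encode_block(design$meta[[v]], v, profile[[v]])
    row[colnames(b)] <- b[1, ]
  }
  for (v in spec$interactions) {
    b <- encode_block(design$meta[[v]], v, profile[[v]])
    row[paste0(design$treatment_label, ":", colnames(b))] <- trt * b[1, ]
  }
  matrix(row[design$labels], nrow = 1,
         dimnames = list(NULL, design$labels))
}

# per-draw multipliers of the interaction coefficients implied by a profile:
# named vector over interaction labels (the encoded base-covariate values)
interaction_multipliers <- function(design, profile) {
  int <- design$map[design$map$class == "interaction", , drop = FALSE]
  if (nrow(int) == 0) return(stats::setNames(numeric(0), character(0)))
  out <- numeric(nrow(int))
  for (v in unique(int$covariate)) {
    if (!v %in% names(profile))
      stop("profile lacks value for interacting covariate '", v, "'",
           call. = FALSE)
    b <- encode_block(design$meta[[v]], v, profile[[v]])
    sel <- int$covariate == v
    out[sel] <- b[1, match(int$base_label[sel], colnames(b))]
  }
  stats::setNames(out, int$label)
}
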