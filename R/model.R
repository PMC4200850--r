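.coef_names <- c("quality", "sx", "au", "ot", "te")
.feature_cols <- c("quality", "dev_sx", "dev_au", "dev_ot", "dev_te")

#' Construct an ALMA linear discriminant model
#'
#' The model is an affine score over five features: the quality-weighted
#' descriptor term `p(c_l) * theta_5` and the four moving-average
#' deviation terms for the experimental measure (`sx`), assay (`au`),
#' organism (`ot`) and target (`te`) condition classes.
#'
#' @param intercept Numeric intercept `a_0`.
#' @param coef Named numeric vector with entries `quality`, `sx`, `au`,
#'   `ot`, `te`.
#' @param cutoff Probability cutoff for classification (default 0.5;
#'   links require `p > cutoff`, strictly).
#' @param link Score-to-probability link; only `"logistic"` is defined.
#' @param meta List of fit diagnostics (`N`, `Rc`, `chi2`, ...); purely
#'   informational.
#' @return An object of class `alma_model`.
#' @export
alma_model <- function(intercept, coef, cutoff = 0.5, link = "logistic",
                       meta = list()) {
  coef <- coef[.coef_names]
  if (anyNA(coef) || !all(is.finite(coef)) || !is.finite(intercept))
    stop(alma_error(
      "model needs finite intercept and coefficients named quality, sx, au, ot, te",
      class = "alma_domain_error"))
  if (!identical(link, "logistic"))
    stop(alma_error(sprintf("unknown link '%s'", link),
                    class = "alma_domain_error"))
  structure(list(intercept = as.numeric(intercept),
                 coef = stats::setNames(as.numeric(coef), .coef_names),
                 cutoff = cutoff, link = link, meta = meta),
            class = "alma_model")
}

#' @export
print.alma_model <- function(x, ...) {
  cat("<alma_model>\n")
  cat(sprintf("  score = %.6f %+.6f*quality %+.6f*dev_sx %+.6f*dev_au %+.6f*dev_ot %+.6f*dev_te\n",
              x$intercept, x$coef["quality"], x$coef["sx"], x$coef["au"],
              x$coef["ot"], x$coef["te"]))
  cat(sprintf("  cutoff = %g, link = %s\n", x$cutoff, x$link))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), vapply(x$meta, format, ""),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' The published reference model
#'
#' Loads the fixed-coefficient ALMA-entropy model shipped with the
#' package (`extdata/reference_eq2.json`): intercept 1.139556 and
#' coefficients -0.403994 (quality), +0.199322 (sx), +0.434889 (au),
#' -0.020189 (ot), -0.001660 (te). Its probabilities use the logistic
#' link centred at score 0, which is an approximation: the original fit's
#' exact posterior mapping was not published.
#'
#' @return An `alma_model`.
#' @export
reference_model <- function() {
  path <- system.file("extdata", "reference_eq2.json", package = "almanet",
                      mustWork = TRUE)
  read_model(path)
}

#' Read / write a model as JSON
#'
#' The JSON layout is
#' `{"intercept":..., "coef":{"quality":..., "sx":..., "au":..., "ot":...,
#' "te":...}, "cutoff":0.5, "link":"logistic", "meta":{...}}`.
#'
#' @param path File path.
#' @return `read_model` returns an `alma_model`; `write_model` returns
#'   the path, invisibly.
#' @export
read_model <- function(path) {
  if (!file.exists(path))
    stop(alma_error(sprintf("model file not found: %s", path)))
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(spec$intercept) || is.null(spec$coef))
    stop(alma_error(sprintf("model file %s lacks intercept/coef", path)))
  alma_model(intercept = spec$intercept, coef = unlist(spec$coef),
             cutoff = if (is.null(spec$cutoff)) 0.5 else spec$cutoff,
             link = if (is.null(spec$link)) "logistic" else spec$link,
             meta = as.list(spec$meta))
}

#' @rdname read_model
#' @param model An `alma_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "alma_model"))
  jsonlite::write_json(
    list(intercept = model$intercept, coef = as.list(model$coef),
         cutoff = model$cutoff, link = model$link, meta = model$meta),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Score feature vectors with an ALMA model
#'
#' The score is a pure affine function:
#' `S = a0 + a_quality * quality + a_sx * dev_sx + a_au * dev_au +
#' a_ot * dev_ot + a_te * dev_te`.
#'
#' @param model An `alma_model`.
#' @param features A data frame (or matrix) with columns `quality`,
#'   `dev_sx`, `dev_au`, `dev_ot`, `dev_te`; one row per record.
#' @return Numeric vector of scores.
#' @export
alma_score <- function(model, features) {
  stopifnot(inherits(model, "alma_model"))
  X <- as.matrix(as.data.frame(features)[, .feature_cols, drop = FALSE])
  as.numeric(model$intercept + X %*% model$coef)
}

#' Map a score to a link probability
#'
#' Monotone logistic map `p = 1 / (1 + exp(-(S - midpoint)))`. For models
#' fitted with [fit_alma_lda()] the score is the log posterior odds, so
#' the midpoint is 0 and the result is the discriminant posterior. For
#' the fixed reference model the same midpoint-0 logistic is used as a
#' documented approximation.
#'
#' @param model An `alma_model`; `model$meta$score_midpoint` (default 0)
#'   sets the decision midpoint.
#' @param score Numeric vector of scores.
#' @return Probabilities in (0, 1).
#' @export
alma_probability <- function(model, score) {
  stopifnot(inherits(model, "alma_model"))
  mid <- model$meta$score_midpoint
  if (is.null(mid)) mid <- 0
  stats::plogis(score - mid)
}

#' Classify probabilities against the model cutoff
#'
#' A link is predicted (`1`) when `p > cutoff`, strictly: a probability
#' exactly at the cutoff classifies as 0.
#'
#' @param model An `alma_model`.
#' @param prob Numeric vector of probabilities.
#' @return Integer vector of 0/1 predicted labels.
#' @export
alma_classify <- function(model, prob) {
  stopifnot(inherits(model, "alma_model"))
  as.integer(prob > model$cutoff)
}
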