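#' Fit the ALMA linear discriminant
#'
#' Two-class Gaussian linear discriminant on the five moving-average
#' features, with pooled within-class covariance and empirical class
#' priors. The returned score is the log posterior odds
#' `log p(L=1|x) / p(L=0|x)`, so the decision boundary (posterior 0.5)
#' sits at score 0 and [alma_probability()] returns the discriminant
#' posterior directly.
#'
#' Fit diagnostics stored in `meta`: `N`, the canonical correlation `Rc`
#' (correlation between the discriminant scores and the class
#' indicator), and Bartlett's chi-square for the discriminant.
#'
#' @param features Data frame with columns `quality`, `dev_sx`,
#'   `dev_au`, `dev_ot`, `dev_te`.
#' @param labels Integer vector of 0/1 class labels.
#' @param ridge Non-negative ridge added to the pooled covariance
#'   diagonal; use a small value if the covariance is singular.
#' @param cutoff Probability cutoff stored in the model (default 0.5).
#' @return An `alma_model`.
#' @export
fit_alma_lda <- function(features, labels, ridge = 0, cutoff = 0.5) {
  X <- as.matrix(as.data.frame(features)[, .feature_cols, drop = FALSE])
  y <- as.integer(labels)
  if (nrow(X) != length(y))
    stop(alma_error("features and labels differ in length",
                    class = "alma_domain_error"))
  if (nrow(X) < 6L)
    stop(alma_error("need at least 6 records to fit",
                    class = "alma_domain_error"))
  if (!all(y %in% c(0L, 1L)) || length(unique(y)) < 2L)
    stop(alma_error("both classes (0 and 1) must be present",
                    class = "alma_domain_error"))
  n0 <- sum(y == 0L); n1 <- sum(y == 1L)
  mu0 <- colMeans(X[y == 0L, , drop = FALSE])
  mu1 <- colMeans(X[y == 1L, , drop = FALSE])
  S0 <- stats::cov(X[y == 0L, , drop = FALSE])
  S1 <- stats::cov(X[y == 1L, , drop = FALSE])
  Sp <- ((n0 - 1L) * S0 + (n1 - 1L) * S1) / (n0 + n1 - 2L)
  if (ridge > 0) Sp <- Sp + diag(ridge, ncol(X))
  w <- tryCatch(solve(Sp, mu1 - mu0), error = function(e)
    stop(alma_error(
      "pooled within-class covariance is singular; refit with ridge > 0",
      class = "alma_numerical_error")))
  a0 <- log(n1 / n0) - 0.5 * sum((mu1 + mu0) * w)
  scores <- as.numeric(a0 + X %*% w)
  rc <- suppressWarnings(stats::cor(scores, y))
  p <- ncol(X)
  lambda <- 1 - rc^2                       # Wilks' lambda, two groups
  chi2 <- -(nrow(X) - 1 - (p + 2) / 2) * log(lambda)
  alma_model(intercept = a0,
             coef = stats::setNames(as.numeric(w), .coef_names),
             cutoff = cutoff,
             meta = list(N = nrow(X), Rc = rc, chi2 = chi2, df = p,
                         score_midpoint = 0))
}

#' Stratified train/validation split
#'
#' Random split preserving the label proportions, mirroring the common
#' 75/25 design for this model family.
#'
#' @param labels Integer 0/1 labels.
#' @param train_fraction Fraction assigned to training (default 0.75).
#' @param seed Integer seed for the split.
#' @return Logical vector, `TRUE` for training rows.
#' @export
stratified_split <- function(labels, train_fraction = 0.75, seed = 1L) {
  y <- as.integer(labels)
  train <- logical(length(y))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    k <- round(length(idx) * train_fraction)
    train[sample(idx, k)] <- TRUE
  }
  train
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) return(invisible())
  assign(".Random.seed", old, envir = globalenv())
}

#' Score and classify a table of endpoint records
#'
#' One prediction per record: moving-average features are assembled
#' against the frozen condition statistics, scored with the model, and
#' mapped to a link probability and a 0/1 predicted label. The same
#' compound receives different scores under different condition sets.
#'
#' @param model An `alma_model`.
#' @param records Endpoint records (labels optional; copied through when
#'   present).
#' @param descriptors Data frame with `compound_id` and `theta5`.
#' @param stats Frozen condition statistics ([condition_stats()]).
#' @param strict Condition-lookup mode, see [ma_features()].
#' @return Data frame with the record's identifying columns plus
#'   `theta5`, `score`, `prob` and `label_pred` (and `label` if the
#'   input carried one).
#' @export
predict_table <- function(model, records, descriptors, stats,
                          strict = TRUE) {
  stopifnot(inherits(model, "alma_model"))
  id_cols <- intersect(
    c("compound_id", "curation_level", "measure", "assay_id",
      "organism", "target_id", "label"),
    names(records))
  if (nrow(records) == 0L) {
    out <- records[, id_cols, drop = FALSE]
    out$theta5 <- numeric(0); out$score <- numeric(0)
    out$prob <- numeric(0); out$label_pred <- integer(0)
    return(out)
  }
  feats <- ma_features(records, descriptors, stats, strict = strict)
  s <- alma_score(model, feats)
  p <- alma_probability(model, s)
  out <- records[, id_cols, drop = FALSE]
  out$theta5 <- .theta5_lookup(records, descriptors)
  out$score <- s
  out$prob <- p
  out$label_pred <- alma_classify(model, p)
  rownames(out) <- NULL
  out
}
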