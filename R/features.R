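# The four assay-context condition classes and the endpoint-table columns
# that carry them.
.condition_classes <- c(sx = "measure", au = "assay_id",
                        ot = "organism", te = "target_id")

#' Data-quality probability of a curation level
#'
#' Maps the curation level of a database record to the data-quality
#' probability entering the model's first term: 1.0 for expert, 0.75 for
#' intermediate, 0.5 for auto-curation.
#'
#' @param level Character vector with values `"expert"`,
#'   `"intermediate"` or `"autocuration"`.
#' @return Numeric vector in \{1, 0.75, 0.5\}.
#' @export
curation_probability <- function(level) {
  p <- c(expert = 1.0, intermediate = 0.75, autocuration = 0.5)[level]
  if (anyNA(p))
    stop(alma_error(sprintf(
      "unknown curation level(s): %s",
      paste(unique(level[is.na(p)]), collapse = ", "))))
  unname(p)
}

.theta5_lookup <- function(records, descriptors) {
  if (!all(c("compound_id", "theta5") %in% names(descriptors)))
    stop(alma_error("descriptor table needs columns compound_id, theta5"))
  idx <- match(records$compound_id, descriptors$compound_id)
  theta5 <- descriptors$theta5[idx]
  bad <- is.na(theta5)
  if (any(bad))
    stop(alma_error(sprintf(
      "no theta5 descriptor for compound(s): %s",
      paste(unique(records$compound_id[bad]), collapse = ", "))))
  theta5
}

#' Moving-average statistics per condition subset
#'
#' For every distinct value of each condition class (experimental
#' measure, assay, organism, target) this computes the subset size `n`,
#' the number of active records `n1`, the activity prior `p1 = n1 / n`,
#' the mean `theta_5` over the *active* compounds of the subset, and the
#' moving-average value `ma_value = p1 * mean_theta5`. Subsets with no
#' active record get `mean_theta5 = 0` and `ma_value = 0`.
#'
#' These statistics should be computed on the training records only and
#' frozen for validation and prediction.
#'
#' @param records Endpoint records (see [read_endpoints()]) with labels.
#' @param descriptors Data frame with `compound_id` and `theta5`.
#' @param classes Which condition classes to tabulate (default all four:
#'   `"sx"`, `"au"`, `"ot"`, `"te"`).
#' @return Data frame with columns `condition_class`, `condition_value`,
#'   `n`, `n1`, `p1`, `mean_theta5`, `ma_value`.
#' @export
condition_stats <- function(records, descriptors,
                            classes = names(.condition_classes)) {
  stopifnot(is.data.frame(records))
  classes <- match.arg(classes, names(.condition_classes),
                       several.ok = TRUE)
  if (!"label" %in% names(records) || anyNA(records$label))
    stop(alma_error("condition statistics need labelled records"))
  theta5 <- .theta5_lookup(records, descriptors)
  active <- records$label == 1L
  out <- lapply(classes, function(cl) {
    col <- .condition_classes[[cl]]
    value <- as.character(records[[col]])
    n <- tapply(value, value, length)
    vals <- names(n)
    n1 <- tabulate(factor(value[active], levels = vals),
                   nbins = length(vals))
    sum_theta <- vapply(vals, function(v)
      sum(theta5[active & value == v]), numeric(1L))
    mean_theta <- ifelse(n1 > 0, sum_theta / pmax(n1, 1L), 0)
    p1 <- as.numeric(n1) / as.numeric(n)
    data.frame(condition_class = cl, condition_value = vals,
               n = as.integer(n), n1 = as.integer(n1), p1 = p1,
               mean_theta5 = mean_theta, ma_value = p1 * mean_theta,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# ma_value lookup per class, with optional global (all-active) fallback.
.stats_lookup <- function(stats, class, values, strict) {
  sub <- stats[stats$condition_class == class, , drop = FALSE]
  idx <- match(values, sub$condition_value)
  ma <- sub$ma_value[idx]
  miss <- is.na(idx)
  if (any(miss)) {
    if (strict)
      stop(alma_error(sprintf(
        "no moving-average statistics for %s value(s): %s (use lenient mode to fall back to the global active-set value)",
        class, paste(unique(values[miss]), collapse = ", "))))
    n <- sum(sub$n); n1 <- sum(sub$n1)
    global_mean <- if (n1 > 0) sum(sub$mean_theta5 * sub$n1) / n1 else 0
    ma[miss] <- (n1 / n) * global_mean
  }
  ma
}

#' Box-Jenkins moving-average feature vectors
#'
#' Assembles the five model features for each record: the quality term
#' `p(c_l) * theta_5` and, per condition class, the deviation
#' `theta_5 - ma_value(condition)` of the compound's descriptor from the
#' condition's moving-average value.
#'
#' @param records Endpoint records; labels are not required.
#' @param descriptors Data frame with `compound_id` and `theta5`.
#' @param stats Condition statistics from [condition_stats()] (computed
#'   on the training records).
#' @param strict If `TRUE` (default) an unseen condition value is an
#'   error; if `FALSE` the global active-set moving-average value of the
#'   class is substituted.
#' @return Data frame with columns `quality`, `dev_sx`, `dev_au`,
#'   `dev_ot`, `dev_te`, one row per record.
#' @export
ma_features <- function(records, descriptors, stats, strict = TRUE) {
  stopifnot(is.data.frame(records), is.data.frame(stats))
  theta5 <- .theta5_lookup(records, descriptors)
  p_cl <- curation_probability(as.character(records$curation_level))
  out <- data.frame(quality = p_cl * theta5)
  for (cl in names(.condition_classes)) {
    values <- as.character(records[[.condition_classes[[cl]]]])
    ma <- .stats_lookup(stats, cl, values, strict)
    out[[paste0("dev_", cl)]] <- theta5 - ma
  }
  out
}
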