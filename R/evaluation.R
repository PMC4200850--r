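#' Confusion matrix with per-class rates
#'
#' Builds the 2x2 observed-by-predicted contingency table and the
#' row-wise correct-classification rates. Rates are kept at full
#' precision internally; rounding to one decimal place happens only at
#' report time.
#'
#' The rates are orientation-neutral: `rate_obs1` is the percentage of
#' observed-1 records classified 1, `rate_obs0` the percentage of
#' observed-0 records classified 0, `accuracy` the overall percentage
#' correct. How the rates are labelled Sn/Sp is a layout decision made
#' in [report_table()].
#'
#' @param observed,predicted Equal-length vectors of 0/1 labels.
#' @return An object of class `confusion_summary`: `counts` (matrix,
#'   rows `obs1`/`obs0`, columns `pred1`/`pred0`), `rate_obs1`,
#'   `rate_obs0`, `accuracy` (percent), `n`.
#' @export
confusion_summary <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop(alma_error("observed and predicted differ in length",
                    class = "alma_domain_error"))
  if (length(observed) == 0L)
    stop(alma_error("cannot summarize an empty prediction set",
                    class = "alma_domain_error"))
  obs <- as.integer(observed); pred <- as.integer(predicted)
  if (!all(obs %in% 0:1) || !all(pred %in% 0:1))
    stop(alma_error("labels must be 0 or 1", class = "alma_domain_error"))
  counts <- matrix(
    c(sum(obs == 1L & pred == 1L), sum(obs == 1L & pred == 0L),
      sum(obs == 0L & pred == 1L), sum(obs == 0L & pred == 0L)),
    nrow = 2L, byrow = TRUE,
    dimnames = list(c("obs1", "obs0"), c("pred1", "pred0")))
  structure(list(
    counts = counts,
    rate_obs1 = 100 * counts["obs1", "pred1"] / sum(counts["obs1", ]),
    rate_obs0 = 100 * counts["obs0", "pred0"] / sum(counts["obs0", ]),
    accuracy = 100 * (counts["obs1", "pred1"] + counts["obs0", "pred0"]) /
      sum(counts),
    n = sum(counts)),
    class = "confusion_summary")
}

#' Build a confusion summary from printed counts
#'
#' Convenience constructor for the four cell counts of a published
#' confusion matrix, in the row order observed-1 (correct, wrong) then
#' observed-0 (wrong, correct).
#'
#' @param obs1_correct,obs1_wrong Observed-1 records predicted 1 / 0.
#' @param obs0_wrong,obs0_correct Observed-0 records predicted 1 / 0.
#' @return A `confusion_summary`.
#' @export
confusion_from_counts <- function(obs1_correct, obs1_wrong,
                                  obs0_wrong, obs0_correct) {
  confusion_summary(
    observed = rep(c(1L, 0L), c(obs1_correct + obs1_wrong,
                                obs0_wrong + obs0_correct)),
    predicted = c(rep(c(1L, 0L), c(obs1_correct, obs1_wrong)),
                  rep(c(1L, 0L), c(obs0_wrong, obs0_correct))))
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("<confusion_summary>\n")
  print(x$counts)
  cat(sprintf("  obs-1 rate %.1f%%, obs-0 rate %.1f%%, accuracy %.1f%% (n = %d)\n",
              x$rate_obs1, x$rate_obs0, x$accuracy, x$n))
  invisible(x)
}

# Label orientation. The published table pairs the label "Sp" with the
# observed-link row and "Sn" with the observed-0 row, while the
# conventional definition is the opposite; both layouts are offered.
.metric_rows <- function(cs, labels = c("table", "conventional")) {
  labels <- match.arg(labels)
  if (labels == "table") {
    m <- c(Sp = "rate_obs1", Sn = "rate_obs0", Ac = "accuracy")
  } else {
    m <- c(Sn = "rate_obs1", Sp = "rate_obs0", Ac = "accuracy")
  }
  num <- c(rate_obs1 = cs$counts["obs1", "pred1"],
           rate_obs0 = cs$counts["obs0", "pred0"],
           accuracy = cs$counts["obs1", "pred1"] + cs$counts["obs0", "pred0"])
  den <- c(rate_obs1 = sum(cs$counts["obs1", ]),
           rate_obs0 = sum(cs$counts["obs0", ]),
           accuracy = cs$n)
  data.frame(metric = names(m),
             value_percent = round(unlist(cs[m]), 1),
             numerator = as.integer(num[m]),
             denominator = as.integer(den[m]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sn/Sp/Ac report over one or more confusion summaries
#'
#' Produces the flat report table `model,split,metric,value_percent,`
#' `numerator,denominator`, one Sp/Sn/Ac block per summary, in input
#' order.
#'
#' @param summaries A named list. Each element is either a
#'   `confusion_summary` (the name becomes the model, split is `""`) or
#'   a named list of `confusion_summary` objects keyed by split (e.g.
#'   `list(Train = ..., CV = ...)`).
#' @param labels `"table"` (default) pairs Sp with the observed-1 row,
#'   matching the published layout; `"conventional"` uses the standard
#'   sensitivity/specificity orientation.
#' @return A data frame.
#' @export
report_table <- function(summaries, labels = "table") {
  if (!length(summaries))
    stop(alma_error("no summaries to report", class = "alma_domain_error"))
  if (inherits(summaries, "confusion_summary"))
    summaries <- list(model = summaries)
  blocks <- list()
  for (m in seq_along(summaries)) {
    el <- summaries[[m]]
    if (inherits(el, "confusion_summary")) el <- list(el)
    splits <- names(el)
    if (is.null(splits)) splits <- rep("", length(el))
    for (s in seq_along(el)) {
      rows <- .metric_rows(el[[s]], labels)
      rows <- cbind(model = names(summaries)[m], split = splits[[s]],
                    rows)
      blocks[[length(blocks) + 1L]] <- rows
    }
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
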