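# CSV dialect used everywhere: UTF-8, comma separated, "." decimal
# point, LF line endings; strings with embedded commas (measure names
# like "Ki (nM)") are quoted. Floats are serialized with %.17g so a
# write/read round-trip is bit-stable.

.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

.endpoint_cols <- c("compound_id", "smiles", "curation_level", "measure",
                    "assay_id", "organism", "target_id", "label")

#' Read an endpoint table
#'
#' Reads the multi-output assay endpoint CSV with header
#' `compound_id,smiles,curation_level,measure,assay_id,organism,`
#' `target_id,label`. Labels must be 0, 1, or blank (prediction-only
#' records). Extra columns are accepted with a warning and ignored.
#'
#' @param path CSV file path.
#' @return Data frame of endpoint records; `label` is integer with `NA`
#'   for blank entries.
#' @export
read_endpoints <- function(path) {
  if (!file.exists(path))
    stop(alma_error(sprintf("endpoint file not found: %s", path)))
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE)
  missing <- setdiff(.endpoint_cols, names(df))
  if (length(missing))
    stop(alma_error(sprintf("endpoint file %s lacks column(s): %s",
                            path, paste(missing, collapse = ", "))))
  extra <- setdiff(names(df), .endpoint_cols)
  if (length(extra)) {
    warning(sprintf("ignoring extra endpoint column(s): %s",
                    paste(extra, collapse = ", ")))
    df <- df[, .endpoint_cols, drop = FALSE]
  }
  bad_label <- !(df$label %in% c("0", "1", ""))
  if (any(bad_label))
    stop(alma_error(sprintf(
      "invalid label value(s) '%s' at line(s): %s (labels must be 0, 1 or blank)",
      paste(unique(df$label[bad_label]), collapse = "', '"),
      paste(utils::head(which(bad_label) + 1L, 10L), collapse = ", "))))
  bad_cur <- !(df$curation_level %in%
                 c("expert", "intermediate", "autocuration"))
  if (any(bad_cur))
    stop(alma_error(sprintf(
      "invalid curation_level value(s) at line(s): %s",
      paste(utils::head(which(bad_cur) + 1L, 10L), collapse = ", "))))
  df$label <- ifelse(df$label == "", NA_integer_, as.integer(df$label))
  df
}

#' Write an endpoint table
#'
#' @param records Endpoint records.
#' @param path CSV file path.
#' @return The path, invisibly.
#' @export
write_endpoints <- function(records, path) {
  out <- records[, .endpoint_cols, drop = FALSE]
  out$label <- ifelse(is.na(out$label), "", as.character(out$label))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read molecules from a SMILES file or CSV
#'
#' Accepts either a one-record-per-line SMILES file
#' (`<smiles><TAB><id>`; the id defaults to the SMILES when absent) or a
#' CSV with `compound_id` and `smiles` columns (detected from the
#' header).
#'
#' @param path Input file.
#' @return Data frame with columns `compound_id`, `smiles`.
#' @export
read_smiles <- function(path) {
  if (!file.exists(path))
    stop(alma_error(sprintf("SMILES file not found: %s", path)))
  first <- readLines(path, n = 1L)
  if (grepl("compound_id", first) && grepl("smiles", first)) {
    df <- utils::read.csv(path, colClasses = "character")
    if (!all(c("compound_id", "smiles") %in% names(df)))
      stop(alma_error(sprintf(
        "CSV %s needs compound_id and smiles columns", path)))
    return(df[, c("compound_id", "smiles")])
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    stop(alma_error(sprintf("no molecules in %s", path)))
  parts <- strsplit(lines, "[\t ]+")
  data.frame(
    compound_id = vapply(parts, function(p)
      if (length(p) >= 2L) p[[2L]] else p[[1L]], character(1L)),
    smiles = vapply(parts, `[[`, character(1L), 1L),
    stringsAsFactors = FALSE)
}

#' Descriptor table writer/reader
#'
#' The descriptor CSV has columns `compound_id,theta0,...,theta<k>` (and
#' an `error` column when failures occurred); floats are written at full
#' round-trip precision.
#'
#' @param block Descriptor table from [descriptor_block()].
#' @param path CSV file path.
#' @return `write_descriptors` the path, invisibly; `read_descriptors` a
#'   data frame with numeric theta columns.
#' @export
write_descriptors <- function(block, path) {
  out <- block[, !(names(block) %in% "smiles"), drop = FALSE]
  if ("error" %in% names(out) && all(is.na(out$error)))
    out$error <- NULL
  for (col in grep("^theta", names(out), value = TRUE))
    out[[col]] <- .fmt_num(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  if (!file.exists(path))
    stop(alma_error(sprintf("descriptor file not found: %s", path)))
  df <- utils::read.csv(path, colClasses = "character")
  if (!"compound_id" %in% names(df) ||
      !any(grepl("^theta", names(df))))
    stop(alma_error(sprintf(
      "%s is not a descriptor table (compound_id + theta columns)", path)))
  for (col in grep("^theta", names(df), value = TRUE))
    df[[col]] <- as.numeric(df[[col]])
  df
}

#' Condition-statistics table writer/reader
#'
#' CSV columns: `condition_class,condition_value,n,n1,p1,mean_theta5,`
#' `ma_value`.
#'
#' @param stats Condition statistics from [condition_stats()].
#' @param path CSV file path.
#' @return `write_condition_stats` the path, invisibly;
#'   `read_condition_stats` the data frame.
#' @export
write_condition_stats <- function(stats, path) {
  out <- stats
  for (col in c("p1", "mean_theta5", "ma_value"))
    out[[col]] <- .fmt_num(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_condition_stats
#' @export
read_condition_stats <- function(path) {
  if (!file.exists(path))
    stop(alma_error(sprintf("condition-stats file not found: %s", path)))
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("condition_class", "condition_value", "n", "n1", "p1",
            "mean_theta5", "ma_value")
  if (!all(need %in% names(df)))
    stop(alma_error(sprintf("%s is not a condition-stats table", path)))
  df$n <- as.integer(df$n); df$n1 <- as.integer(df$n1)
  for (col in c("p1", "mean_theta5", "ma_value"))
    df[[col]] <- as.numeric(df[[col]])
  df
}

#' Prediction table writer/reader
#'
#' @param predictions Prediction table from [predict_table()].
#' @param path CSV file path.
#' @return `write_predictions` the path, invisibly; `read_predictions`
#'   the data frame with numeric score/prob columns.
#' @export
write_predictions <- function(predictions, path) {
  out <- predictions
  for (col in intersect(c("theta5", "score", "prob"), names(out)))
    out[[col]] <- .fmt_num(out[[col]])
  if ("label" %in% names(out))
    out$label <- ifelse(is.na(out$label), "", as.character(out$label))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  if (!file.exists(path))
    stop(alma_error(sprintf("prediction file not found: %s", path)))
  df <- utils::read.csv(path, colClasses = "character")
  for (col in intersect(c("theta5", "score", "prob"), names(df)))
    df[[col]] <- as.numeric(df[[col]])
  if ("label" %in% names(df))
    df$label <- ifelse(df$label == "", NA_integer_, as.integer(df$label))
  if ("label_pred" %in% names(df))
    df$label_pred <- as.integer(df$label_pred)
  df
}
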