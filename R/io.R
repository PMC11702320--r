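# File formats:
#   single counts:  CSV, header "tp,fp,fn,tn", one data row
#   paired counts:  CSV, header "i,j,k,count", the 8 (i,j,k) cells exactly once
#   labels:         CSV with columns actual,predicted (single) or
#                   actual,pred1,pred2 (paired), values 0/1

#' Read a confusion-count file
#'
#' @param path Path to a CSV file. A header `tp,fp,fn,tn` with one data row
#'   yields a [confusion_counts()] object; a header `i,j,k,count` whose rows
#'   cover all eight (i, j, k) cells exactly once yields a [paired_counts()]
#'   object.
#' @return A `confusion_counts` or `paired_counts` object.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, strip.white = TRUE)
  if (identical(names(df), c("tp", "fp", "fn", "tn"))) {
    if (nrow(df) != 1)
      stop("single-table file must have exactly one data row (line 2), got ",
           nrow(df), call. = FALSE)
    if (any(is.na(df)) || any(df < 0))
      stop("negative or missing count at line 2", call. = FALSE)
    return(confusion_counts(df$tp, df$fp, df$fn, df$tn))
  }
  if (identical(names(df), c("i", "j", "k", "count"))) {
    if (any(!unlist(df[c("i", "j", "k")]) %in% c(0, 1)))
      stop("i, j, k must be 0/1", call. = FALSE)
    key <- paste0("p", df$i, df$j, df$k)
    dup <- which(duplicated(key))
    if (length(dup))
      stop("duplicate cell (", key[dup[1]], ") at line ", dup[1] + 1, call. = FALSE)
    missing <- setdiff(.PAIRED_CELLS, key)
    if (length(missing))
      stop("missing cell: ", paste(missing, collapse = ", "), call. = FALSE)
    if (any(is.na(df$count)) || any(df$count < 0))
      stop("negative or missing count at line ",
           which(is.na(df$count) | df$count < 0)[1] + 1, call. = FALSE)
    cnt <- stats::setNames(df$count, key)
    return(paired_counts(cnt[.PAIRED_CELLS]))
  }
  stop("unrecognized header: expected tp,fp,fn,tn or i,j,k,count", call. = FALSE)
}

#' Write a confusion-count file
#'
#' Inverse of [read_counts()]; round-trips exactly.
#'
#' @param counts A `confusion_counts` or `paired_counts` object.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  if (inherits(counts, "confusion_counts")) {
    df <- data.frame(tp = counts[["tp"]], fp = counts[["fp"]],
                     fn = counts[["fn"]], tn = counts[["tn"]])
  } else if (inherits(counts, "paired_counts")) {
    idx <- do.call(rbind, strsplit(substring(names(counts), 2), ""))
    df <- data.frame(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
                     k = as.integer(idx[, 3]), count = as.integer(counts))
  } else stop("expected a confusion_counts or paired_counts object", call. = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read binary label columns
#'
#' @param path Path to a CSV file with columns `actual,predicted`
#'   (`paired = FALSE`) or `actual,pred1,pred2` (`paired = TRUE`), values 0/1.
#' @param paired Whether to expect two prediction columns.
#' @return A list of 0/1 integer vectors named after the columns.
#' @export
read_labels <- function(path, paired = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, strip.white = TRUE)
  want <- if (paired) c("actual", "pred1", "pred2") else c("actual", "predicted")
  missing <- setdiff(want, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  df <- df[want]
  bad <- which(apply(df, 1, function(r) any(is.na(r)) || any(!r %in% c(0, 1))))
  if (length(bad))
    stop(length(bad), " row(s) with missing or non-binary values; first at row ",
         bad[1], call. = FALSE)
  lapply(df, as.integer)
}

#' Write an analysis report
#'
#' Serializes interval, metric, coverage or grid results. Floats are written
#' with 6 significant digits; undefined values appear as the literal string
#' `"NA"` together with the reason field, never as empty cells.
#'
#' @param results An `mcc_ci` object, a list of them, a metric list from
#'   [metric_set()], or a `data.frame` (coverage or grid results).
#' @param format `"json"` or `"tsv"`.
#' @param path Output path, or `""` to write to stdout.
#' @return The path, invisibly.
#' @export
write_report <- function(results, format = c("json", "tsv"), path = "") {
  format <- match.arg(format)
  if (inherits(results, "mcc_ci")) results <- list(results)
  if (is.list(results) && length(results) && inherits(results[[1]], "mcc_ci")) {
    df <- do.call(rbind, lapply(results, function(ci)
      data.frame(method = ci$method, estimate = .fmt6(ci$estimate),
                 lower = .fmt6(ci$lower), upper = .fmt6(ci$upper),
                 level = ci$level, na = ci$na, na_reason = ci$na_reason,
                 stringsAsFactors = FALSE)))
  } else if (is.data.frame(results)) {
    df <- results
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], .fmt6)
  } else if (is.list(results)) {
    df <- data.frame(metric = names(results),
                     value = vapply(results, .fmt6, character(1)),
                     stringsAsFactors = FALSE)
  } else stop("unsupported results object", call. = FALSE)
  out <- if (format == "json") {
    jsonlite::toJSON(df, dataframe = "rows", pretty = TRUE, na = "string")
  } else {
    paste(c(paste(names(df), collapse = "\t"),
            apply(df, 1, paste, collapse = "\t")), collapse = "\n")
  }
  if (identical(path, "")) cat(out, "\n", sep = "") else writeLines(out, path)
  invisible(path)
}

.fmt6 <- function(x) {
  x <- as.numeric(x)
  ifelse(is.na(x), "NA", as.character(signif(x, 6)))
}
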