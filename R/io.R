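# Reading and writing the pipeline's delimited-text artifacts.
#
# Response CSV schema: person_id,gender,age_group,item01..itemJJ with scores
# 0..3 (blank or NA for missing); gender in {M, F}, age_group in
# {younger, older}. Unknown extra columns are kept as metadata.

#' Read a response table from CSV
#'
#' Validates the schema: unique `person_id`, item scores integers within
#' 0..`max_score` (or missing). Malformed cells raise an error naming the
#' row and column.
#'
#' @param path CSV file path.
#' @param max_score Largest admissible item score (default 3).
#' @return A validated response tibble.
#' @export
read_responses <- function(path, max_score = 3) {
  df <- tryCatch(
    as_tibble(read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))),
    error = function(e) abort(paste0("Cannot read `", path, "`: ", conditionMessage(e)))
  )
  if (nrow(df) == 0) abort(paste0("`", path, "` contains no data rows."))
  if (!"person_id" %in% names(df)) abort("Missing `person_id` column.")
  if (anyDuplicated(df$person_id)) {
    dup <- df$person_id[duplicated(df$person_id)][1]
    abort(paste0("Duplicate person_id: ", dup, "."))
  }
  item_cols <- grep("^item[0-9]+$", names(df), value = TRUE)
  if (length(item_cols) == 0) abort("No item columns (item01, ...) found.")
  for (cl in item_cols) {
    v <- df[[cl]]
    bad <- which(!is.na(v) & (v != as.integer(v) | v < 0 | v > max_score))
    if (length(bad)) {
      abort(paste0("Invalid score in column `", cl, "`, row ", bad[1],
                   ": ", v[bad[1]], " (scores must be integers 0..",
                   max_score, ")."))
    }
    df[[cl]] <- as.integer(v)
  }
  n_missing <- sum(is.na(as.matrix(df[item_cols])))
  if (n_missing > 0) {
    inform(paste0("read_responses: ", n_missing, " missing item response(s)."))
  }
  df
}

#' Write a response table to CSV
#'
#' Drops the simulation-only `theta` column if present; missing scores are
#' written as `NA`.
#'
#' @param data Response tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(data, path) {
  data <- data[setdiff(names(data), "theta")]
  write.csv(as.data.frame(data), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write analysis reports to CSV
#'
#' `write_ctt_report()` writes the item-total table followed by a `Total`
#' summary row (columns `item`, `mean`, `sd`, `cv`, `alpha_if_deleted`);
#' `write_theta()`, `write_dif_report()` and `write_curves()` write their
#' tibbles as plain CSV.
#'
#' @param report A `ctt_report`, theta tibble, `dif_report`, or
#'   `curve_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ctt_report <- function(report, path) {
  stopifnot(inherits(report, "ctt_report"))
  items <- report$items
  items$item <- as.character(items$item)
  total_row <- tibble(item = "Total", mean = report$total$mean,
                      sd = report$total$sd, cv = report$total$cv,
                      alpha_if_deleted = report$total$alpha, flagged = FALSE)
  write.csv(as.data.frame(bind_rows(items, total_row)), path,
            row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_ctt_report
#' @export
write_theta <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_ctt_report
#' @export
write_dif_report <- function(report, path) {
  items <- if (inherits(report, "dif_report")) report$items else report
  write.csv(as.data.frame(items), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_ctt_report
#' @export
write_curves <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Flat key-value configuration files
#'
#' Serializes a flat named list as `key = value` lines (one per key;
#' vectors comma-separated) and reads it back with numeric/logical
#' auto-coercion. Used for pipeline and simulation settings.
#'
#' @param config Named list of scalars or atomic vectors.
#' @param path File path.
#' @return `read_config()` returns a named list; `write_config()` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    paste0(k, " = ", paste(config[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) abort(paste0("Malformed config line: `", ln, "`."))
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num
      else if (all(parts %in% c("TRUE", "FALSE"))) as.logical(parts)
      else parts
  }
  out
}
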