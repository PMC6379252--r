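#' Construct and validate a graded-response item bank
#'
#' An item bank is a tibble with one row per item holding the graded response
#' model (GRM) parameters on the logistic metric: a discrimination `a` and
#' ordered thresholds `b1 < b2 < ... < b{K-1}`, where K is the number of
#' response categories (4 for BDI-II-type items scored 0-3). Optional columns
#' `se_a`, `se_b1`, ... carry standard errors; `label` carries item names.
#'
#' @param items A data frame with columns `a`, `b1`..`b{K-1}`, and optionally
#'   `item`, `label`, and `se_*` columns.
#' @return A tibble of class `item_bank`, rows ordered by `item`.
#' @examples
#' item_bank(data.frame(a = c(1.5, 2), b1 = c(0, -1), b2 = c(1, 0.5), b3 = c(2, 1.5)))
#' @export
item_bank <- function(items) {
  items <- as_tibble(items)
  b_cols <- grep("^b[0-9]+$", names(items), value = TRUE)
  if (!"a" %in% names(items) || length(b_cols) == 0) {
    abort("An item bank needs an `a` column and at least one `b1` threshold column.")
  }
  b_cols <- paste0("b", seq_along(b_cols))
  if (!all(b_cols %in% names(items))) {
    abort("Threshold columns must be consecutive: b1, b2, ...")
  }
  if (!"item" %in% names(items)) items$item <- seq_len(nrow(items))
  if (!"label" %in% names(items)) items$label <- paste0("item", sprintf("%02d", items$item))
  if (nrow(items) == 0) abort("Item bank is empty.")
  if (any(!is.finite(items$a)) || any(items$a <= 0)) {
    abort("Discriminations `a` must be positive and finite.")
  }
  b <- as.matrix(items[b_cols])
  # NA thresholds are allowed only as a trailing block (items whose top
  # categories were collapsed during calibration); observed thresholds must
  # be strictly increasing
  bad <- apply(b, 1, function(x) {
    obs <- which(!is.na(x))
    length(obs) == 0 || any(is.na(x[seq_len(max(obs))])) ||
      any(!is.finite(x[obs])) || any(diff(x[obs]) <= 0)
  })
  if (any(bad)) {
    abort(paste0("Thresholds must be strictly increasing (NAs only trailing); ",
                 "offending item(s): ", paste(items$item[bad], collapse = ", ")))
  }
  out <- items[c("item", "label", "a", b_cols,
                 intersect(c("se_a", paste0("se_", b_cols)), names(items)))]
  out <- arrange(out, .data$item)
  class(out) <- c("item_bank", class(out))
  out
}

#' Number of response categories of an item bank
#' @param bank An [item_bank()].
#' @return Integer K (number of ordinal categories, thresholds + 1).
#' @export
n_categories <- function(bank) {
  length(grep("^b[0-9]+$", names(bank))) + 1L
}

# internal: parameters as a list(a = vector, b = J x (K-1) matrix)
bank_params <- function(bank) {
  b_cols <- grep("^b[0-9]+$", names(bank), value = TRUE)
  list(a = bank$a,
       b = matrix(as.matrix(bank[b_cols]), nrow = nrow(bank),
                  dimnames = list(bank$label, b_cols)))
}

#' Published BDI-II item bank
#'
#' GRM parameters (logistic metric, no scaling constant) for the 21 BDI-II
#' items as calibrated on a large Brazilian college-student sample, with
#' standard errors. Each item has 4 categories scored 0-3; thresholds are the
#' latent-severity locations where the cumulative endorsement probability
#' crosses one half.
#'
#' @return A 21-row [item_bank()].
#' @examples
#' bdi2_bank()
#' @export
bdi2_bank <- function() {
  bank <- tibble(
    item = 1:21,
    label = c("Sadness", "Pessimism", "Past failure", "Loss of pleasure",
              "Guilty feelings", "Punishment feelings", "Self-dislike",
              "Self-criticalness", "Suicidal thoughts", "Crying", "Agitation",
              "Loss of interest", "Indecisiveness", "Worthlessness",
              "Loss of energy", "Changes in sleep", "Irritability",
              "Changes in appetite", "Concentration difficulty",
              "Tiredness or fatigue", "Loss of interest in sex"),
    a    = c(2.38, 2.20, 2.04, 2.27, 1.72, 1.74, 2.86, 1.62, 2.12, 1.52, 1.59,
             2.73, 2.03, 3.31, 2.35, 1.58, 2.13, 1.40, 2.07, 2.24, 1.32),
    se_a = c(0.06, 0.05, 0.05, 0.05, 0.04, 0.05, 0.07, 0.03, 0.07, 0.04, 0.04,
             0.06, 0.04, 0.09, 0.05, 0.03, 0.04, 0.03, 0.04, 0.04, 0.04),
    b1   = c(1.10, 1.12, 1.32, 0.95, 0.75, 1.46, 1.24, 0.25, 1.89, 1.16, 0.83,
             0.89, 0.78, 1.31, 0.40, 0.03, 0.65, 0.48, 0.57, 0.32, 1.91),
    se_b1 = c(0.05, 0.05, 0.05, 0.05, 0.03, 0.05, 0.07, 0.03, 0.08, 0.03, 0.03,
              0.05, 0.04, 0.10, 0.04, 0.03, 0.04, 0.03, 0.03, 0.03, 0.04),
    b2   = c(2.75, 2.57, 1.98, 2.34, 2.96, 2.39, 1.60, 1.78, 3.22, 1.93, 2.90,
             2.26, 1.88, 1.80, 1.96, 1.69, 2.10, 2.31, 1.60, 1.75, 3.26),
    se_b2 = c(0.12, 0.09, 0.07, 0.08, 0.08, 0.07, 0.09, 0.04, 0.15, 0.04, 0.06,
              0.11, 0.06, 0.12, 0.07, 0.04, 0.07, 0.04, 0.05, 0.06, 0.07),
    b3   = c(3.13, 3.35, 3.41, 3.25, 3.78, 2.63, 2.54, 3.24, 3.60, 2.73, 3.19,
             2.87, 2.12, 2.72, 3.05, 3.04, 2.93, 3.28, 2.84, 2.52, 4.44),
    se_b3 = c(0.15, 0.16, 0.14, 0.15, 0.13, 0.07, 0.14, 0.08, 0.19, 0.06, 0.08,
              0.15, 0.06, 0.20, 0.13, 0.07, 0.11, 0.07, 0.09, 0.09, 0.12)
  )
  item_bank(bank)
}

#' Read / write an item bank as CSV
#'
#' The CSV schema is `item,label,a,se_a,b1,se_b1,b2,se_b2,b3,se_b3` (standard
#' errors optional on read).
#'
#' @param path File path.
#' @param bank An [item_bank()].
#' @return `read_item_bank()` returns an [item_bank()]; `write_item_bank()`
#'   returns `path` invisibly.
#' @export
read_item_bank <- function(path) {
  item_bank(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_item_bank
#' @export
write_item_bank <- function(bank, path) {
  write.csv(as.data.frame(bank), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
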