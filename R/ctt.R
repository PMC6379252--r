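# Classical-test-theory descriptives for ordinal scale data.
# Response tables carry item scores in columns named item01, item02, ...

# internal: item-score matrix from a response tibble
response_matrix <- function(data) {
  cols <- grep("^item[0-9]+$", names(data), value = TRUE)
  if (length(cols) == 0) abort("No item columns (item01, item02, ...) found.")
  m <- as.matrix(data[cols])
  storage.mode(m) <- "integer"
  m
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' alpha = J/(J-1) * (1 - sum(item variances) / variance(total)),
#' using sample variances with denominator N-1. Rows with any missing item
#' response are dropped first (listwise deletion, reported via a message).
#'
#' @param data Response tibble with `item*` columns.
#' @return Alpha (scalar).
#' @examples
#' cronbach_alpha(make_study_fixture(seed = 1, n_persons = 500))
#' @export
cronbach_alpha <- function(data) {
  m <- response_matrix(data)
  if (ncol(m) < 2) abort("Cronbach's alpha needs at least 2 items.")
  cc <- complete.cases(m)
  if (!all(cc)) {
    inform(paste0("cronbach_alpha: dropped ", sum(!cc),
                  " incomplete row(s) (listwise deletion)."))
    m <- m[cc, , drop = FALSE]
  }
  total_var <- var(rowSums(m))
  if (total_var == 0) abort("Total score has zero variance; alpha is undefined.")
  J <- ncol(m)
  J / (J - 1) * (1 - sum(apply(m, 2, var)) / total_var)
}

#' Item-level descriptive statistics
#'
#' Per-item mean, SD, Pearson's coefficient of variation (SD/M, reported as 0
#' and flagged when the item is constant, NA when the mean is not positive),
#' and Cronbach's alpha with the item deleted, plus the same summaries for
#' the total score. Mirrors the usual item-total analysis table.
#'
#' @param data Response tibble with `item*` columns.
#' @return A list of class `ctt_report`: `items` (tibble with `item`, `mean`,
#'   `sd`, `cv`, `alpha_if_deleted`, `flagged`), `total` (one-row tibble with
#'   `mean`, `sd`, `cv`, `alpha`), and `n_used`.
#' @export
item_descriptives <- function(data) {
  m <- response_matrix(data)
  cc <- complete.cases(m)
  m <- m[cc, , drop = FALSE]
  if (nrow(m) == 0) abort("No complete rows.")
  J <- ncol(m)
  item_mean <- unname(colMeans(m))
  item_sd <- unname(apply(m, 2, sd))
  item_cv <- dplyr::if_else(item_sd == 0, 0,
                            ifelse(item_mean > 0, item_sd / item_mean, NA_real_))
  total <- rowSums(m)
  alpha <- if (J > 1 && var(total) > 0) {
    J / (J - 1) * (1 - sum(item_sd^2) / var(total))
  } else NA_real_
  alpha_del <- if (J > 2) {
    vapply(seq_len(J), function(j) {
      mj <- m[, -j, drop = FALSE]
      tv <- var(rowSums(mj))
      if (tv == 0) return(NA_real_)
      (J - 1) / (J - 2) * (1 - sum(apply(mj, 2, var)) / tv)
    }, numeric(1))
  } else rep(NA_real_, J)
  items <- tibble(
    item = seq_len(J),
    mean = item_mean, sd = item_sd, cv = item_cv,
    alpha_if_deleted = alpha_del,
    flagged = item_sd == 0 | item_mean <= 0
  )
  structure(list(
    items = items,
    total = tibble(mean = mean(total), sd = sd(total),
                   cv = sd(total) / mean(total), alpha = alpha),
    n_used = nrow(m)
  ), class = "ctt_report")
}

#' @export
print.ctt_report <- function(x, ...) {
  cat("Item-total analysis (n =", x$n_used, ")\n")
  print(x$items, n = nrow(x$items))
  cat(sprintf("Total: M = %.2f, SD = %.2f, CV = %.2f, alpha = %.3f\n",
              x$total$mean, x$total$sd, x$total$cv, x$total$alpha))
  invisible(x)
}

#' Proportion above a screening cut-off
#'
#' Classifies each respondent as a probable case when the total score is
#' strictly greater than `cutoff` (so a cut-off of 13 flags totals of 14 or
#' more, the conventional banding for this scale), and tabulates the
#' proportion overall and within each binary group.
#'
#' @param data Response tibble with `item*` columns and optional `gender` /
#'   `age_group` columns.
#' @param cutoff Integer cut-off on the total score (default 13).
#' @param strict If `TRUE` (default) a case is total > cutoff; if `FALSE`,
#'   total >= cutoff.
#' @return A tibble with columns `group`, `level`, `n`, `prop`.
#' @export
classify_cutoff <- function(data, cutoff = 13, strict = TRUE) {
  m <- response_matrix(data)
  total <- rowSums(m)
  case <- if (strict) total > cutoff else total >= cutoff
  out <- tibble(group = "overall", level = "all",
                n = length(case), prop = mean(case, na.rm = TRUE))
  for (g in intersect(c("gender", "age_group"), names(data))) {
    by <- tapply(case, data[[g]], mean, na.rm = TRUE)
    nn <- tapply(case, data[[g]], length)
    out <- bind_rows(out, tibble(group = g, level = names(by),
                                 n = as.integer(nn), prop = as.numeric(by)))
  }
  out
}

#' Two-group comparison of total scores and case proportions
#'
#' Welch's two-sample t comparison of total scores between the two levels of
#' a grouping variable, and a two-proportion chi-square comparison of the
#' above-cut-off classification. These are unweighted descriptive
#' comparisons, not survey-design-adjusted tests.
#'
#' @param data Response tibble.
#' @param grouping `"gender"` or `"age_group"`.
#' @param cutoff Cut-off passed to [classify_cutoff()].
#' @return A one-row tibble: group levels, per-group means and SDs, mean
#'   difference, Welch t statistic and p-value, per-group case proportions,
#'   chi-square statistic and p-value.
#' @export
compare_groups <- function(data, grouping = c("gender", "age_group"),
                           cutoff = 13) {
  grouping <- match.arg(grouping)
  if (!grouping %in% names(data)) abort(paste0("Column `", grouping, "` not found."))
  lev <- if (grouping == "gender") c("M", "F") else c("younger", "older")
  g <- factor(data[[grouping]], levels = lev)
  if (any(table(g) < 2)) abort("Each group needs at least 2 members.")
  total <- rowSums(response_matrix(data))
  tt <- t.test(total[g == lev[1]], total[g == lev[2]])
  case <- total > cutoff
  x <- c(sum(case[g == lev[1]]), sum(case[g == lev[2]]))
  n <- c(sum(g == lev[1]), sum(g == lev[2]))
  pt <- suppressWarnings(prop.test(x, n))
  tibble(
    grouping = grouping, ref = lev[1], focal = lev[2],
    mean_ref = mean(total[g == lev[1]]), sd_ref = sd(total[g == lev[1]]),
    mean_focal = mean(total[g == lev[2]]), sd_focal = sd(total[g == lev[2]]),
    mean_diff = mean(total[g == lev[2]]) - mean(total[g == lev[1]]),
    t_statistic = unname(tt$statistic), t_p_value = tt$p.value,
    prop_ref = x[1] / n[1], prop_focal = x[2] / n[2],
    chisq_statistic = unname(pt$statistic), chisq_p_value = pt$p.value
  )
}
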