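# Iterative hybrid ordinal-logistic-regression DIF screening.
#
# Per item, four nested proportional-odds models of the response:
#   model 0: intercepts only
#   model 1: + latent-trait score theta
#   model 2: + group main effect        (uniform DIF signature)
#   model 3: + theta x group interaction (non-uniform DIF signature)
# An item is flagged when the pseudo-R2 gain from model 1 to model 3 exceeds
# a threshold (default 0.02); the 1v2 and 2v3 gains classify the DIF as
# uniform / non-uniform. Purification then recalibrates the flagged items
# with group-specific parameters (anchors shared), rescores theta, and
# repeats until the flagged set stabilizes.

# collapse categories with sparse group cells (< min_cell in either group)
# into an adjacent category; returns the recoded 0..K'-1 vector
collapse_sparse_categories <- function(y, group, min_cell = 5) {
  repeat {
    lev <- sort(unique(y[!is.na(y)]))
    if (length(lev) <= 2) return(y)
    tab <- table(factor(y, levels = lev), group)
    sparse <- lev[apply(tab, 1, min) < min_cell]
    if (length(sparse) == 0) return(y)
    k <- sparse[which.min(rowSums(tab)[match(sparse, lev)])]
    pos <- match(k, lev)
    target <- if (pos == 1) lev[2] else lev[pos - 1]
    y[!is.na(y) & y == k] <- target
  }
}

#' DIF screen for a single item
#'
#' Fits the four nested proportional-odds models of one item's responses on
#' a latent-trait score and a binary group, and applies the pseudo-R2 change
#' rules: overall DIF when the model 1 vs 3 gain exceeds `threshold`;
#' uniform when the 1 vs 2 gain exceeds it; non-uniform when the 2 vs 3 gain
#' exceeds it; `mixed` when both do. Categories with fewer than `min_cell`
#' observations in either group are collapsed into an adjacent category
#' before fitting. An alternative significance rule (`flag_rule = "lr"`)
#' flags on the 1 vs 3 likelihood-ratio test at `alpha / bonferroni_m`.
#'
#' @param y Integer item responses 0..K-1 (NA dropped together with the
#'   person's `theta` and `group`).
#' @param theta Latent-trait scores (typically from [eap_score()]).
#' @param group Binary group labels; first factor level = reference.
#' @param threshold Pseudo-R2 change threshold (default 0.02).
#' @param flavor Which pseudo-R2 drives the rule: `"mcfadden"` (default,
#'   monotone for nested ML fits), `"cox_snell"`, or `"nagelkerke"`.
#' @param min_cell Minimum group-by-category cell count (default 5).
#' @param flag_rule `"r2"` (default) or `"lr"`.
#' @param alpha,bonferroni_m Significance level and Bonferroni divisor for
#'   the `"lr"` rule.
#' @return One-row tibble: log-likelihoods `loglik0`..`loglik3`, LR
#'   statistics with df and p-values for 1v2/1v3/2v3, all three pseudo-R2
#'   deltas per comparison, the model-2 group coefficient `beta_group`,
#'   `flagged`, and `dif_type` (`none`/`uniform`/`nonuniform`/`mixed`).
#' @export
dif_single_item <- function(y, theta, group, threshold = 0.02,
                            flavor = c("mcfadden", "cox_snell", "nagelkerke"),
                            min_cell = 5, flag_rule = c("r2", "lr"),
                            alpha = 0.01, bonferroni_m = 1) {
  flavor <- match.arg(flavor)
  flag_rule <- match.arg(flag_rule)
  group <- factor(group)
  if (nlevels(group) != 2) abort("`group` must have exactly 2 levels.")
  keep <- !is.na(y) & !is.na(theta) & !is.na(group)
  y <- as.integer(y[keep]); theta <- theta[keep]; group <- group[keep]
  g <- as.numeric(group == levels(group)[2])
  y <- collapse_sparse_categories(y, group, min_cell)
  lev <- sort(unique(y))
  y <- match(y, lev) - 1L

  m0 <- fit_proportional_odds(y, NULL)
  m1 <- fit_proportional_odds(y, cbind(theta = theta))
  m2 <- fit_proportional_odds(y, cbind(theta = theta, group = g))
  m3 <- fit_proportional_odds(y, cbind(theta = theta, group = g,
                                       interaction = theta * g))
  lr <- function(big, small) 2 * (big$loglik - small$loglik)
  r2 <- function(m) pseudo_r2(m, m0)
  r12 <- r2(m2) - r2(m1); r13 <- r2(m3) - r2(m1); r23 <- r2(m3) - r2(m2)
  names(r12) <- paste0("r2_", names(r12), "_12")
  names(r13) <- paste0("r2_", names(r13), "_13")
  names(r23) <- paste0("r2_", names(r23), "_23")
  lr_12 <- lr(m2, m1); lr_13 <- lr(m3, m1); lr_23 <- lr(m3, m2)
  p_13 <- pchisq(lr_13, df = 2, lower.tail = FALSE)
  delta <- function(tab, pair) tab[[paste0("r2_", flavor, "_", pair)]]
  all13 <- delta(r13, "13"); all12 <- delta(r12, "12"); all23 <- delta(r23, "23")
  flagged <- if (flag_rule == "r2") {
    all13 > threshold
  } else {
    p_13 < alpha / bonferroni_m
  }
  dif_type <- if (!flagged) "none" else {
    uni <- all12 > threshold
    nonuni <- all23 > threshold
    dplyr::case_when(uni && nonuni ~ "mixed",
                     nonuni ~ "nonuniform",
                     uni ~ "uniform",
                     TRUE ~ "uniform")  # flagged overall, constant signature
  }
  dplyr::bind_cols(
    tibble(loglik0 = m0$loglik, loglik1 = m1$loglik, loglik2 = m2$loglik,
           loglik3 = m3$loglik,
           lr_12 = lr_12, df_12 = 1, p_12 = pchisq(lr_12, 1, lower.tail = FALSE),
           lr_13 = lr_13, df_13 = 2, p_13 = p_13,
           lr_23 = lr_23, df_23 = 1, p_23 = pchisq(lr_23, 1, lower.tail = FALSE)),
    r12, r13, r23,
    tibble(beta_group = if (length(m2$beta) >= 2) m2$beta[2] else NA_real_,
           n_categories_used = length(lev),
           flagged = flagged, dif_type = dif_type)
  )
}

# build a per-group item_bank tibble from an internal parameter list
params_to_bank <- function(params, labels, Kmax) {
  rows <- lapply(seq_along(params), function(j) {
    b <- params[[j]]$b
    c(a = params[[j]]$a,
      setNames(c(b, rep(NA_real_, Kmax - 1 - length(b))),
               paste0("b", seq_len(Kmax - 1))))
  })
  tab <- as_tibble(do.call(rbind, rows))
  tab$item <- seq_along(params)
  tab$label <- labels
  item_bank(tab)
}

#' Iterative hybrid OLR DIF analysis
#'
#' Runs the full procedure on a response table: (1) calibrate the graded
#' response model on all persons pooled and score theta by EAP; (2) screen
#' every item with [dif_single_item()]; (3) purify: recalibrate giving
#' flagged items group-specific parameters while anchor items stay shared
#' (which fixes the latent metric), rescore theta with each person's
#' group-specific bank, and rescreen; repeat until the flagged set is
#' unchanged or `max_purification_iters` is reached.
#'
#' @param data Response tibble with `item*` columns and the grouping column.
#' @param grouping `"gender"` or `"age_group"` (reference level = men /
#'   younger, focal = women / older).
#' @param bank Optional pre-calibrated [item_bank()]; when supplied the
#'   initial pooled calibration is skipped and theta is scored from it.
#' @param threshold,flavor,min_cell,flag_rule,alpha Flag-rule settings, as in
#'   [dif_single_item()].
#' @param anchor_mode `"group_specific"` (default): flagged items get
#'   group-specific parameters in the purification refit; `"anchors_only"`:
#'   theta is rescored from the anchor items alone.
#' @param max_purification_iters Maximum purification rounds (default 10).
#' @param grid Quadrature grid for calibration and scoring.
#' @param grm_tol,grm_max_iter EM controls for the internal calibrations.
#' @return An object of class `dif_report`: `items` (one row per item from
#'   [dif_single_item()] plus `item`/`label`), `anchor_set`, `flagged_set`,
#'   `n_purification_iters`, `converged`, `trace` (list of flagged sets),
#'   `theta` (final scores tibble), `banks` (per-group banks from the final
#'   refit, when DIF was found), `grouping`, and the settings used.
#' @examples
#' dat <- make_study_fixture(seed = 5, n_persons = 600)
#' rep <- dif_analysis(dat, "gender", bank = bdi2_bank(), grid = theta_grid(31))
#' glance(rep)
#' @export
dif_analysis <- function(data, grouping = c("gender", "age_group"),
                         bank = NULL, threshold = 0.02,
                         flavor = c("mcfadden", "cox_snell", "nagelkerke"),
                         min_cell = 5, flag_rule = c("r2", "lr"), alpha = 0.01,
                         anchor_mode = c("group_specific", "anchors_only"),
                         max_purification_iters = 10,
                         grid = theta_grid(), grm_tol = 1e-4,
                         grm_max_iter = 500) {
  grouping <- match.arg(grouping)
  flavor <- match.arg(flavor)
  flag_rule <- match.arg(flag_rule)
  anchor_mode <- match.arg(anchor_mode)
  if (!grouping %in% names(data)) abort(paste0("Column `", grouping, "` not found."))
  lev <- if (grouping == "gender") c("M", "F") else c("younger", "older")
  group <- factor(data[[grouping]], levels = lev)
  if (any(is.na(group))) abort("Group labels outside the expected levels.")
  Y <- response_matrix(data)
  J <- ncol(Y)
  labels <- colnames(Y)

  prep <- prepare_scores(Y, collapse = TRUE)
  if (is.null(bank)) {
    fit0 <- fit_grm(data, grid = grid, max_iter = grm_max_iter, tol = grm_tol,
                    se = FALSE)
    bank <- fit0$bank
  }
  theta <- eap_score(data, bank, grid)$theta

  screen_all <- function(theta) {
    purrr::map_dfr(seq_len(J), function(j) {
      dplyr::bind_cols(tibble(item = j, label = labels[j]),
                       dif_single_item(Y[, j], theta, group,
                                       threshold = threshold, flavor = flavor,
                                       min_cell = min_cell,
                                       flag_rule = flag_rule, alpha = alpha,
                                       bonferroni_m = J))
    })
  }

  items <- screen_all(theta)
  flagged <- which(items$flagged)
  trace <- list(flagged)
  converged <- FALSE
  banks <- NULL
  iter <- 0
  while (iter < max_purification_iters) {
    iter <- iter + 1
    if (length(flagged) == 0) { converged <- TRUE; break }
    if (length(flagged) == J) {
      abort("All items flagged for DIF; no anchor items remain.")
    }
    if (anchor_mode == "group_specific") {
      em <- grm_em(prep$Y, prep$K_item, grid, group = group, free = flagged,
                   max_iter = grm_max_iter, tol = grm_tol)
      theta_new <- numeric(nrow(Y))
      for (g in levels(group)) {
        ig <- which(group == g)
        theta_new[ig] <- eap_from_params(Y[ig, , drop = FALSE],
                                         em$params[[g]], grid)$theta
      }
      Kmax <- max(prep$K_item)
      banks <- lapply(em$params, params_to_bank, labels = labels, Kmax = Kmax)
    } else {
      anchors <- setdiff(seq_len(J), flagged)
      sub <- data[, c(setdiff(names(data), labels), labels[anchors])]
      fit_a <- fit_grm(sub, grid = grid, max_iter = grm_max_iter,
                       tol = grm_tol, se = FALSE)
      theta_new <- eap_score(sub, fit_a$bank, grid)$theta
    }
    theta <- theta_new
    items <- screen_all(theta)
    new_flagged <- which(items$flagged)
    trace <- c(trace, list(new_flagged))
    if (identical(new_flagged, flagged)) { converged <- TRUE; flagged <- new_flagged; break }
    flagged <- new_flagged
  }
  if (!converged) {
    warn("Purification did not stabilize within max_purification_iters.")
  }
  structure(list(
    items = items,
    flagged_set = flagged,
    anchor_set = setdiff(seq_len(J), flagged),
    n_purification_iters = length(trace) - 1L,
    converged = converged,
    trace = trace,
    theta = tibble(person_id = data$person_id %||% seq_len(nrow(Y)),
                   theta = theta),
    banks = banks,
    grouping = grouping,
    settings = list(threshold = threshold, flavor = flavor,
                    min_cell = min_cell, flag_rule = flag_rule, alpha = alpha,
                    anchor_mode = anchor_mode)
  ), class = "dif_report")
}

#' @export
print.dif_report <- function(x, ...) {
  cat(sprintf("Hybrid OLR DIF analysis by %s (%s rule, %s, threshold %.3g)\n",
              x$grouping, x$settings$flag_rule, x$settings$flavor,
              x$settings$threshold))
  cat(sprintf("%d purification iteration(s); %s\n", x$n_purification_iters,
              if (x$converged) "flag set stable" else "NOT stable"))
  fl <- x$items[x$items$flagged, c("item", "label", "dif_type")]
  if (nrow(fl) == 0) cat("No items flagged.\n") else print(fl)
  invisible(x)
}

#' Tidy a DIF report
#' @param x A `dif_report`.
#' @param ... Unused.
#' @return `tidy()`: the per-item screening tibble. `glance()`: a one-row
#'   summary.
#' @export
tidy.dif_report <- function(x, ...) x$items

#' @rdname tidy.dif_report
#' @export
glance.dif_report <- function(x, ...) {
  tibble(grouping = x$grouping, n_items = nrow(x$items),
         n_flagged = length(x$flagged_set),
         n_anchors = length(x$anchor_set),
         n_purification_iters = x$n_purification_iters,
         converged = x$converged)
}
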