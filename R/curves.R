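# Item and test characteristic curves as long-format tables, plus ggplot2
# displays. Curve tables use the schema kind, group, item, theta,
# value_label, value.

default_curve_grid <- function() seq(-4, 4, length.out = 201)

new_curve_table <- function(x) {
  class(x) <- c("curve_table", class(x))
  x
}

#' Item characteristic curves
#'
#' For each requested item: the expected item score E\[X | theta\] and the K
#' category-probability curves over a theta grid.
#'
#' @param bank An [item_bank()].
#' @param items Item indices (default all).
#' @param theta Theta grid (default 201 points on \[-4, 4\]).
#' @param group Optional group label attached to the rows.
#' @return A `curve_table` tibble: `kind` (`ICC_expected` /
#'   `ICC_categories`), `group`, `item`, `theta`, `value_label`, `value`.
#' @examples
#' icc(bdi2_bank(), items = 10)
#' @export
icc <- function(bank, items = bank$item, theta = default_curve_grid(),
                group = NA_character_) {
  stopifnot(all(items %in% bank$item))
  pars <- bank_params(bank)
  K <- n_categories(bank)
  rows <- purrr::map_dfr(items, function(it) {
    j <- match(it, bank$item)
    b <- pars$b[j, ]; b <- b[!is.na(b)]
    P <- grm_category_prob(pars$a[j], b, theta)
    expected <- as.numeric(P %*% (seq_len(ncol(P)) - 1))
    bind_rows(
      tibble(kind = "ICC_expected", group = group, item = it, theta = theta,
             value_label = "expected", value = expected),
      purrr::map_dfr(seq_len(ncol(P)), function(k) {
        tibble(kind = "ICC_categories", group = group, item = it,
               theta = theta, value_label = paste0("p", k - 1),
               value = P[, k])
      })
    )
  })
  new_curve_table(rows)
}

#' Test characteristic curve
#'
#' Expected total score as a function of theta: the sum of the item expected
#' scores. Strictly increasing, from 0 up to (K-1) * J.
#'
#' @inheritParams icc
#' @return A `curve_table` tibble with `kind = "TCC"` and
#'   `value_label = "expected_total"`.
#' @examples
#' tcc(bdi2_bank())
#' @export
tcc <- function(bank, theta = default_curve_grid(), group = NA_character_) {
  pars <- bank_params(bank)
  per_item <- vapply(seq_len(nrow(bank)), function(j) {
    b <- pars$b[j, ]; b <- b[!is.na(b)]
    P <- grm_category_prob(pars$a[j], b, theta)
    as.numeric(P %*% (seq_len(ncol(P)) - 1))
  }, numeric(length(theta)))
  total <- rowSums(matrix(per_item, nrow = length(theta)))
  new_curve_table(tibble(kind = "TCC", group = group, item = NA_integer_,
                         theta = theta, value_label = "expected_total",
                         value = total))
}

#' Impact of DIF items on the expected total score
#'
#' Compares two group-specific banks that share their anchor (non-DIF)
#' items: the difference of the group test characteristic curves computed
#' over all items, and over the DIF items alone. Because the anchors are
#' identical, the two differences coincide; the summary reports the largest
#' absolute expected-total-score difference and where it occurs, in raw
#' score points.
#'
#' @param bank_ref,bank_focal Group-specific [item_bank()]s with identical
#'   parameters on every item not listed in `dif_items`.
#' @param dif_items Integer indices of the DIF items.
#' @param theta Theta grid.
#' @return A list: `curves` (`curve_table` with kinds `TCC_diff_all` and
#'   `TCC_diff_dif_items`, value = focal minus reference expected score) and
#'   `summary` (tibble with `scope`, `max_abs_diff`, `theta_at_max`).
#' @export
dif_impact <- function(bank_ref, bank_focal, dif_items,
                       theta = default_curve_grid()) {
  if (nrow(bank_ref) != nrow(bank_focal)) abort("Banks differ in item count.")
  anchors <- setdiff(bank_ref$item, dif_items)
  num_cols <- grep("^(a|b[0-9]+)$", names(bank_ref), value = TRUE)
  ar <- as.matrix(bank_ref[match(anchors, bank_ref$item), num_cols])
  af <- as.matrix(bank_focal[match(anchors, bank_focal$item), num_cols])
  if (!isTRUE(all.equal(ar, af, tolerance = 1e-8))) {
    abort("Anchor items differ between the two banks; they must be shared.")
  }
  d_all <- tcc(bank_focal, theta)$value - tcc(bank_ref, theta)$value
  sub_ref <- bank_ref[match(dif_items, bank_ref$item), ]
  sub_focal <- bank_focal[match(dif_items, bank_focal$item), ]
  d_dif <- if (length(dif_items)) {
    tcc(item_bank(sub_focal), theta)$value - tcc(item_bank(sub_ref), theta)$value
  } else rep(0, length(theta))
  curves <- new_curve_table(bind_rows(
    tibble(kind = "TCC_diff_all", group = NA_character_, item = NA_integer_,
           theta = theta, value_label = "delta_expected_total", value = d_all),
    tibble(kind = "TCC_diff_dif_items", group = NA_character_,
           item = NA_integer_, theta = theta,
           value_label = "delta_expected_total", value = d_dif)
  ))
  summary <- tibble(
    scope = c("all_items", "dif_items"),
    max_abs_diff = c(max(abs(d_all)), max(abs(d_dif))),
    theta_at_max = c(theta[which.max(abs(d_all))], theta[which.max(abs(d_dif))])
  )
  list(curves = curves, summary = summary)
}

#' Plot a curve table
#'
#' @param object A `curve_table` from [icc()], [tcc()], or [dif_impact()].
#' @param ... Unused.
#' @return A ggplot object; category curves are coloured by category, items
#'   are facetted, and groups are distinguished by linetype when present.
#' @export
autoplot.curve_table <- function(object, ...) {
  df <- as_tibble(object)
  has_group <- any(!is.na(df$group))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$value,
                                        colour = .data$value_label)) +
    ggplot2::geom_line(
      if (has_group) ggplot2::aes(linetype = .data$group) else NULL
    ) +
    ggplot2::labs(x = expression(theta), y = "value", colour = NULL,
                  linetype = NULL) +
    ggplot2::theme_minimal()
  if (length(unique(df$item[!is.na(df$item)])) > 1) {
    p <- p + ggplot2::facet_wrap(~item, labeller = ggplot2::label_both)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Convenience ICC / TCC plots
#'
#' @param bank An [item_bank()] (for `plot_icc` / `plot_tcc`).
#' @param items Items to display.
#' @param theta Theta grid.
#' @return A ggplot object.
#' @export
plot_icc <- function(bank, items = bank$item, theta = default_curve_grid()) {
  autoplot(icc(bank, items = items, theta = theta))
}

#' @rdname plot_icc
#' @export
plot_tcc <- function(bank, theta = default_curve_grid()) {
  autoplot(tcc(bank, theta = theta))
}
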