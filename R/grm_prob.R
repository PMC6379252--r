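#' Quadrature grid over the latent trait
#'
#' Fixed-node Gaussian quadrature for integrals against the standard-normal
#' latent-trait density: equally spaced nodes with normal-density weights,
#' renormalized to sum to one.
#'
#' @param n_nodes Number of nodes (default 61).
#' @param range Node range in theta units (default `c(-5, 5)`).
#' @return A tibble with columns `theta` and `weight`.
#' @examples
#' theta_grid(21)
#' @export
theta_grid <- function(n_nodes = 61, range = c(-5, 5)) {
  if (n_nodes < 11) abort("Use at least 11 quadrature nodes.")
  theta <- seq(range[1], range[2], length.out = n_nodes)
  w <- dnorm(theta)
  tibble(theta = theta, weight = w / sum(w))
}

#' GRM boundary (cumulative) probability
#'
#' P*(X >= k | theta) = logistic(a * (theta - b_k)) for k = 1..K-1, with the
#' conventions P*(X >= 0) = 1 and P*(X >= K) = 0.
#'
#' @param a Discrimination (positive).
#' @param b Numeric vector of ordered thresholds for one item.
#' @param k Boundary index, 1..K-1.
#' @param theta Latent-trait value(s).
#' @return Probability vector, one element per `theta`.
#' @examples
#' grm_boundary_prob(1.58, 0.03, k = 1, theta = 0.03) # 0.5 at its threshold
#' @export
grm_boundary_prob <- function(a, b, k, theta) {
  if (k < 1 || k > length(b)) {
    abort(paste0("Boundary index k must be in 1..", length(b), "."))
  }
  plogis(a * (theta - b[k]))
}

#' GRM category probabilities
#'
#' Probability of each response category 0..K-1 at given trait values, as
#' adjacent differences of boundary probabilities.
#'
#' @inheritParams grm_boundary_prob
#' @return A `length(theta)` x K matrix; rows sum to 1.
#' @examples
#' grm_category_prob(1, c(0, 1, 2), theta = 0)
#' @export
grm_category_prob <- function(a, b, theta) {
  cum <- cbind(1, plogis(outer(theta, b, function(th, bb) a * (th - bb))), 0)
  p <- cum[, -ncol(cum), drop = FALSE] - cum[, -1, drop = FALSE]
  colnames(p) <- paste0("p", seq_len(ncol(p)) - 1L)
  p
}

# internal: list of node-by-category probability matrices, one per item;
# items with trailing NA thresholds (collapsed top categories) get zero
# probability columns for the unused scores
bank_prob_list <- function(bank, nodes) {
  pars <- bank_params(bank)
  K <- ncol(pars$b) + 1L
  lapply(seq_along(pars$a), function(j) {
    b <- pars$b[j, ]
    b <- b[!is.na(b)]
    p <- grm_category_prob(pars$a[j], b, nodes)
    if (ncol(p) < K) {
      p <- cbind(p, matrix(0, nrow(p), K - ncol(p)))
      colnames(p) <- paste0("p", 0:(K - 1))
    }
    p
  })
}

#' Model-implied marginal category proportions
#'
#' Integrates each item's category probabilities over the standard-normal
#' latent trait by quadrature, giving the population response-proportion
#' table the model implies.
#'
#' @param bank An [item_bank()].
#' @param grid A [theta_grid()] tibble.
#' @return A tibble with columns `item`, `label`, `category` (score 0..K-1),
#'   and `prob`; probabilities sum to 1 within item.
#' @examples
#' implied_marginals(bdi2_bank()) |> dplyr::filter(item == 1)
#' @export
implied_marginals <- function(bank, grid = theta_grid()) {
  probs <- bank_prob_list(bank, grid$theta)
  K <- n_categories(bank)
  purrr::map2_dfr(probs, seq_len(nrow(bank)), function(p, j) {
    tibble(item = bank$item[j], label = bank$label[j],
           category = 0:(K - 1), prob = as.numeric(crossprod(p, grid$weight)))
  })
}

#' Model-implied item and total-score moments
#'
#' Expected item means, the expected total score, and the total-score
#' variance decomposed under local independence as
#' Var(E\[T|theta\]) + E(Var\[T|theta\]), plus the model-implied Cronbach's
#' alpha of the sum score.
#'
#' @inheritParams implied_marginals
#' @return A list with tibble `items` (columns `item`, `label`, `mean`, `sd`)
#'   and scalars `total_mean`, `total_sd`, `alpha`.
#' @examples
#' implied_moments(bdi2_bank())$total_mean
#' @export
implied_moments <- function(bank, grid = theta_grid()) {
  probs <- bank_prob_list(bank, grid$theta)
  K <- n_categories(bank)
  k <- 0:(K - 1)
  cond_mean <- vapply(probs, function(p) as.numeric(p %*% k), numeric(nrow(grid)))
  cond_m2 <- vapply(probs, function(p) as.numeric(p %*% k^2), numeric(nrow(grid)))
  item_mean <- as.numeric(crossprod(cond_mean, grid$weight))
  item_var <- as.numeric(crossprod(cond_m2, grid$weight)) - item_mean^2
  cond_total <- rowSums(cond_mean)
  total_mean <- sum(item_mean)
  var_between <- sum(grid$weight * (cond_total - total_mean)^2)
  var_within <- sum(crossprod(cond_m2 - cond_mean^2, grid$weight))
  total_var <- var_between + var_within
  J <- nrow(bank)
  alpha <- if (J > 1) J / (J - 1) * (1 - sum(item_var) / total_var) else NA_real_
  list(items = tibble(item = bank$item, label = bank$label,
                      mean = item_mean, sd = sqrt(item_var)),
       total_mean = total_mean, total_sd = sqrt(total_var), alpha = alpha)
}
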