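# Shared fixtures: small banks and response tables built in code.

small_bank <- function(n_items = 5) {
  item_bank(bdi2_bank()[seq_len(n_items), ])
}

# direct (non-package) marginal log-likelihood for a 2-item K=3 toy dataset,
# integrating over an explicit quadrature grid; independent of the EM path
toy_marginal_loglik <- function(Y, a, b, nodes, weights) {
  # a: length-2; b: list of two length-2 ordered threshold vectors
  ll <- 0
  for (i in seq_len(nrow(Y))) {
    lik <- weights
    for (j in 1:2) {
      cum <- cbind(1, plogis(a[j] * outer(nodes, b[[j]], `-`)), 0)
      p <- cum[, 1 + Y[i, j]] - cum[, 2 + Y[i, j]]
      lik <- lik * p
    }
    ll <- ll + log(sum(lik))
  }
  ll
}

# minimal response tibble from a raw score matrix
as_response <- function(m, gender = NULL, age = NULL) {
  colnames(m) <- paste0("item", sprintf("%02d", seq_len(ncol(m))))
  out <- tibble::as_tibble(m)
  out <- dplyr::bind_cols(tibble::tibble(person_id = seq_len(nrow(m))), out)
  if (!is.null(gender)) out$gender <- gender
  if (!is.null(age)) out$age_group <- age
  out
}
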