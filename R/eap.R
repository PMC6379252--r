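# EAP (expected a posteriori) trait scoring under a calibrated bank.

# internal: EAP over a quadrature grid given per-item parameter lists
eap_from_params <- function(Y, params, grid) {
  N <- nrow(Y); J <- ncol(Y)
  nodes <- grid$theta
  logw <- log(grid$weight)
  LL <- matrix(0, N, length(nodes))
  for (j in seq_len(J)) {
    P <- log(pmax(grm_category_prob(params[[j]]$a, params[[j]]$b, nodes), 1e-300))
    yj <- Y[, j]
    obs <- !is.na(yj) & yj <= (ncol(P) - 1L)
    if (any(obs)) LL[obs, ] <- LL[obs, ] + t(P[, yj[obs] + 1L, drop = FALSE])
  }
  LL <- sweep(LL, 2, logw, `+`)
  mx <- apply(LL, 1, max)
  E <- exp(LL - mx)
  rs <- rowSums(E)
  post <- E / rs
  theta <- as.numeric(post %*% nodes)
  psd <- sqrt(pmax(as.numeric(post %*% nodes^2) - theta^2, 0))
  list(theta = theta, psd = psd)
}

#' Score respondents by expected a posteriori estimation
#'
#' Posterior mean and SD of the latent trait for each response pattern,
#' integrating the pattern likelihood against the standard-normal prior over
#' the quadrature grid. Missing item responses are skipped in the
#' likelihood; a person with no responses at all receives the prior mean 0
#' with prior SD 1 and is flagged.
#'
#' @param data Response tibble with `item*` columns.
#' @param bank Calibrated [item_bank()] whose item count matches the data.
#' @param grid A [theta_grid()].
#' @return A tibble with columns `person_id` (if present in `data`), `theta`,
#'   `psd`, `n_answered`, and `all_missing`.
#' @examples
#' dat <- simulate_responses(simulation_spec(100, bdi2_bank()), seed = 3)
#' eap_score(dat, bdi2_bank())
#' @export
eap_score <- function(data, bank, grid = theta_grid()) {
  Y <- response_matrix(data)
  if (ncol(Y) != nrow(bank)) {
    abort(paste0("Bank has ", nrow(bank), " items but data has ", ncol(Y),
                 " item columns."))
  }
  pars <- bank_params(bank)
  plist <- lapply(seq_len(nrow(bank)), function(j) {
    b <- pars$b[j, ]; list(a = pars$a[j], b = b[!is.na(b)])
  })
  sc <- eap_from_params(Y, plist, grid)
  n_ans <- rowSums(!is.na(Y))
  all_miss <- n_ans == 0
  theta <- ifelse(all_miss, 0, sc$theta)
  psd <- ifelse(all_miss, 1, sc$psd)
  out <- tibble(theta = theta, psd = psd, n_answered = n_ans,
                all_missing = all_miss)
  if ("person_id" %in% names(data)) {
    out <- dplyr::bind_cols(tibble(person_id = data$person_id), out)
  }
  out
}
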