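# Proportional-odds (cumulative-logit) maximum likelihood, fitted by
# Newton-Raphson with step-halving. Model: logit P(Y <= k) = zeta_k - x'beta,
# k = 1..K-1, with ordered cutpoints zeta.

olr_loglik <- function(par, y, X, K) {
  zeta <- par[seq_len(K - 1)]
  if (is.unsorted(zeta, strictly = TRUE)) return(-Inf)
  beta <- par[-seq_len(K - 1)]
  eta <- if (length(beta)) as.numeric(X %*% beta) else 0
  upper <- c(zeta, Inf)[y + 2L - 1L]   # zeta_{y+1}
  lower <- c(-Inf, zeta)[y + 1L]       # zeta_y
  p <- plogis(upper - eta) - plogis(lower - eta)
  if (any(p <= 0)) return(-Inf)
  sum(log(p))
}

# analytic gradient; y is 0-based
olr_grad <- function(par, y, X, K) {
  zeta <- par[seq_len(K - 1)]
  beta <- par[-seq_len(K - 1)]
  n <- length(y)
  eta <- if (length(beta)) as.numeric(X %*% beta) else rep(0, n)
  ui <- y + 1L          # index of upper cutpoint (K means +Inf)
  li <- y               # index of lower cutpoint (0 means -Inf)
  Fu <- ifelse(ui > K - 1, 1, plogis(zeta[pmin(ui, K - 1)] - eta))
  Fl <- ifelse(li < 1, 0, plogis(zeta[pmax(li, 1)] - eta))
  fu <- Fu * (1 - Fu)
  fl <- Fl * (1 - Fl)
  P <- pmax(Fu - Fl, 1e-300)
  gz <- numeric(K - 1)
  for (k in seq_len(K - 1)) {
    gz[k] <- sum((fu / P)[ui == k]) - sum((fl / P)[li == k])
  }
  gb <- if (length(beta)) as.numeric(crossprod(X, -(fu - fl) / P)) else numeric(0)
  c(gz, gb)
}

#' Fit a proportional-odds ordinal regression
#'
#' Cumulative-logit proportional-odds model fitted by full maximum
#' likelihood: Newton-Raphson on the (cutpoints, slopes) vector with a
#' numerically differentiated Hessian of the analytic score and step-halving
#' whenever a step fails to increase the log-likelihood. Deterministic given
#' the data. Used as the working model of the DIF engine; the intercept-only
#' fit reproduces the observed cumulative logits exactly.
#'
#' @param y Integer ordinal responses 0..K-1 (at least 2 observed levels).
#' @param X Numeric predictor matrix (or NULL / zero columns for the null
#'   model).
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @return A list of class `olr_fit`: `zeta` (ordered cutpoints), `beta`,
#'   `loglik`, `n_params`, `n`, `df`, `converged`, `iterations`.
#' @examples
#' y <- c(rep(0, 10), rep(1, 20), rep(2, 30), rep(3, 40))
#' fit_proportional_odds(y, NULL)$zeta  # observed cumulative logits
#' @export
fit_proportional_odds <- function(y, X = NULL, max_iter = 100, tol = 1e-10) {
  y <- as.integer(y)
  lev <- sort(unique(y))
  if (length(lev) < 2) abort("Ordinal response has fewer than 2 observed levels.")
  if (!identical(lev, seq(0L, max(lev)))) {
    # recode to contiguous 0..K-1 (caller may have collapsed categories)
    y <- match(y, lev) - 1L
  }
  K <- length(unique(y))
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (ncol(X) == 0) X <- NULL
  }
  if (!is.null(X)) {
    if (nrow(X) != length(y)) abort("X and y lengths differ.")
    if (any(!is.finite(X))) abort("Predictors must be finite.")
  }
  n <- length(y)
  np <- (K - 1) + if (is.null(X)) 0 else ncol(X)
  # start: empirical cumulative logits, zero slopes
  cum <- cumsum(tabulate(y + 1L, K))[seq_len(K - 1)] / n
  par <- c(qlogis(pmin(pmax(cum, 1e-10), 1 - 1e-10)),
           rep(0, np - (K - 1)))
  ll <- olr_loglik(par, y, X, K)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    g <- olr_grad(par, y, X, K)
    # central-difference Hessian of the analytic score
    h <- 1e-5
    H <- matrix(0, np, np)
    for (i in seq_len(np)) {
      e <- numeric(np); e[i] <- h
      H[, i] <- (olr_grad(par + e, y, X, K) - olr_grad(par - e, y, X, K)) / (2 * h)
    }
    H <- (H + t(H)) / 2
    step <- tryCatch(solve(H, g), error = function(e) g / max(1, sqrt(sum(g^2))))
    # Newton direction for a maximum: par - H^{-1} g (H is negative definite)
    cand <- par - step
    ll_new <- olr_loglik(cand, y, X, K)
    halvings <- 0
    while ((!is.finite(ll_new) || ll_new < ll) && halvings < 30) {
      step <- step / 2
      cand <- par - step
      ll_new <- olr_loglik(cand, y, X, K)
      halvings <- halvings + 1
    }
    if (!is.finite(ll_new) || ll_new < ll) {
      break  # no ascent possible; treat current point as the optimum
    }
    delta <- ll_new - ll
    par <- cand
    ll <- ll_new
    if (delta < tol && max(abs(g)) < 1e-5) { converged <- TRUE; break }
  }
  if (!converged && max(abs(olr_grad(par, y, X, K))) > 1e-3) {
    warn("Proportional-odds fit did not fully converge (possible separation).")
  }
  structure(list(zeta = par[seq_len(K - 1)], beta = par[-seq_len(K - 1)],
                 loglik = ll, n_params = np, n = n, df = np,
                 converged = converged, iterations = it),
            class = "olr_fit")
}

#' Pseudo-R-squared statistics for nested ordinal fits
#'
#' McFadden: 1 - ll/ll0. Cox-Snell: 1 - exp(2 (ll0 - ll) / n). Nagelkerke:
#' Cox-Snell rescaled by its maximum 1 - exp(2 ll0 / n). The null fit must be
#' nested in `fit` and estimated on the same data.
#'
#' @param fit,null_fit `olr_fit` objects on the same data.
#' @param n Sample size (defaults to `fit$n`).
#' @return A one-row tibble with columns `mcfadden`, `cox_snell`,
#'   `nagelkerke`.
#' @examples
#' y <- rbinom(200, 3, 0.4); x <- rnorm(200)
#' f0 <- fit_proportional_odds(y, NULL)
#' f1 <- fit_proportional_odds(y, cbind(x))
#' pseudo_r2(f1, f0)
#' @export
pseudo_r2 <- function(fit, null_fit, n = fit$n) {
  ll <- fit$loglik; ll0 <- null_fit$loglik
  cs <- 1 - exp(2 * (ll0 - ll) / n)
  denom <- 1 - exp(2 * ll0 / n)
  if (ll0 == 0) {
    warn("Null log-likelihood is 0; Nagelkerke R2 undefined.")
    nk <- NA_real_
  } else nk <- cs / denom
  tibble(mcfadden = 1 - ll / ll0, cox_snell = cs, nagelkerke = nk)
}
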