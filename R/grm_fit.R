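# Marginal maximum likelihood calibration of the graded response model by EM.
#
# The E-step evaluates each person's posterior over a fixed quadrature grid
# under a standard-normal latent-trait prior; the M-step maximizes each
# item's expected complete-data log-likelihood by quasi-Newton ascent in a
# reparameterization (log a; b1; log threshold increments) that keeps a > 0
# and the thresholds strictly ordered by construction.

# ---- expected complete-data objective for one item -------------------------

# pars: c(log a, b1, log(b2-b1), ...); R: Q x K expected count table
item_objective <- function(pars, R, nodes) {
  a <- exp(pars[1])
  b <- cumsum(c(pars[2], exp(pars[-(1:2)])))
  P <- grm_category_prob(a, b, nodes)
  -sum(R * log(pmax(P, 1e-300)))
}

item_gradient <- function(pars, R, nodes) {
  a <- exp(pars[1])
  b <- cumsum(c(pars[2], exp(pars[-(1:2)])))
  Km1 <- length(b)
  cum <- plogis(outer(nodes, b, function(th, bb) a * (th - bb)))   # Q x (K-1)
  s <- cum * (1 - cum)
  P <- cbind(1, cum, 0)
  P <- pmax(P[, -ncol(P), drop = FALSE] - P[, -1, drop = FALSE], 1e-300)
  W <- R / P                                                       # Q x K
  # d(-f)/da and d(-f)/db_m on the natural scale
  g_a <- 0
  g_b <- numeric(Km1)
  for (m in seq_len(Km1)) {
    # boundary m enters P_{m-1} with +, P_m with -
    dstar_da <- s[, m] * (nodes - b[m])
    g_a <- g_a + sum((W[, m] - W[, m + 1]) * dstar_da)
    g_b[m] <- sum((W[, m] - W[, m + 1]) * (-a * s[, m]))
  }
  # chain rule to (log a, b1, log increments); g_a/g_b accumulated above are
  # derivatives of the negated objective already
  gt <- numeric(length(pars))
  gt[1] <- a * g_a
  gt[2] <- sum(g_b)
  if (Km1 > 1) {
    for (m in 2:Km1) gt[m + 1] <- exp(pars[m + 1]) * sum(g_b[m:Km1])
  }
  gt
}

item_to_trans <- function(a, b) c(log(a), b[1], if (length(b) > 1) log(diff(b)))
trans_to_item <- function(pars) {
  list(a = exp(pars[1]), b = cumsum(c(pars[2], exp(pars[-(1:2)]))))
}

# ---- the EM engine ---------------------------------------------------------

# Y: N x J integer matrix (scores 0..K_j-1, NA allowed), already collapsed to
# contiguous observed categories per item. K_item: per-item category counts.
# group: NULL or a factor; free: item indices with group-specific parameters.
grm_em <- function(Y, K_item, grid, group = NULL, free = integer(0),
                   max_iter = 500, tol = 1e-4, start = NULL, verbose = FALSE) {
  N <- nrow(Y); J <- ncol(Y)
  nodes <- grid$theta; Q <- length(nodes)
  logw <- log(grid$weight)
  groups <- if (is.null(group)) factor(rep("all", N)) else factor(group)
  glev <- levels(groups)
  idx_g <- lapply(glev, function(g) which(groups == g))
  names(idx_g) <- glev

  # parameter blocks: anchors have one block ("all"); free items one per group
  block_key <- function(j, g) if (j %in% free) paste0(j, ".", g) else paste0(j, ".all")
  blocks <- new.env(parent = emptyenv())
  for (j in seq_len(J)) {
    st <- if (!is.null(start)) start[[j]] else {
      y <- Y[, j]
      pk <- vapply(seq_len(K_item[j] - 1), function(k) mean(y >= k, na.rm = TRUE),
                   numeric(1))
      b0 <- qlogis(pmin(pmax(1 - pk, 1e-4), 1 - 1e-4))
      if (length(b0) > 1) {  # enforce strict ordering of the start
        for (k in 2:length(b0)) if (b0[k] <= b0[k - 1]) b0[k] <- b0[k - 1] + 1e-3
      }
      list(a = 1, b = b0)
    }
    for (g in if (j %in% free) glev else "all") {
      assign(block_key(j, g), st, envir = blocks)
    }
  }

  # indicator matrices per item (N x K_j), zero rows for missing
  ind <- lapply(seq_len(J), function(j) {
    Im <- outer(Y[, j], 0:(K_item[j] - 1), `==`)
    Im[is.na(Im)] <- FALSE
    storage.mode(Im) <- "double"
    Im
  })

  loglik_trace <- numeric(0)
  converged <- FALSE
  post_by_group <- NULL
  for (iter in seq_len(max_iter)) {
    # E-step
    loglik <- 0
    post_by_group <- list()
    for (g in glev) {
      ig <- idx_g[[g]]
      LL <- matrix(0, length(ig), Q)
      for (j in seq_len(J)) {
        p <- get(block_key(j, g), envir = blocks)
        P <- log(pmax(grm_category_prob(p$a, p$b, nodes), 1e-300))  # Q x K_j
        yj <- Y[ig, j]
        obs <- !is.na(yj)
        if (any(obs)) LL[obs, ] <- LL[obs, ] + t(P[, yj[obs] + 1L, drop = FALSE])
      }
      LL <- sweep(LL, 2, logw, `+`)
      mx <- apply(LL, 1, max)
      E <- exp(LL - mx)
      rs <- rowSums(E)
      loglik <- loglik + sum(log(rs) + mx)
      post_by_group[[g]] <- E / rs
    }
    loglik_trace <- c(loglik_trace, loglik)

    # M-step
    max_change <- 0
    for (j in seq_len(J)) {
      gset <- if (j %in% free) glev else "all"
      for (g in gset) {
        R <- matrix(0, Q, K_item[j])
        use_groups <- if (g == "all") glev else g
        for (gg in use_groups) {
          ig <- idx_g[[gg]]
          R <- R + crossprod(post_by_group[[gg]], ind[[j]][ig, , drop = FALSE])
        }
        cur <- get(block_key(j, g), envir = blocks)
        p0 <- item_to_trans(cur$a, cur$b)
        opt <- optim(p0, item_objective, item_gradient, R = R, nodes = nodes,
                     method = "BFGS",
                     control = list(maxit = 60, reltol = 1e-12))
        newp <- trans_to_item(opt$par)
        max_change <- max(max_change, abs(newp$a - cur$a), abs(newp$b - cur$b))
        assign(block_key(j, g), newp, envir = blocks)
      }
    }
    if (verbose) {
      message(sprintf("EM iter %d: loglik %.4f, max change %.2e",
                      iter, loglik, max_change))
    }
    if (max_change < tol) { converged <- TRUE; break }
  }

  params <- lapply(glev, function(g) {
    lapply(seq_len(J), function(j) get(block_key(j, g), envir = blocks))
  })
  names(params) <- glev
  list(params = params, loglik = loglik_trace[length(loglik_trace)],
       loglik_trace = loglik_trace, n_iter = length(loglik_trace),
       converged = converged, post_by_group = post_by_group,
       idx_g = idx_g, glev = glev, free = free, K_item = K_item)
}

# ---- standard-error computation (outer product of gradients) ---------------

# per-person score vectors of the marginal log-likelihood, single-group fit
grm_opg_se <- function(Y, params, K_item, grid, post) {
  N <- nrow(Y); J <- ncol(Y)
  nodes <- grid$theta
  se <- vector("list", J)
  G_all <- NULL
  for (j in seq_len(J)) {
    a <- params[[j]]$a; b <- params[[j]]$b
    Km1 <- length(b)
    cum <- plogis(outer(nodes, b, function(th, bb) a * (th - bb)))
    s <- cum * (1 - cum)
    Pfull <- cbind(1, cum, 0)
    P <- pmax(Pfull[, -ncol(Pfull), drop = FALSE] - Pfull[, -1, drop = FALSE], 1e-300)
    # dlogP_k/dpar at each node, par = (a, b_1..b_Km1)
    np <- Km1 + 1
    Gj <- matrix(0, N, np)
    yj <- Y[, j]
    for (k in 0:(K_item[j] - 1)) {
      sel <- which(yj == k)
      if (length(sel) == 0) next
      # dP_k/da = s_k (th - b_k) - s_{k+1}(th - b_{k+1}), s_0 = s_K = 0
      d_a <- numeric(length(nodes))
      if (k >= 1) d_a <- d_a + s[, k] * (nodes - b[k])
      if (k + 1 <= Km1) d_a <- d_a - s[, k + 1] * (nodes - b[k + 1])
      D <- matrix(0, length(nodes), np)
      D[, 1] <- d_a / P[, k + 1]
      if (k >= 1) D[, 1 + k] <- -a * s[, k] / P[, k + 1]
      if (k + 1 <= Km1) D[, 1 + k + 1] <- a * s[, k + 1] / P[, k + 1]
      Gj[sel, ] <- post[sel, , drop = FALSE] %*% D
    }
    G_all <- cbind(G_all, Gj)
  }
  info <- crossprod(G_all)
  v <- tryCatch(diag(solve(info)), error = function(e) rep(NA_real_, ncol(info)))
  if (anyNA(v)) {
    warn("Information matrix is singular; standard errors set to NA.")
  }
  ses <- sqrt(pmax(v, 0))
  # split back into per-item (a, b) SEs
  pos <- 0
  for (j in seq_len(J)) {
    np <- K_item[j]  # 1 + (K_j - 1)
    se[[j]] <- list(a = ses[pos + 1], b = ses[pos + 2:np])
    pos <- pos + np
  }
  se
}

# ---- data preparation ------------------------------------------------------

# collapse never-observed categories to a contiguous 0..K_j-1 coding
prepare_scores <- function(Y, collapse = TRUE) {
  J <- ncol(Y)
  K_item <- integer(J)
  maps <- vector("list", J)
  for (j in seq_len(J)) {
    obs <- sort(unique(Y[, j][!is.na(Y[, j])]))
    if (length(obs) < 2) {
      abort(paste0("Item ", j, " has fewer than 2 observed categories; ",
                   "it cannot be calibrated."))
    }
    full <- seq(min(0, obs[1]), max(obs))
    if (!all(seq(0, max(obs)) %in% obs)) {
      if (!collapse) {
        abort(paste0("Item ", j, " has unobserved categories (",
                     paste(setdiff(seq(0, max(obs)), obs), collapse = ", "),
                     "); rerun with collapse = TRUE or recode."))
      }
      warn(paste0("Item ", j, ": collapsing unobserved categories; ",
                  "observed scores ", paste(obs, collapse = ","),
                  " recoded to 0..", length(obs) - 1, "."))
      Y[, j] <- match(Y[, j], obs) - 1L
      K_item[j] <- length(obs)
      maps[[j]] <- obs
    } else {
      K_item[j] <- length(obs)
      maps[[j]] <- obs
    }
  }
  list(Y = Y, K_item = K_item, maps = maps)
}

# ---- public fitting surface ------------------------------------------------

#' Calibrate the graded response model by marginal maximum likelihood
#'
#' EM estimation with a standard-normal latent-trait prior integrated over a
#' fixed quadrature grid. Threshold ordering is enforced structurally (first
#' threshold plus positive log-increments), so every iterate is a valid item
#' bank. Standard errors come from the outer-product-of-gradients
#' approximation to the information matrix and should be read as approximate.
#' Categories never observed for an item are collapsed into the adjacent
#' lower category (with a warning) when `collapse = TRUE`.
#'
#' @param data Response tibble with `item*` columns (scores 0..K-1, NA
#'   allowed and skipped in the pattern likelihood).
#' @param grid A [theta_grid()]; default 61 nodes on \[-5, 5\].
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol EM stops when the largest absolute parameter change in an
#'   iteration falls below `tol` (default 1e-4).
#' @param se Compute standard errors (default TRUE).
#' @param collapse Collapse never-observed categories instead of failing.
#' @param start Optional starting [item_bank()].
#' @param verbose Print per-iteration progress.
#' @return An object of class `grm_fit`: `bank` (calibrated [item_bank()]
#'   with SEs), `loglik`, `loglik_trace`, `n_iter`, `converged`, `n_persons`,
#'   `grid`, and `category_maps` recording any collapsing.
#' @examples
#' dat <- simulate_responses(simulation_spec(400, bdi2_bank()[1:5, ]), seed = 2)
#' fit <- fit_grm(dat, grid = theta_grid(31), tol = 1e-3)
#' tidy(fit)
#' @export
fit_grm <- function(data, grid = theta_grid(), max_iter = 500, tol = 1e-4,
                    se = TRUE, collapse = TRUE, start = NULL, verbose = FALSE) {
  Y <- response_matrix(data)
  if (nrow(Y) < 10) abort("Calibration needs at least 10 respondents.")
  prep <- prepare_scores(Y, collapse = collapse)
  start_list <- if (!is.null(start)) {
    pars <- bank_params(start)
    lapply(seq_len(nrow(start)), function(j) {
      b <- pars$b[j, ]; list(a = pars$a[j], b = b[!is.na(b)])
    })
  }
  em <- grm_em(prep$Y, prep$K_item, grid, max_iter = max_iter, tol = tol,
               start = start_list, verbose = verbose)
  params <- em$params[["all"]]
  ses <- if (se) {
    grm_opg_se(prep$Y, params, prep$K_item, grid, em$post_by_group[["all"]])
  }
  Kmax <- max(prep$K_item)
  row_of <- function(j) {
    b <- params[[j]]$b
    out <- c(a = params[[j]]$a,
             setNames(c(b, rep(NA_real_, Kmax - 1 - length(b))),
                      paste0("b", seq_len(Kmax - 1))))
    if (se) {
      sb <- ses[[j]]$b
      out <- c(out, se_a = ses[[j]]$a,
               setNames(c(sb, rep(NA_real_, Kmax - 1 - length(sb))),
                        paste0("se_b", seq_len(Kmax - 1))))
    }
    out
  }
  tab <- as_tibble(do.call(rbind, lapply(seq_along(params), row_of)))
  tab$item <- seq_along(params)
  labels <- grep("^item[0-9]+$", names(data), value = TRUE)
  tab$label <- labels
  bank <- item_bank(tab)
  structure(list(bank = bank, loglik = em$loglik,
                 loglik_trace = em$loglik_trace, n_iter = em$n_iter,
                 converged = em$converged, n_persons = nrow(Y),
                 grid = grid, category_maps = prep$maps),
            class = "grm_fit")
}

#' @export
print.grm_fit <- function(x, ...) {
  cat(sprintf("GRM calibration: %d items, %d persons\n",
              nrow(x$bank), x$n_persons))
  cat(sprintf("log-likelihood %.2f after %d EM iterations (%s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  print(x$bank)
  invisible(x)
}

#' Tidy a GRM calibration
#'
#' @param x A `grm_fit`.
#' @param ... Unused.
#' @return One row per estimated parameter with columns `item`, `label`,
#'   `term` (`a`, `b1`, ...), `estimate`, `std.error`.
#' @export
tidy.grm_fit <- function(x, ...) {
  bank <- x$bank
  terms <- c("a", grep("^b[0-9]+$", names(bank), value = TRUE))
  purrr::map_dfr(terms, function(tm) {
    tibble(item = bank$item, label = bank$label, term = tm,
           estimate = bank[[tm]],
           std.error = if (paste0("se_", tm) %in% names(bank))
             bank[[paste0("se_", tm)]] else NA_real_)
  }) %>%
    filter(!is.na(.data$estimate)) %>%
    arrange(.data$item, .data$term)
}

#' @rdname tidy.grm_fit
#' @export
glance.grm_fit <- function(x, ...) {
  tibble(logLik = x$loglik, n_iter = x$n_iter, converged = x$converged,
         n_persons = x$n_persons, n_items = nrow(x$bank))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
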