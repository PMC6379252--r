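#' Specify a synthetic graded-response dataset
#'
#' Describes a population of respondents for [simulate_responses()]: sample
#' size, generating item bank, the composition of two independent binary
#' attributes (gender and age group), latent-trait locations, and optional
#' injected differential item functioning (DIF). The latent trait is drawn as
#' theta ~ N(mean[gender] + shift[age_group], sd[gender]); the reference
#' calibration uses a standard-normal trait.
#'
#' @param n_persons Number of respondents (positive integer).
#' @param bank Generating [item_bank()].
#' @param gender_fractions Named proportions for levels `M` and `F`; sum to 1.
#' @param age_fractions Named proportions for levels `younger` and `older`.
#' @param gender_theta_mean Named latent-trait means for `M` and `F`.
#' @param gender_theta_sd Named positive latent-trait SDs for `M` and `F`.
#' @param age_theta_shift Named additive latent-trait shifts for `younger`
#'   and `older` (age acts as an independent location shift).
#' @param dif Optional list of [dif_injection()] entries.
#' @param missing_rate Proportion of item responses masked missing completely
#'   at random (default 0).
#' @return A list of class `simulation_spec`.
#' @seealso [simulate_responses()], [make_study_fixture()]
#' @export
simulation_spec <- function(n_persons,
                            bank,
                            gender_fractions = c(M = 0.449, F = 0.551),
                            age_fractions = c(younger = 0.859, older = 0.141),
                            gender_theta_mean = c(M = 0, F = 0),
                            gender_theta_sd = c(M = 1, F = 1),
                            age_theta_shift = c(younger = 0, older = 0),
                            dif = list(),
                            missing_rate = 0) {
  if (length(n_persons) != 1 || !is.finite(n_persons) || n_persons < 1) {
    abort("`n_persons` must be a positive integer.")
  }
  stopifnot(inherits(bank, "item_bank"))
  check_fractions <- function(x, levels, what) {
    if (!setequal(names(x), levels) || any(x < 0) || abs(sum(x) - 1) > 1e-8) {
      abort(paste0("`", what, "` must be named proportions over {",
                   paste(levels, collapse = ", "), "} summing to 1."))
    }
  }
  check_fractions(gender_fractions, c("M", "F"), "gender_fractions")
  check_fractions(age_fractions, c("younger", "older"), "age_fractions")
  if (any(gender_theta_sd <= 0)) abort("Latent-trait SDs must be positive.")
  for (d in dif) {
    if (!inherits(d, "dif_injection")) abort("`dif` must be a list of dif_injection() entries.")
    if (!d$item %in% bank$item) {
      abort(paste0("DIF injection targets item ", d$item, " which is not in the bank."))
    }
  }
  if (missing_rate < 0 || missing_rate >= 1) abort("`missing_rate` must be in [0, 1).")
  structure(list(n_persons = as.integer(n_persons), bank = bank,
                 gender_fractions = gender_fractions[c("M", "F")],
                 age_fractions = age_fractions[c("younger", "older")],
                 gender_theta_mean = gender_theta_mean[c("M", "F")],
                 gender_theta_sd = gender_theta_sd[c("M", "F")],
                 age_theta_shift = age_theta_shift[c("younger", "older")],
                 dif = dif, missing_rate = missing_rate),
            class = "simulation_spec")
}

#' Inject differential item functioning into a simulated item
#'
#' Uniform DIF is a constant shift: every threshold of the focal group is
#' lowered by `threshold_shift` (positive values make the item easier to
#' endorse at matched trait level). Non-uniform DIF multiplies the focal
#' group's discrimination by `discrimination_ratio`, so the group effect
#' varies with the trait. `threshold_shift = 0` and
#' `discrimination_ratio = 1` leave the item unchanged.
#'
#' @param item 1-based item index in the generating bank.
#' @param grouping Which attribute carries the DIF: `"gender"` or `"age_group"`.
#' @param focal Focal group level (`"F"` or `"older"` by default coding).
#' @param threshold_shift Real shift subtracted from every threshold for the
#'   focal group.
#' @param discrimination_ratio Positive multiplier on the focal group's
#'   discrimination.
#' @return A list of class `dif_injection`.
#' @export
dif_injection <- function(item, grouping = c("gender", "age_group"),
                          focal = NULL, threshold_shift = 0,
                          discrimination_ratio = 1) {
  grouping <- match.arg(grouping)
  focal <- focal %||% if (grouping == "gender") "F" else "older"
  if (discrimination_ratio <= 0) abort("`discrimination_ratio` must be positive.")
  structure(list(item = as.integer(item), grouping = grouping, focal = focal,
                 threshold_shift = threshold_shift,
                 discrimination_ratio = discrimination_ratio),
            class = "dif_injection")
}

# internal: apply injections for one item given group membership; returns
# per-person (a, b) after shifting the focal group's parameters
item_params_for_persons <- function(a, b, dif_for_item, persons) {
  a_vec <- rep(a, nrow(persons))
  b_mat <- matrix(b, nrow = nrow(persons), ncol = length(b), byrow = TRUE)
  for (d in dif_for_item) {
    focal <- persons[[d$grouping]] == d$focal
    a_vec[focal] <- a_vec[focal] * d$discrimination_ratio
    b_mat[focal, ] <- b_mat[focal, ] - d$threshold_shift
  }
  list(a = a_vec, b = b_mat)
}

#' Simulate ordinal responses from the graded response model
#'
#' Draws group membership, then each person's latent trait, then item
#' responses item-by-item from the GRM category probabilities at the drawn
#' trait value. A single seeded random stream makes the output reproducible:
#' identical spec and seed give an identical table.
#'
#' @param spec A [simulation_spec()].
#' @param seed Integer seed for the random stream.
#' @return A tibble with columns `person_id`, `gender`, `age_group`, `theta`
#'   (the generating trait value, kept for simulation studies), and
#'   `item01`..`itemJJ` integer scores 0..K-1.
#' @examples
#' spec <- simulation_spec(200, bdi2_bank())
#' simulate_responses(spec, seed = 1)
#' @export
simulate_responses <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(as.integer(seed))
  n <- spec$n_persons
  pars <- bank_params(spec$bank)
  J <- nrow(spec$bank)
  gender <- sample(c("M", "F"), n, replace = TRUE, prob = spec$gender_fractions)
  age_group <- sample(c("younger", "older"), n, replace = TRUE,
                      prob = spec$age_fractions)
  mu <- spec$gender_theta_mean[gender] + spec$age_theta_shift[age_group]
  sdv <- spec$gender_theta_sd[gender]
  theta <- rnorm(n, mu, sdv)
  persons <- tibble(gender = gender, age_group = age_group)
  dif_by_item <- split(spec$dif, vapply(spec$dif, `[[`, integer(1), "item"))
  scores <- matrix(NA_integer_, n, J)
  for (j in seq_len(J)) {
    dj <- dif_by_item[[as.character(spec$bank$item[j])]]
    if (is.null(dj)) {
      cum <- plogis(outer(theta, pars$b[j, ], function(th, bb) pars$a[j] * (th - bb)))
    } else {
      pp <- item_params_for_persons(pars$a[j], pars$b[j, ], dj, persons)
      cum <- plogis(pp$a * (theta - pp$b))
    }
    u <- runif(n)
    scores[, j] <- rowSums(u < cum)   # number of boundaries passed = category
  }
  if (spec$missing_rate > 0) {
    scores[matrix(runif(n * J) < spec$missing_rate, n, J)] <- NA_integer_
  }
  colnames(scores) <- paste0("item", sprintf("%02d", seq_len(J)))
  dplyr::bind_cols(
    tibble(person_id = seq_len(n), gender = gender, age_group = age_group,
           theta = theta),
    as_tibble(scores)
  )
}

# internal: expected total score when theta ~ N(mu, 1)
expected_total_at <- function(bank, mu, n_nodes = 121, range = c(-7, 7)) {
  nodes <- seq(range[1], range[2], length.out = n_nodes)
  probs <- bank_prob_list(bank, nodes)
  K <- n_categories(bank)
  cond_total <- rowSums(vapply(probs, function(p) as.numeric(p %*% (0:(K - 1))),
                               numeric(n_nodes)))
  vapply(mu, function(m) {
    w <- dnorm(nodes, mean = m)
    sum(w * cond_total) / sum(w)
  }, numeric(1))
}

#' Latent-trait mean matching a target expected total score
#'
#' Inverts the test characteristic curve in the population: finds the mean mu
#' of a unit-variance normal latent-trait distribution under which the
#' model-implied expected total score equals `target_total`. Used to place
#' simulated groups so their expected sum scores match published group means.
#'
#' @param bank An [item_bank()].
#' @param target_total Target expected total score, strictly inside
#'   (0, (K-1) * J).
#' @param tol Root-finding tolerance on the total score (default 1e-6).
#' @return The latent mean mu (scalar).
#' @examples
#' calibrate_group_mean(bdi2_bank(), 6.99)
#' @export
calibrate_group_mean <- function(bank, target_total, tol = 1e-6) {
  max_total <- (n_categories(bank) - 1) * nrow(bank)
  if (target_total <= 0 || target_total >= max_total) {
    abort(paste0("`target_total` must lie strictly inside (0, ", max_total, ")."))
  }
  uniroot(function(m) expected_total_at(bank, m) - target_total,
          interval = c(-6, 6), extendInt = "upX", tol = tol)$root
}

# internal: gender mean solving the age-mixture expected total
calibrate_gender_mean <- function(bank, target_total, age_shift, age_frac) {
  f <- function(m) {
    sum(age_frac * expected_total_at(bank, m + age_shift)) - target_total
  }
  uniroot(f, interval = c(-6, 6), extendInt = "upX", tol = 1e-6)$root
}

#' Study-sized synthetic fixture
#'
#' A synthetic stand-in for the college-student survey: 12,677 respondents,
#' 21 items generated from the published item bank, gender split 44.9% men /
#' 55.1% women and age split 85.9% younger / 14.1% older. Group latent-trait
#' locations are calibrated through the test characteristic curve so that the
#' expected total scores match the published group means (men 5.92, women
#' 7.85; younger 7.17, older 5.83), with age entering as a centered additive
#' shift. No DIF is injected unless supplied.
#'
#' @param seed Integer seed.
#' @param n_persons Sample size (default 12677).
#' @param dif Optional list of [dif_injection()] entries.
#' @return A response tibble as from [simulate_responses()].
#' @export
make_study_fixture <- function(seed = 1, n_persons = 12677, dif = list()) {
  bank <- bdi2_bank()
  age_frac <- c(younger = 0.859, older = 0.141)
  mu_age <- c(younger = calibrate_group_mean(bank, 7.17),
              older = calibrate_group_mean(bank, 5.83))
  age_shift <- mu_age - sum(age_frac * mu_age)
  gender_mean <- c(
    M = calibrate_gender_mean(bank, 5.92, age_shift, age_frac),
    F = calibrate_gender_mean(bank, 7.85, age_shift, age_frac)
  )
  spec <- simulation_spec(
    n_persons = n_persons, bank = bank,
    gender_theta_mean = gender_mean,
    age_theta_shift = age_shift,
    dif = dif
  )
  simulate_responses(spec, seed = seed)
}
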