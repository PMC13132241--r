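# Repeated-measures Bland-Altman agreement model.
#
# Epoch-level differences d_it (index minus criterion) are modelled as
#   d_it = mu + b_i + e_it,  b_i ~ N(0, tau2),  e_it ~ N(0, sigma2),
# with e_it optionally AR(1)-correlated within participant. Estimation is
# profile REML: mu and sigma2 have closed forms given the variance ratio
# lambda = tau2/sigma2 (and phi), so the restricted likelihood is profiled
# down to a 1- or 2-parameter search. For the random-intercept covariance
# sigma2*(R + lambda*J), Woodbury reduces every per-participant quantity to
# the R^-1 quadratic forms, which are O(n) for AR(1); with phi = 0 the fit
# needs only per-participant (n, sum d, sum d^2), which also makes the
# cluster bootstrap cheap.

#' Fit the repeated-measures Bland-Altman model
#'
#' Estimates mean bias `mu`, between-participant variance `tau2`, and
#' within-participant variance `sigma2` of paired-epoch differences by
#' restricted maximum likelihood, with a random intercept per participant
#' and optionally AR(1)-correlated residuals within participant. Limits of
#' agreement are `mu +/- 1.96 * sqrt(tau2 + sigma2)`.
#'
#' @param table Paired-epoch tibble with at least `participant_id` and
#'   `difference` columns (epochs assumed time-ordered within participant,
#'   which matters only when `with_ar1 = TRUE`).
#' @param with_ar1 Model residual autocorrelation within participant as a
#'   first-order autoregressive process? Default `FALSE`.
#' @return An object of class `hr_agreement`: a list with elements `mu`,
#'   `mu_se`, `mu_ci`, `tau2`, `sigma2`, `phi`, `total_sd`, `loa_lower`,
#'   `loa_upper`, `loa_lower_ci`, `loa_upper_ci` (filled by
#'   [cluster_bootstrap_loa()]), `n_epochs`, `n_participants`, `logLik`,
#'   and flags `degenerate` and `tau2_truncated`.
#' @seealso [limits_of_agreement()], [cluster_bootstrap_loa()],
#'   [proportional_bias_check()]
#' @export
fit_agreement <- function(table, with_ar1 = FALSE) {
  d_split <- split(table$difference, table$participant_id)
  n_part <- length(d_split)
  if (n_part < 2L) {
    rlang::abort("agreement model needs at least 2 participants", class = "hragree_estimation_error")
  }
  if (any(lengths(d_split) < 2L)) {
    rlang::abort("every participant needs at least 2 paired epochs", class = "hragree_estimation_error")
  }
  n_total <- nrow(table)

  if (stats::sd(table$difference) == 0) {
    mu <- table$difference[1]
    fit <- new_hr_agreement(mu = mu, mu_se = 0, tau2 = 0, sigma2 = 0,
                            phi = if (with_ar1) 0 else NA_real_,
                            n_epochs = n_total, n_participants = n_part,
                            logLik = NA_real_, degenerate = TRUE,
                            tau2_truncated = FALSE, with_ar1 = with_ar1,
                            data = table)
    return(fit)
  }

  if (!with_ar1) {
    stats_df <- cluster_stats(table)
    est <- reml_iid(stats_df)
    phi <- NA_real_
  } else {
    est <- reml_ar1(d_split)
    phi <- est$phi
  }

  new_hr_agreement(mu = est$mu, mu_se = est$mu_se, tau2 = est$tau2,
                   sigma2 = est$sigma2, phi = phi,
                   n_epochs = n_total, n_participants = n_part,
                   logLik = est$logLik, degenerate = FALSE,
                   tau2_truncated = est$tau2_truncated, with_ar1 = with_ar1,
                   data = table)
}

new_hr_agreement <- function(mu, mu_se, tau2, sigma2, phi, n_epochs,
                             n_participants, logLik, degenerate,
                             tau2_truncated, with_ar1, data) {
  total_sd <- sqrt(tau2 + sigma2)
  z <- stats::qnorm(0.975)
  structure(list(
    mu = mu, mu_se = mu_se, mu_ci = c(mu - z * mu_se, mu + z * mu_se),
    tau2 = tau2, sigma2 = sigma2, phi = phi,
    total_sd = total_sd,
    loa_lower = mu - 1.96 * total_sd,
    loa_upper = mu + 1.96 * total_sd,
    loa_lower_ci = c(NA_real_, NA_real_),
    loa_upper_ci = c(NA_real_, NA_real_),
    n_epochs = n_epochs, n_participants = n_participants,
    logLik = logLik, degenerate = degenerate,
    tau2_truncated = tau2_truncated, with_ar1 = with_ar1,
    data = data
  ), class = "hr_agreement")
}

# per-participant sufficient statistics for the phi = 0 fit
cluster_stats <- function(table) {
  table |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n = dplyr::n(), s = sum(.data$difference),
                     q = sum(.data$difference^2), .groups = "drop")
}

# Profiled REML deviance (up to constants) at variance ratio lambda, from
# sufficient stats. Returns the deviance and the implied (mu, sigma2, RSS).
reml_profile_iid <- function(lambda, st) {
  w <- 1 / (1 + lambda * st$n)        # shrinkage weight per cluster
  A <- sum(st$n * w)                  # 1' W^-1 1 summed
  mu <- sum(st$s * w) / A
  rss <- sum(st$q - 2 * mu * st$s + mu^2 * st$n -
               lambda * (st$s - mu * st$n)^2 * w)
  N <- sum(st$n)
  sigma2 <- rss / (N - 1)
  dev <- (N - 1) * log(sigma2) + sum(log(1 + lambda * st$n)) + log(A)
  list(dev = dev, mu = mu, sigma2 = sigma2, A = A)
}

reml_iid <- function(st) {
  f <- function(loglam) reml_profile_iid(exp(loglam), st)$dev
  opt <- stats::optimize(f, interval = c(-20, 12), tol = 1e-8)
  at_zero <- reml_profile_iid(0, st)
  if (at_zero$dev <= opt$objective) {
    lambda <- 0
    prof <- at_zero
  } else {
    lambda <- exp(opt$minimum)
    prof <- reml_profile_iid(lambda, st)
  }
  truncated <- lambda < 1e-6
  if (truncated) {
    lambda <- 0
    prof <- reml_profile_iid(0, st)
  }
  finish_reml(lambda, prof, N = sum(st$n))
}

finish_reml <- function(lambda, prof, N, phi = NULL) {
  sigma2 <- prof$sigma2
  out <- list(
    mu = prof$mu,
    mu_se = sqrt(sigma2 / prof$A),
    tau2 = lambda * sigma2,
    sigma2 = sigma2,
    tau2_truncated = lambda == 0,
    logLik = -0.5 * (prof$dev + (N - 1) * (1 + log(2 * pi)))
  )
  if (!is.null(phi)) out$phi <- phi
  out
}

# x' R^-1 y for the AR(1) correlation matrix R_jk = phi^|j-k|, in O(n)
ar1_quadform <- function(x, y, phi) {
  n <- length(x)
  if (n == 1L) return(x * y)
  core <- sum(x * y) + phi^2 * sum(x[-c(1L, n)] * y[-c(1L, n)]) -
    phi * (sum(x[-1L] * y[-n]) + sum(x[-n] * y[-1L]))
  core / (1 - phi^2)
}

# Profiled REML deviance for (lambda, phi) from per-participant vectors
reml_profile_ar1 <- function(lambda, phi, d_split) {
  a <- u <- q <- numeric(length(d_split))
  logdet_r <- 0
  for (i in seq_along(d_split)) {
    d <- d_split[[i]]
    ones <- rep(1, length(d))
    a[i] <- ar1_quadform(ones, ones, phi)
    u[i] <- ar1_quadform(ones, d, phi)
    q[i] <- ar1_quadform(d, d, phi)
    logdet_r <- logdet_r + (length(d) - 1L) * log(1 - phi^2)
  }
  w <- 1 / (1 + lambda * a)
  A <- sum(a * w)
  mu <- sum(u * w) / A
  rss <- sum(q - 2 * mu * u + mu^2 * a - lambda * (u - mu * a)^2 * w)
  N <- sum(lengths(d_split))
  sigma2 <- rss / (N - 1)
  dev <- (N - 1) * log(sigma2) + logdet_r + sum(log(1 + lambda * a)) + log(A)
  list(dev = dev, mu = mu, sigma2 = sigma2, A = A)
}

reml_ar1 <- function(d_split) {
  # method-of-moments / lag-1 starting values
  st <- tibble::tibble(
    participant_id = names(d_split),
    n = lengths(d_split),
    s = vapply(d_split, sum, 0),
    q = vapply(d_split, function(d) sum(d^2), 0)
  )
  init <- reml_iid(st)
  lam0 <- max(init$tau2 / init$sigma2, 1e-4)
  resid_split <- lapply(d_split, function(d) d - mean(d))
  num <- sum(vapply(resid_split, function(r) sum(r[-1] * r[-length(r)]), 0))
  den <- sum(vapply(resid_split, function(r) sum(r^2), 0))
  phi0 <- max(min(num / den, 0.95), -0.95)

  f <- function(par) {
    reml_profile_ar1(exp(par[1]), tanh(par[2]), d_split)$dev
  }
  opt <- stats::optim(c(log(lam0), atanh(phi0)), f, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  lambda <- exp(opt$par[1])
  phi <- tanh(opt$par[2])
  # boundary check: lambda -> 0
  at_zero <- reml_profile_ar1(0, phi, d_split)
  if (at_zero$dev <= opt$value || lambda < 1e-6) {
    lambda <- 0
    prof <- at_zero
  } else {
    prof <- reml_profile_ar1(lambda, phi, d_split)
  }
  finish_reml(lambda, prof, N = sum(lengths(d_split)), phi = phi)
}

#' Limits of agreement from bias and variance components
#'
#' `total_sd = sqrt(tau2 + sigma2)`; the 95% limits are
#' `mu -/+ 1.96 * total_sd` (fixed 1.96 multiplier, no small-sample
#' t adjustment).
#'
#' @param mu Mean bias (beats/min), or an `hr_agreement` fit (then the
#'   other arguments are taken from it).
#' @param tau2,sigma2 Between- and within-participant variance components
#'   (beats^2/min^2); must be non-negative.
#' @return A one-row tibble with `total_sd`, `loa_lower`, `loa_upper`.
#' @examples
#' limits_of_agreement(0, tau2 = 0, sigma2 = 1) # -1.96, 1.96
#' @export
limits_of_agreement <- function(mu, tau2 = NULL, sigma2 = NULL) {
  if (inherits(mu, "hr_agreement")) {
    fit <- mu
    mu <- fit$mu; tau2 <- fit$tau2; sigma2 <- fit$sigma2
  }
  if (tau2 < 0 || sigma2 < 0) {
    rlang::abort("variance components must be non-negative", class = "hragree_domain_error")
  }
  total_sd <- sqrt(tau2 + sigma2)
  tibble::tibble(total_sd = total_sd,
                 loa_lower = mu - 1.96 * total_sd,
                 loa_upper = mu + 1.96 * total_sd)
}

#' Cluster-bootstrap confidence intervals for the limits of agreement
#'
#' Resamples whole participants with replacement, refits the agreement
#' model on each replicate, and returns percentile confidence intervals
#' for the lower and upper limits. Resampling participants (rather than
#' epochs) preserves the within-participant correlation the model asserts.
#' Replicates drawing fewer than 2 distinct participants are redrawn.
#'
#' @param table Paired-epoch tibble (as for [fit_agreement()]).
#' @param n_replicates Number of bootstrap replicates. Default 1000; at
#'   least 100 for reportable intervals.
#' @param seed Integer seed; identical seeds give identical intervals.
#' @param ci_level Confidence level in (0, 1). Default 0.95.
#' @param with_ar1 Passed to the per-replicate refit.
#' @return A list with `loa_lower_ci`, `loa_upper_ci` (each `c(lower,
#'   upper)`), `mu_ci`, the replicate tibble `replicates`, and `n_redrawn`.
#' @export
cluster_bootstrap_loa <- function(table, n_replicates = 1000, seed = NULL,
                                  ci_level = 0.95, with_ar1 = FALSE) {
  stopifnot(n_replicates >= 1, ci_level > 0, ci_level < 1)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  if (stats::sd(table$difference) == 0) {
    fit <- fit_agreement(table, with_ar1 = with_ar1)
    return(list(loa_lower_ci = rep(fit$loa_lower, 2),
                loa_upper_ci = rep(fit$loa_upper, 2),
                mu_ci = rep(fit$mu, 2),
                replicates = tibble::tibble(mu = rep(fit$mu, n_replicates),
                                            loa_lower = rep(fit$loa_lower, n_replicates),
                                            loa_upper = rep(fit$loa_upper, n_replicates)),
                n_redrawn = 0L))
  }

  if (!with_ar1) {
    st <- cluster_stats(table)
    draw_fit <- function(idx) {
      est <- reml_iid(st[idx, ])
      c(est$mu, est$tau2, est$sigma2)
    }
    ids <- seq_len(nrow(st))
    distinct <- function(idx) length(unique(st$participant_id[idx]))
  } else {
    d_split <- split(table$difference, table$participant_id)
    draw_fit <- function(idx) {
      est <- reml_ar1(stats::setNames(d_split[idx], paste0("b", seq_along(idx))))
      c(est$mu, est$tau2, est$sigma2)
    }
    ids <- seq_along(d_split)
    distinct <- function(idx) length(unique(idx))
  }

  n_id <- length(ids)
  n_redrawn <- 0L
  reps <- matrix(NA_real_, n_replicates, 3)
  for (b in seq_len(n_replicates)) {
    repeat {
      idx <- sample(ids, n_id, replace = TRUE)
      if (distinct(idx) >= 2L) break
      n_redrawn <- n_redrawn + 1L
    }
    reps[b, ] <- draw_fit(idx)
  }
  if (n_redrawn > 0) {
    rlang::inform(sprintf("cluster_bootstrap_loa: redrew %d degenerate replicate(s)", n_redrawn))
  }
  total_sd <- sqrt(reps[, 2] + reps[, 3])
  replicates <- tibble::tibble(mu = reps[, 1],
                               loa_lower = reps[, 1] - 1.96 * total_sd,
                               loa_upper = reps[, 1] + 1.96 * total_sd)
  alpha <- (1 - ci_level) / 2
  pct <- function(x) unname(stats::quantile(x, c(alpha, 1 - alpha), type = 7))
  list(loa_lower_ci = pct(replicates$loa_lower),
       loa_upper_ci = pct(replicates$loa_upper),
       mu_ci = pct(replicates$mu),
       replicates = replicates,
       n_redrawn = n_redrawn)
}

#' Proportional-bias and heteroscedasticity diagnostics
#'
#' Regresses the epoch difference on the pair mean
#' `(hr_index + hr_criterion)/2`. The slope (with participant-clustered
#' uncertainty) measures proportional bias; the slope of `|residual|` on
#' the pair mean measures whether dispersion grows with heart rate.
#'
#' @param table Paired-epoch tibble with `hr_index`, `hr_criterion`,
#'   `difference`, `participant_id`; at least 10 rows.
#' @param ci_level Confidence level for the slope interval. Default 0.95.
#' @return One-row tibble: `slope`, `slope_ci_lower`, `slope_ci_upper`
#'   (cluster-robust), and `heteroscedasticity_stat` (beats/min of absolute
#'   residual per beats/min of pair mean; positive means dispersion
#'   increases with heart rate).
#' @export
proportional_bias_check <- function(table, ci_level = 0.95) {
  if (nrow(table) < 10L) {
    rlang::abort("proportional-bias check needs at least 10 paired epochs",
                 class = "hragree_domain_error")
  }
  df <- dplyr::mutate(table, pair_mean = (.data$hr_index + .data$hr_criterion) / 2)
  if (stats::sd(df$pair_mean) == 0) {
    rlang::abort("pair means are constant: slope undefined", class = "hragree_domain_error")
  }
  fit <- stats::lm(difference ~ pair_mean, data = df)
  vc <- sandwich::vcovCL(fit, cluster = df$participant_id)
  slope <- stats::coef(fit)[["pair_mean"]]
  se <- sqrt(vc["pair_mean", "pair_mean"])
  g <- length(unique(df$participant_id))
  tq <- stats::qt(1 - (1 - ci_level) / 2, df = max(g - 1L, 1L))
  hetero <- stats::lm(abs(stats::resid(fit)) ~ df$pair_mean)
  tibble::tibble(
    slope = slope,
    slope_ci_lower = slope - tq * se,
    slope_ci_upper = slope + tq * se,
    heteroscedasticity_stat = stats::coef(hetero)[[2]]
  )
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
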