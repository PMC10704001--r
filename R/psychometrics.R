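#' Per-level binomial response counts for psychometric fitting
#'
#' @param levels Stimulus values (Hz, ms, us, or dB), strictly increasing,
#'   positive (fits are performed on the log-stimulus axis).
#' @param n_trials,n_correct Integer vectors aligned with `levels`.
#' @param guess Guess rate gamma: 1/2 (2AFC), 1/3 (3AFC), or 1/6 (6AFC).
#' @return An object of class `psychometric_data`.
#' @export
psychometric_data <- function(levels, n_trials, n_correct, guess) {
  stopifnot(length(levels) == length(n_trials),
            length(levels) == length(n_correct))
  if (any(levels <= 0)) stop("levels must be positive (log-axis model)")
  if (is.unsorted(levels, strictly = TRUE)) {
    stop("levels must be strictly increasing")
  }
  if (any(n_correct < 0) || any(n_correct > n_trials)) {
    stop("need 0 <= n_correct <= n_trials at every level")
  }
  if (!(guess > 0 && guess < 1)) stop("guess rate must be in (0, 1)")
  structure(
    list(levels = as.numeric(levels), n_trials = as.integer(n_trials),
         n_correct = as.integer(n_correct), guess = guess),
    class = "psychometric_data"
  )
}

# Logistic sigmoid on the log-stimulus axis, parameterised by midpoint m
# (log units) and width w = log-axis distance between the 5% and 95% points.
WIDTH_SCALE <- 2 * stats::qlogis(0.95)

sigmoid_log <- function(log_x, m, w) {
  stats::plogis(WIDTH_SCALE * (log_x - m) / w)
}

# Beta-binomial log pmf with mean p and intraclass correlation eta in [0, 1);
# eta = 0 degenerates to the binomial.
dbetabinom_log <- function(k, n, p, eta) {
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  if (eta <= 0) return(stats::dbinom(k, n, p, log = TRUE))
  nu <- (1 - eta) / eta
  a <- p * nu
  b <- (1 - p) * nu
  lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
}

#' Grid configuration for the Bayesian psychometric fit
#'
#' @param n_m,n_w,n_lapse,n_eta Grid sizes for the sigmoid midpoint, width,
#'   lapse rate, and beta-binomial overdispersion.
#' @param lapse_max Upper bound of the lapse grid.
#' @param eta_max Upper bound of the overdispersion grid (< 1). `eta_max = 0`
#'   with `n_eta = 1` gives a pure-binomial fit.
#' @param m_pad Extension of the midpoint grid beyond the data's log-level
#'   range, as a fraction of that range.
#' @return A named list.
#' @export
grid_config <- function(n_m = 40, n_w = 40, n_lapse = 20, n_eta = 10,
                        lapse_max = 0.1, eta_max = 0.6, m_pad = 0.3) {
  list(n_m = n_m, n_w = n_w, n_lapse = n_lapse, n_eta = n_eta,
       lapse_max = lapse_max, eta_max = eta_max, m_pad = m_pad)
}

#' Priors for the Bayesian psychometric fit
#'
#' The midpoint prior is uniform over a grid spanning the data's log-level
#' range (padded); the width prior is uniform on log width over the same
#' grid; lapse and overdispersion carry Beta priors concentrated near zero.
#'
#' @param lapse_shape2 Second shape of the Beta(1, .) lapse prior (on
#'   lapse / lapse_max).
#' @param eta_shape2 Second shape of the Beta(1, .) overdispersion prior.
#' @return A named list.
#' @export
psychometric_priors <- function(lapse_shape2 = 24, eta_shape2 = 9) {
  list(lapse_shape2 = lapse_shape2, eta_shape2 = eta_shape2)
}

#' Fit a psychometric function by Bayesian grid integration
#'
#' Fits the four-parameter performance model
#' `P(correct | x) = gamma + (1 - gamma - lapse) * S(log x; m, w)` with a
#' logistic sigmoid `S` (midpoint `m`, 5–95% width `w`, both on the log
#' stimulus axis), a fixed guess rate `gamma`, a lapse rate, and a
#' beta-binomial observation model with overdispersion `eta` (intraclass
#' correlation; `eta = 0` is binomial). The full posterior over
#' `(m, w, lapse, eta)` is computed by numerical integration on a product
#' grid; normalization is exact on the grid.
#'
#' All-correct or all-chance data do not error: the fit is returned with
#' `boundary = TRUE`, signalling that the posterior piles up at a grid edge
#' and the threshold is not localized by the data.
#'
#' @param data A [psychometric_data()].
#' @param priors A [psychometric_priors()].
#' @param grid A [grid_config()].
#' @return An object of class `psychometric_fit`: grid vectors, the
#'   normalized posterior array `posterior` (dims m, w, lapse, eta),
#'   posterior means `estimate`, the data, and a `boundary` flag.
#' @export
fit_psychometric <- function(data, priors = psychometric_priors(),
                             grid = grid_config()) {
  stopifnot(inherits(data, "psychometric_data"))
  if (length(data$levels) < 3) stop("need responses at >= 3 levels")
  log_x <- log(data$levels)
  rng <- range(log_x)
  span <- diff(rng)
  if (span <= 0) stop("degenerate level range")
  m_grid <- seq(rng[1] - grid$m_pad * span, rng[2] + grid$m_pad * span,
                length.out = grid$n_m)
  w_min <- min(diff(sort(log_x)))
  w_grid <- exp(seq(log(w_min), log(3 * span), length.out = grid$n_w))
  lapse_grid <- seq(0, grid$lapse_max, length.out = grid$n_lapse)
  eta_grid <- seq(0, grid$eta_max, length.out = grid$n_eta)

  n_mw <- grid$n_m * grid$n_w
  m_vec <- rep(m_grid, times = grid$n_w)
  w_vec <- rep(w_grid, each = grid$n_m)
  n_lev <- length(log_x)
  # sigmoid values for every (m, w) at every level: n_mw x n_lev
  s_mat <- sigmoid_log(
    matrix(log_x, n_mw, n_lev, byrow = TRUE),
    matrix(m_vec, n_mw, n_lev),
    matrix(w_vec, n_mw, n_lev)
  )
  k_mat <- matrix(data$n_correct, n_mw, n_lev, byrow = TRUE)
  n_mat <- matrix(data$n_trials, n_mw, n_lev, byrow = TRUE)

  loglik <- array(0, dim = c(n_mw, grid$n_lapse, grid$n_eta))
  for (il in seq_len(grid$n_lapse)) {
    p_mat <- data$guess + (1 - data$guess - lapse_grid[il]) * s_mat
    for (ie in seq_len(grid$n_eta)) {
      ll <- dbetabinom_log(k_mat, n_mat, p_mat, eta_grid[ie])
      loglik[, il, ie] <- rowSums(ll)
    }
  }

  # log prior: uniform m, log-uniform w (uniform on the log-spaced grid),
  # Beta(1, s) on lapse/lapse_max and on eta
  lp_lapse <- stats::dbeta(
    if (grid$lapse_max > 0) lapse_grid / grid$lapse_max else lapse_grid,
    1, priors$lapse_shape2, log = TRUE)
  lp_eta <- if (grid$n_eta == 1) 0 else
    stats::dbeta(pmin(eta_grid, 1 - 1e-9), 1, priors$eta_shape2, log = TRUE)
  logpost <- sweep(loglik, 2, lp_lapse, `+`)
  logpost <- sweep(logpost, 3, lp_eta, `+`)
  logpost <- logpost - max(logpost)
  post <- exp(logpost)
  post <- post / sum(post)
  post <- array(post, dim = c(grid$n_m, grid$n_w, grid$n_lapse, grid$n_eta))

  marg_m <- apply(post, 1, sum)
  marg_w <- apply(post, 2, sum)
  marg_lapse <- apply(post, 3, sum)
  marg_eta <- apply(post, 4, sum)
  estimate <- c(
    m = sum(marg_m * m_grid),
    w = sum(marg_w * w_grid),
    lapse = sum(marg_lapse * lapse_grid),
    eta = sum(marg_eta * eta_grid)
  )
  # posterior piling at an edge of the midpoint grid => data don't bracket
  # the transition (all-correct / all-chance / out-of-range threshold)
  boundary <- which.max(marg_m) %in% c(1L, grid$n_m)

  structure(
    list(
      m_grid = m_grid, w_grid = w_grid, lapse_grid = lapse_grid,
      eta_grid = eta_grid, posterior = post, estimate = estimate,
      guess = data$guess, data = data, boundary = boundary
    ),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  e <- x$estimate
  cat(sprintf(
    paste0("<psychometric_fit> guess %.3f | midpoint exp(m) = %.4g, ",
           "width %.3g (log), lapse %.3f, eta %.3f%s\n"),
    x$guess, exp(e["m"]), e["w"], e["lapse"], e["eta"],
    if (x$boundary) " [boundary]" else ""
  ))
  invisible(x)
}

# Threshold (stimulus units) at target proportion correct for grid points
# (m, w, lapse); NA where the target is unattainable for that lapse.
threshold_grid_values <- function(fit, target_pc) {
  f <- (target_pc - fit$guess) / (1 - fit$guess - fit$lapse_grid)
  ok <- f > 0 & f < 1
  q <- ifelse(ok, stats::qlogis(pmin(pmax(f, 1e-12), 1 - 1e-12)), NA_real_)
  # thr = exp(m + w * qlogis(f) / WIDTH_SCALE): dims m x w x lapse
  arr <- array(NA_real_,
               dim = c(length(fit$m_grid), length(fit$w_grid),
                       length(fit$lapse_grid)))
  for (il in seq_along(fit$lapse_grid)) {
    if (!ok[il]) next
    arr[, , il] <- exp(outer(fit$m_grid, fit$w_grid * q[il] / WIDTH_SCALE, `+`))
  }
  arr
}

#' Threshold at a target performance level
#'
#' Inverts the fitted psychometric function at `target_pc` (0.794 for 3AFC,
#' 0.75 for 2AFC by field convention) for every posterior grid point and
#' propagates the posterior weights into a point estimate (posterior mean)
#' and a 95% credible interval.
#'
#' @param fit A [fit_psychometric()] result.
#' @param target_pc Target proportion correct, strictly between the guess
#'   rate and the smallest attainable ceiling `1 - lapse_max`.
#' @param ci Credible-interval mass (default 0.95).
#' @return An object of class `threshold_estimate`: `threshold` (stimulus
#'   units), `ci` (lower, upper), `target_pc`, and `boundary` (inherited).
#' @export
threshold_at <- function(fit, target_pc, ci = 0.95) {
  stopifnot(inherits(fit, "psychometric_fit"))
  ceiling_min <- 1 - max(fit$lapse_grid)
  if (target_pc <= fit$guess) {
    stop(sprintf("target_pc must exceed the guess rate %.3f", fit$guess))
  }
  if (target_pc >= ceiling_min) {
    stop(sprintf("target_pc must be below the attainable ceiling %.3f",
                 ceiling_min))
  }
  thr <- threshold_grid_values(fit, target_pc)
  w <- apply(fit$posterior, c(1, 2, 3), sum) # marginalize eta
  keep <- !is.na(thr)
  vals <- thr[keep]
  wts <- w[keep]
  wts <- wts / sum(wts)
  ord <- order(vals)
  vals <- vals[ord]
  cw <- cumsum(wts[ord])
  alpha <- (1 - ci) / 2
  est <- sum(vals * wts[ord])
  lo <- vals[which(cw >= alpha)[1]]
  hi <- vals[which(cw >= 1 - alpha)[1]]
  structure(
    list(threshold = est, ci = c(lower = lo, upper = hi),
         target_pc = target_pc, boundary = fit$boundary),
    class = "threshold_estimate"
  )
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("<threshold_estimate> %.4g [%.4g, %.4g] at %.1f%% correct%s\n",
              x$threshold, x$ci[1], x$ci[2], 100 * x$target_pc,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Co-modulation masking release from per-condition thresholds
#'
#' Computes the masking-release differences `CORR - REF` and `CORR - ACORR`
#' from tone-detection thresholds (dB SNR) in the three flanker conditions.
#' The sign convention makes a release positive: each value is the reference
#' condition's threshold minus the CORR threshold, so lower (better)
#' thresholds under co-modulated flankers give positive CMR.
#'
#' @param thresholds Named list or vector with elements `REF`, `CORR`,
#'   `ACORR`: either numeric thresholds in dB SNR or
#'   [threshold_at()] results (whose CIs are then propagated by interval
#'   arithmetic).
#' @return A data frame with columns `comparison`, `cmr_db`, and (when CIs
#'   are available) `ci_lower`, `ci_upper`.
#' @export
cmr_effect <- function(thresholds) {
  need <- c("REF", "CORR", "ACORR")
  if (!all(need %in% names(thresholds))) {
    stop("missing condition(s): ",
         paste(setdiff(need, names(thresholds)), collapse = ", "))
  }
  get_val <- function(x) if (inherits(x, "threshold_estimate")) x$threshold else as.numeric(x)
  get_ci <- function(x) if (inherits(x, "threshold_estimate")) x$ci else NULL
  v <- vapply(thresholds[need], get_val, numeric(1))
  out <- data.frame(
    comparison = c("CORR-REF", "CORR-ACORR"),
    cmr_db = c(v["REF"] - v["CORR"], v["ACORR"] - v["CORR"]),
    row.names = NULL
  )
  cis <- lapply(thresholds[need], get_ci)
  if (!any(vapply(cis, is.null, logical(1)))) {
    out$ci_lower <- c(cis$REF["lower"] - cis$CORR["upper"],
                      cis$ACORR["lower"] - cis$CORR["upper"])
    out$ci_upper <- c(cis$REF["upper"] - cis$CORR["lower"],
                      cis$ACORR["upper"] - cis$CORR["lower"])
  }
  out
}

#' Convert between SNR in dB and linear amplitude ratio
#'
#' The psychometric fit works on a positive stimulus axis (log-transformed
#' internally). SNR ladders expressed in dB, which may be negative, are
#' mapped to linear amplitude ratios `10^(snr/20)` before fitting, and
#' thresholds mapped back with [ratio_to_snr_db()].
#'
#' @param snr_db SNR in dB.
#' @return Linear amplitude ratio.
#' @export
snr_db_to_ratio <- function(snr_db) 10^(snr_db / 20)

#' @rdname snr_db_to_ratio
#' @param ratio Linear amplitude ratio.
#' @export
ratio_to_snr_db <- function(ratio) 20 * log10(ratio)
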