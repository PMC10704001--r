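# Independent oracles used across test files. These deliberately avoid the
# package's own code paths where they check one.

# F0 estimate: mean instantaneous frequency of the band-passed fundamental.
est_f0 <- function(x, sr, lo = 80, hi = 140) {
  n <- length(x)
  spec <- stats::fft(x)
  fr <- (seq_len(n) - 1) * sr / n
  fr <- pmin(fr, sr - fr)
  spec[fr < lo | fr > hi] <- 0
  fund <- Re(stats::fft(spec, inverse = TRUE)) / n
  ph <- Arg(audscreen:::analytic_signal(fund))
  d <- diff(ph)
  d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
  mean(d[round(n * 0.2):round(n * 0.8)]) * sr / (2 * pi)
}

rms_of <- function(x) sqrt(mean(x^2))
db_of <- function(x) 20 * log10(rms_of(x))

# Synthetic consonant confusion matrix with planted blocks: members of a
# block confuse each other heavily, everything else weakly.
planted_confusion_records <- function(blocks, n_per = 200, p_within = 0.12,
                                      p_off = 0.005,
                                      labels = consonant_labels(),
                                      seed = 1) {
  membership <- stats::setNames(rep(NA_integer_, length(labels)), labels)
  for (i in seq_along(blocks)) membership[blocks[[i]]] <- i
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    recs <- lapply(labels, function(p) {
      prob <- stats::setNames(rep(p_off, length(labels)), labels)
      same_block <- !is.na(membership[p]) &
        membership == membership[p] & labels != p
      prob[same_block] <- p_within
      prob[p] <- 1 - sum(prob[names(prob) != p])
      data.frame(
        presented = p,
        responded = sample(labels, n_per, replace = TRUE, prob = prob),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, recs)
  })
}

# Brute-force posterior over (m, w, lapse) with a *binomial* likelihood, on
# the same grids as a given fit; the eta -> 0 oracle for fit_psychometric.
binomial_grid_posterior <- function(fit, priors = psychometric_priors()) {
  d <- fit$data
  log_x <- log(d$levels)
  n_m <- length(fit$m_grid)
  n_w <- length(fit$w_grid)
  n_l <- length(fit$lapse_grid)
  post <- array(NA_real_, dim = c(n_m, n_w, n_l))
  for (im in seq_len(n_m)) for (iw in seq_len(n_w)) for (il in seq_len(n_l)) {
    s <- stats::plogis(2 * stats::qlogis(0.95) *
                         (log_x - fit$m_grid[im]) / fit$w_grid[iw])
    p <- d$guess + (1 - d$guess - fit$lapse_grid[il]) * s
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    post[im, iw, il] <- sum(stats::dbinom(d$n_correct, d$n_trials, p,
                                          log = TRUE))
  }
  lp_lapse <- stats::dbeta(fit$lapse_grid / max(fit$lapse_grid), 1,
                           priors$lapse_shape2, log = TRUE)
  post <- sweep(post, 3, lp_lapse, `+`)
  post <- exp(post - max(post))
  post / sum(post)
}
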