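#' Group summary statistics from a published report
#'
#' Normalizes reported dispersion to a standard deviation: SEM inputs are
#' converted via `sigma = SEM * sqrt(n)` (requiring `n`), SD inputs pass
#' through. The reported central value may be a mean or a median (used
#' interchangeably as the location estimate, following meta-analytic
#' practice when only medians are printed).
#'
#' @param mu Central value (mean or median).
#' @param dispersion_kind `"SD"` or `"SEM"`.
#' @param value The dispersion value (>= 0).
#' @param n Group size (required for SEM; may be `NULL` when a source does
#'   not report it).
#' @param units Unit label, carried through for provenance.
#' @return An object of class `group_stats` with fields `mu`, `sigma`, `n`
#'   (NA when unknown), `units`, and `dispersion_kind` (provenance).
#' @examples
#' stats_from_report(10, "SEM", 1, n = 25)$sigma # 5
#' @export
stats_from_report <- function(mu, dispersion_kind = c("SD", "SEM"), value,
                              n = NULL, units = "") {
  dispersion_kind <- match.arg(dispersion_kind)
  if (value < 0) stop("dispersion value must be >= 0")
  if (!is.null(n) && n < 2) stop("n must be >= 2 when provided")
  sigma <- if (dispersion_kind == "SEM") {
    if (is.null(n)) stop("SEM given without n: cannot recover SD")
    value * sqrt(n)
  } else {
    value
  }
  structure(
    list(mu = mu, sigma = sigma, n = if (is.null(n)) NA_integer_ else n,
         units = units, dispersion_kind = dispersion_kind),
    class = "group_stats"
  )
}

#' Hedges' g: bias-corrected standardized mean difference
#'
#' `g = J * (a$mu - b$mu) / s_pooled` with the small-sample correction
#' `J = 1 - 3 / (4 df - 1)`, `df = n1 + n2 - 2`. Pooling is either
#' n-weighted (`s^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2)`, the classic
#' definition) or equal-weight (`s^2 = (s1^2 + s2^2) / 2`), the latter used
#' when group sizes are unknown, in which case `J = 1`.
#'
#' @param a,b [stats_from_report()] objects (the difference is `a - b`).
#' @param pooling `"equal"` or `"n_weighted"`.
#' @return An object of class `effect_size`: `g`, `variance` (NA when n's
#'   are unknown), `ci_95`, correction factor `J`, and `pooling`.
#' @export
hedges_g <- function(a, b, pooling = c("equal", "n_weighted")) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(a, "group_stats"), inherits(b, "group_stats"))
  if (a$sigma == 0 && b$sigma == 0) {
    stop("both group SDs are zero: standardized difference undefined")
  }
  have_n <- !is.na(a$n) && !is.na(b$n)
  if (pooling == "n_weighted" && !have_n) {
    stop("n-weighted pooling requires both group sizes")
  }
  s_pooled <- if (pooling == "n_weighted") {
    sqrt(((a$n - 1) * a$sigma^2 + (b$n - 1) * b$sigma^2) / (a$n + b$n - 2))
  } else {
    sqrt((a$sigma^2 + b$sigma^2) / 2)
  }
  j <- if (have_n) {
    df <- a$n + b$n - 2
    1 - 3 / (4 * df - 1)
  } else {
    1
  }
  g <- j * (a$mu - b$mu) / s_pooled
  variance <- if (have_n) {
    (a$n + b$n) / (a$n * b$n) + g^2 / (2 * (a$n + b$n - 2))
  } else {
    NA_real_
  }
  ci <- if (is.na(variance)) c(NA_real_, NA_real_) else
    g + c(-1, 1) * 1.96 * sqrt(variance)
  structure(
    list(g = g, variance = variance, ci_95 = ci, J = j, pooling = pooling),
    class = "effect_size"
  )
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size> g = %.3f (J = %.3f, %s pooling)",
              x$g, x$J, x$pooling))
  if (!is.na(x$variance)) {
    cat(sprintf(", var = %.4f, 95%% CI [%.3f, %.3f]",
                x$variance, x$ci_95[1], x$ci_95[2]))
  }
  cat("\n")
  invisible(x)
}

#' Inverse-variance pooling of effect sizes
#'
#' Fixed-effect meta-analytic pooling: weights `w_i = 1 / var_i`, pooled
#' `g = sum(w g) / sum(w)`, pooled variance `1 / sum(w)`.
#'
#' @param gs Numeric vector of effect sizes (or a list of `effect_size`
#'   objects, from which `g` and `variance` are taken).
#' @param variances Numeric vector of sampling variances (> 0); ignored when
#'   `gs` is a list of `effect_size` objects.
#' @return An `effect_size` with the pooled estimate, variance, and CI.
#' @export
pool_effects <- function(gs, variances = NULL) {
  if (is.list(gs) && all(vapply(gs, inherits, logical(1), "effect_size"))) {
    variances <- vapply(gs, function(e) e$variance, numeric(1))
    gs <- vapply(gs, function(e) e$g, numeric(1))
  }
  if (length(gs) < 1) stop("need at least one effect")
  if (length(gs) != length(variances)) stop("gs and variances differ in length")
  if (any(!is.finite(variances)) || any(variances <= 0)) {
    stop("all variances must be finite and > 0")
  }
  w <- 1 / variances
  g <- sum(w * gs) / sum(w)
  v <- 1 / sum(w)
  structure(
    list(g = g, variance = v, ci_95 = g + c(-1, 1) * 1.96 * sqrt(v),
         J = NA_real_, pooling = "inverse_variance"),
    class = "effect_size"
  )
}

#' Ratio of group standard deviations
#'
#' @param a,b [stats_from_report()] objects.
#' @return `a$sigma / b$sigma`.
#' @export
sd_ratio <- function(a, b) {
  stopifnot(inherits(a, "group_stats"), inherits(b, "group_stats"))
  if (b$sigma <= 0) stop("denominator SD must be > 0")
  a$sigma / b$sigma
}
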