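#' Generate a synthetic initial-rate enzyme assay
#'
#' Emulates the structure of a coupled spectrophotometric PGK1 assay:
#' initial reaction rates measured across a substrate (ADP) titration, with
#' or without a competitive inhibitor, plus additive homoscedastic Gaussian
#' noise. Noise-free rates follow
#' `vmax * S / (km * (1 + I/ki) + S)` -- a Michaelis-Menten curve whose
#' apparent Km is inflated by the competitive term while the maximal rate is
#' untouched.
#'
#' Units are caller-defined but must be consistent: `substrate` and `km`
#' share one concentration unit, `inhibitor` and `ki` another, and `vmax`
#' sets the rate unit (e.g. NADH absorbance per millisecond).
#'
#' @param vmax True maximal rate.
#' @param km True Michaelis constant (same unit as `substrate`).
#' @param substrate Substrate concentrations; should span sub-Km to supra-Km.
#' @param inhibitor Competitive inhibitor concentration (default 0).
#' @param ki Inhibitor dissociation constant (default `Inf`, no inhibition).
#' @param noise_sd Standard deviation of the additive rate noise (default 0).
#' @param seed Optional integer seed; the same seed reproduces the dataset
#'   exactly and the caller's RNG state is left untouched.
#' @return An `assay_dataset` tibble with columns `substrate` and `rate`;
#'   the generating parameters, noise level and seed are kept as attributes.
#' @examples
#' generate_assay(vmax = 8.5e-7, km = 2.2,
#'                substrate = c(0.5, 1, 2, 4, 8, 16, 32),
#'                noise_sd = 4e-8, seed = 1)
#' @export
generate_assay <- function(vmax, km, substrate, inhibitor = 0, ki = Inf,
                           noise_sd = 0, seed = NULL) {
  stopifnot(vmax > 0, km > 0, ki > 0, inhibitor >= 0, noise_sd >= 0)
  if (any(!is.finite(substrate)) || any(substrate <= 0)) {
    stop("substrate concentrations must be positive and finite", call. = FALSE)
  }
  km_app <- km * (1 + inhibitor / ki)
  mu <- vmax * substrate / (km_app + substrate)
  noise <- if (noise_sd > 0) {
    with_local_seed(seed, stats::rnorm(length(substrate), 0, noise_sd))
  } else {
    numeric(length(substrate))
  }
  out <- tibble::tibble(substrate = substrate, rate = mu + noise)
  structure(out, class = c("assay_dataset", class(out)),
            true_params = list(vmax = vmax, km = km, ki = ki,
                               inhibitor = inhibitor, km_apparent = km_app),
            noise_sd = noise_sd, seed = seed)
}

# Run `expr` under a seeded RNG without disturbing the caller's stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Fit the Michaelis-Menten equation to initial-rate data
#'
#' Direct nonlinear least squares on the hyperbolic form
#' `rate = Vmax * S / (Km + S)` via bounded Levenberg-Marquardt (no
#' double-reciprocal linearisation). Positivity of both constants is
#' enforced through lower bounds. Standard errors are the asymptotic
#' least-squares errors from the fit's variance-covariance estimate.
#'
#' @param data A data frame with columns `substrate` and `rate` (at least 4
#'   distinct substrate concentrations), e.g. from [generate_assay()].
#' @param start Optional named list of starting values (`vmax`, `km`);
#'   defaults are derived from the data (maximal observed rate, substrate
#'   nearest half-maximal rate).
#' @return An `mm_fit` object; use [generics::tidy()] for the coefficient
#'   table, [generics::glance()] for the fit summary, or `coef()`.
#' @examples
#' d <- generate_assay(vmax = 1, km = 2, substrate = c(0.5, 1, 2, 4, 8, 16))
#' coef(fit_mm(d))
#' @export
fit_mm <- function(data, start = NULL) {
  if (!all(c("substrate", "rate") %in% names(data))) {
    stop("data must have 'substrate' and 'rate' columns", call. = FALSE)
  }
  data <- tibble::as_tibble(data[, c("substrate", "rate")])
  if (length(unique(data$substrate)) < 4) {
    stop("need at least 4 distinct substrate concentrations", call. = FALSE)
  }
  if (is.null(start)) {
    vmax0 <- max(data$rate)
    if (vmax0 <= 0) vmax0 <- stats::sd(data$rate) + .Machine$double.eps
    half <- data$substrate[which.min(abs(data$rate - vmax0 / 2))]
    start <- list(vmax = vmax0, km = max(half, min(data$substrate) / 2))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rate ~ vmax * substrate / (km + substrate),
      data = data, start = start,
      lower = c(vmax = .Machine$double.xmin, km = .Machine$double.xmin),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop("Michaelis-Menten fit failed: ", conditionMessage(e),
           "\n  rate range: [", format(min(data$rate)), ", ",
           format(max(data$rate)), "]", call. = FALSE)
    }
  )
  structure(list(fit = fit, data = data), class = "mm_fit")
}

#' @export
coef.mm_fit <- function(object, ...) stats::coef(object$fit)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Coefficient table of a Michaelis-Menten fit
#'
#' @param x An `mm_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.mm_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' One-row summary of a Michaelis-Menten fit
#'
#' @param x An `mm_fit`.
#' @param ... Unused.
#' @return A tibble with residual sum of squares, residual standard error,
#'   convergence flag, iteration count and number of observations.
#' @export
glance.mm_fit <- function(x, ...) {
  ci <- x$fit$convInfo
  tibble::tibble(
    rss = sum(stats::residuals(x$fit)^2),
    sigma = summary(x$fit)$sigma,
    converged = isTRUE(ci$isConv),
    iterations = ci$finIter,
    nobs = nrow(x$data)
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  co <- stats::coef(x$fit)
  cat("<mm_fit> Michaelis-Menten least-squares fit\n")
  cat(sprintf("  Vmax = %.6g, Km = %.6g (n = %d, converged: %s)\n",
              co[["vmax"]], co[["km"]], nrow(x$data),
              isTRUE(x$fit$convInfo$isConv)))
  invisible(x)
}
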