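#' Empirical CDF points
#'
#' One point per distinct value at the middle of its jump: for untied data
#' this is the Hazen plotting position `(i - 0.5)/n` at the i-th order
#' statistic. Mid-jump heights keep the fit invariant under dataset
#' duplication and make symmetric samples fit a symmetric CDF exactly,
#' which top-of-jump heights (`i/n`) do not.
#'
#' @param values numeric vector.
#' @return data.frame `x` (distinct sorted values), `F` (mid-jump heights).
#' @export
ecdf_points <- function(values) {
  n <- length(values)
  r <- rle(sort(values))
  cum <- cumsum(r$lengths)
  data.frame(x = r$values, F = (cum - r$lengths / 2) / n)
}

#' Fit a normal CDF to an empirical distribution
#'
#' Nonlinear least squares of the empirical CDF against
#' `CDF(x) = 1/2 [1 + erf((x - mu) / sqrt(2 sigma^2))]` with free `mu` and
#' `sigma`, initialized at the sample mean and SD. Used for velocity and
#' fluorescence-intensity distributions; the derived mean is `mu`.
#'
#' @param values numeric, n >= 5, finite.
#' @return a `cdf_fit`: `model`, `mu`, `sigma`, `derived_mean`, `n`.
#' @export
fit_normal_cdf <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 5) stop("need at least 5 values", call. = FALSE)
  if (stats::sd(values) == 0) stop("degenerate data: zero variance", call. = FALSE)
  ec <- ecdf_points(values)
  fit <- tryCatch(
    minpack.lm::nlsLM(F ~ stats::pnorm(x, mu, sigma), data = ec,
                      start = list(mu = mean(values), sigma = stats::sd(values)),
                      lower = c(mu = -Inf, sigma = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {       # multi-start fallback
    best <- NULL
    for (f_mu in c(0.8, 1, 1.2)) for (f_s in c(0.5, 1, 2)) {
      cand <- tryCatch(
        minpack.lm::nlsLM(F ~ stats::pnorm(x, mu, sigma), data = ec,
                          start = list(mu = f_mu * mean(values),
                                       sigma = f_s * stats::sd(values)),
                          lower = c(mu = -Inf, sigma = 1e-12)),
        error = function(e) NULL)
      if (!is.null(cand) &&
          (is.null(best) || stats::deviance(cand) < stats::deviance(best)))
        best <- cand
    }
    fit <- best
  }
  if (is.null(fit)) stop("normal CDF fit failed to converge", call. = FALSE)
  p <- stats::coef(fit)
  structure(list(model = "normal", mu = unname(p["mu"]),
                 sigma = unname(p["sigma"]), t = NA_real_, x0 = NA_real_,
                 derived_mean = unname(p["mu"]), n = length(values)),
            class = "cdf_fit")
}

#' Fit a minimum-corrected exponential CDF
#'
#' Values below the minimum `x0` are excluded; the empirical CDF of the
#' remainder is fit by least squares to `CDF(x) = 1 - exp((x0 - x)/t)` with
#' free scale `t`. The derived mean adds the minimum back: `t + x0`. Dwell
#' times use `x0 = 0` (no minimum correction), which reduces exactly to a
#' plain exponential fit.
#'
#' @param values numeric sample.
#' @param x0 minimum (same units as the data); 0.3 um for run lengths by
#'   convention, 0 for dwell times.
#' @return a `cdf_fit`: `model`, `t`, `x0`, `derived_mean = t + x0`, `n`
#'   (values entering the fit).
#' @export
fit_exponential_cdf <- function(values, x0 = 0) {
  values <- values[is.finite(values) & values >= x0]
  if (!length(values)) stop("no values at or above x0", call. = FALSE)
  if (length(values) < 5) stop("need at least 5 values >= x0", call. = FALSE)
  ec <- ecdf_points(values)
  t0 <- max(mean(values) - x0, 1e-9)
  fit <- tryCatch(
    minpack.lm::nlsLM(F ~ 1 - exp((x0 - x) / t), data = ec,
                      start = list(t = t0), lower = c(t = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  t_hat <- if (!is.null(fit)) unname(stats::coef(fit)["t"]) else {
    # 1-parameter problem: golden-section fallback on the LS objective
    obj <- function(t) sum((ec$F - (1 - exp((x0 - ec$x) / t)))^2)
    stats::optimize(obj, c(t0 / 50, t0 * 50))$minimum
  }
  structure(list(model = if (x0 > 0) "exponential_shifted" else "exponential",
                 mu = NA_real_, sigma = NA_real_, t = t_hat, x0 = x0,
                 derived_mean = t_hat + x0, n = length(values)),
            class = "cdf_fit")
}

#' @export
print.cdf_fit <- function(x, ...) {
  cat(sprintf("<cdf_fit> %s: derived mean = %.4g (n = %d)",
              x$model, x$derived_mean, x$n))
  if (!is.null(x$bootstrap_se) && is.finite(x$bootstrap_se))
    cat(sprintf(" +/- %.3g (95%% CI, %d resamples)", x$ci95, x$n_bootstrap))
  cat("\n")
  invisible(x)
}

#' Bootstrap standard error and 95% CI of a CDF-fit mean
#'
#' n-out-of-n resampling with replacement of the raw values; the SD of the
#' derived mean over the resampled fits is the standard error, and the 95%
#' CI is twice the standard error. Deterministic given the seed.
#'
#' @param values the raw sample.
#' @param fitter a function mapping a sample to a `cdf_fit` (e.g.
#'   `fit_normal_cdf` or `function(v) fit_exponential_cdf(v, x0 = 0.3)`).
#' @param n_bootstrap number of resamples (default 200).
#' @param seed RNG seed.
#' @param max_fail_frac error if the fitter fails on more than this fraction
#'   of resamples.
#' @return list `bootstrap_se`, `ci95` (= 2 * SE), `n_bootstrap`, `seed`,
#'   `means` (resampled derived means).
#' @export
bootstrap_ci <- function(values, fitter, n_bootstrap = 200, seed = 1L,
                         max_fail_frac = 0.1) {
  set.seed(as.integer(seed))
  means <- rep(NA_real_, n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    res <- tryCatch(fitter(sample(values, length(values), replace = TRUE)),
                    error = function(e) NULL)
    if (!is.null(res)) means[b] <- res$derived_mean
  }
  n_fail <- sum(is.na(means))
  if (n_fail > max_fail_frac * n_bootstrap)
    stop(sprintf("bootstrap unstable: fitter failed on %d/%d resamples",
                 n_fail, n_bootstrap), call. = FALSE)
  se <- stats::sd(means, na.rm = TRUE)
  list(bootstrap_se = se, ci95 = 2 * se, n_bootstrap = n_bootstrap,
       seed = as.integer(seed), means = means)
}

#' Fit a CDF model with bootstrap errors in one call
#'
#' @param values raw sample.
#' @param model `"normal"` or `"exponential"`.
#' @param x0 minimum correction for the exponential model.
#' @param n_bootstrap,seed bootstrap settings.
#' @return a `cdf_fit` augmented with `bootstrap_se`, `ci95`, `n_bootstrap`,
#'   `seed`.
#' @export
fit_cdf_with_ci <- function(values, model = c("normal", "exponential"),
                            x0 = 0, n_bootstrap = 200, seed = 1L) {
  model <- match.arg(model)
  fitter <- if (model == "normal") fit_normal_cdf else
    function(v) fit_exponential_cdf(v, x0 = x0)
  fit <- fitter(values)
  bs <- bootstrap_ci(values, fitter, n_bootstrap = n_bootstrap, seed = seed)
  fit$bootstrap_se <- bs$bootstrap_se
  fit$ci95 <- bs$ci95
  fit$n_bootstrap <- bs$n_bootstrap
  fit$seed <- bs$seed
  fit
}

#' Histogram with fitted-curve overlay
#'
#' Normalized-count histogram (counts divided by the total number of
#' particles) plus the fitted density evaluated at bin centers and scaled to
#' the histogram mass, for plotting a fit over binned data.
#'
#' @param values raw sample.
#' @param fit a `cdf_fit`.
#' @param bins number of bins or a vector of breaks.
#' @return data.frame `bin_left`, `bin_right`, `bin_center`,
#'   `normalized_count`, `overlay`.
#' @export
summarize_with_overlay <- function(values, fit, bins = 20) {
  breaks <- if (length(bins) == 1)
    seq(min(values), max(values), length.out = bins + 1) else bins
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  centers <- (utils::head(breaks, -1) + utils::tail(breaks, -1)) / 2
  widths <- diff(breaks)
  dens <- switch(fit$model,
                 normal = stats::dnorm(centers, fit$mu, fit$sigma),
                 exponential = ,
                 exponential_shifted = ifelse(
                   centers < fit$x0, 0,
                   exp((fit$x0 - centers) / fit$t) / fit$t))
  norm_counts <- h$counts / length(values)
  overlay <- dens * widths
  mass <- sum(norm_counts)
  if (sum(overlay) > 0) overlay <- overlay * mass / sum(overlay)
  data.frame(bin_left = utils::head(breaks, -1),
             bin_right = utils::tail(breaks, -1),
             bin_center = centers,
             normalized_count = norm_counts,
             overlay = overlay)
}
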