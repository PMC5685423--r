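#' 4AFC logistic psychometric function
#'
#' Probability of a correct response as a function of gap size:
#' `p(correct) = 0.25 + 0.75 / (1 + exp((mu - x) / sigma))`,
#' rising from the 25% guess floor to 1, with size threshold `mu`
#' (the 62.5%-correct point) and slope parameter `sigma`.
#'
#' @param x gap size(s), arcmin.
#' @param mu size threshold, arcmin.
#' @param sigma slope parameter, arcmin (> 0).
#' @return probabilities in (0.25, 1).
#' @export
#' @examples
#' psychometric_p(8, mu = 8, sigma = 2) # 0.625
psychometric_p <- function(x, mu, sigma) {
  if (!is.numeric(sigma) || any(sigma <= 0))
    stop("sigma must be positive")
  0.25 + 0.75 / (1 + exp((mu - x) / sigma))
}

# Aggregate trial data to (x, n, k) per gap level; accepts a trials tibble
# (gap_arcmin/correct), a data.frame with gap/correct, or an aggregate.
aggregate_trials <- function(trials) {
  if (is.data.frame(trials) && all(c("x", "n", "k") %in% names(trials)))
    return(trials)
  gap <- if ("gap_arcmin" %in% names(trials)) trials$gap_arcmin
         else trials$gap
  correct <- trials$correct
  if (is.null(gap) || is.null(correct))
    stop("trials must have gap (or gap_arcmin) and correct columns")
  x <- sort(unique(gap))
  data.frame(
    x = x,
    n = vapply(x, function(v) sum(gap == v), numeric(1)),
    k = vapply(x, function(v) sum(correct[gap == v]), numeric(1))
  )
}

# Negative Bernoulli log-likelihood on aggregated data.
nll_psychometric <- function(mu, sigma, agg) {
  p <- psychometric_p(agg$x, mu, sigma)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(agg$k * log(p) + (agg$n - agg$k) * log(1 - p))
}

# Nelder-Mead refinement on (mu, log sigma) from a given start.
refine_fit <- function(agg, mu0, sigma0) {
  obj <- function(par) nll_psychometric(par[1], exp(par[2]), agg)
  stats::optim(c(mu0, log(sigma0)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-10, maxit = 1000))
}

#' Maximum-likelihood psychometric fit
#'
#' Fits `(mu, sigma)` of the 4AFC logistic by maximizing the Bernoulli
#' log-likelihood of the pooled trials. Optimization is a coarse grid
#' initialization over `mu` in \[1, 30\] arcmin x `sigma` in \[0.1, 10\]
#' (log-spaced), followed by Nelder-Mead refinement on `(mu, log sigma)`;
#' the result is deterministic given the data. Fits whose threshold or
#' slope lands far outside the grid are flagged as boundary solutions.
#'
#' @param trials a trial-record tibble (columns `gap_arcmin`/`gap` and
#'   `correct`) or an aggregated data frame with columns `x`, `n`, `k`.
#' @param mu_grid,sigma_grid initialization grids.
#' @return an object of class `psychometric_fit`: `mu`, `sigma`,
#'   `log_likelihood`, `n_trials`, `boundary`, `ci_mu` (`NA` until
#'   [bootstrap_ci()] is run).
#' @export
fit_ml <- function(trials, mu_grid = seq(1, 30, length.out = 30),
                   sigma_grid = exp(seq(log(0.1), log(10), length.out = 21))) {
  agg <- aggregate_trials(trials)
  if (nrow(agg) < 2)
    stop("need at least 2 distinct gap levels")
  n_tot <- sum(agg$n)
  k_tot <- sum(agg$k)
  if (k_tot == n_tot || k_tot == 0)
    stop(sprintf(
      "non-identifiable: all %d trials %s; threshold unconstrained",
      n_tot, if (k_tot == 0) "incorrect" else "correct"))
  # vectorized grid evaluation: levels x grid-points in one shot
  grid <- expand.grid(mu = mu_grid, sigma = sigma_grid)
  Z <- outer(-agg$x, grid$mu, "+") /
    matrix(grid$sigma, nrow(agg), nrow(grid), byrow = TRUE)
  P <- pmin(pmax(0.25 + 0.75 / (1 + exp(Z)), 1e-12), 1 - 1e-12)
  nl <- -(colSums(agg$k * log(P)) + colSums((agg$n - agg$k) * log(1 - P)))
  best <- grid[which.min(nl), ]
  opt <- refine_fit(agg, best$mu, best$sigma)
  mu <- opt$par[1]
  sigma <- exp(opt$par[2])
  boundary <- mu < min(agg$x) - 10 * sigma || mu > max(agg$x) + 10 * sigma ||
    sigma < 1e-3 || sigma > 1e3
  structure(
    list(mu = mu, sigma = sigma, log_likelihood = -opt$value,
         n_trials = n_tot, boundary = boundary,
         ci_mu = c(NA_real_, NA_real_), n_boot = 0L, seed = NA_integer_,
         data = agg),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> mu = %.3f arcmin, sigma = %.3f arcmin (n = %d, logLik = %.2f)%s\n",
    x$mu, x$sigma, x$n_trials, x$log_likelihood,
    if (x$boundary) " [boundary]" else ""))
  if (!any(is.na(x$ci_mu)))
    cat(sprintf("  95%% CI for mu: [%.3f, %.3f] (%d bootstrap resamples)\n",
                x$ci_mu[1], x$ci_mu[2], x$n_boot))
  invisible(x)
}

#' Nonparametric bootstrap confidence interval for the threshold
#'
#' Resamples trials with replacement (same n), refits, and takes the 2.5th
#' and 97.5th percentiles of the bootstrap distribution of `mu`. Resampling
#' treats the trial as the exchangeable unit. Failed refits (degenerate
#' resamples) are dropped; more than 20% failures raises an error.
#'
#' @param trials trial records as in [fit_ml()].
#' @param n_boot number of bootstrap resamples (>= 1).
#' @param seed integer seed; same seed gives an identical interval.
#' @return a `psychometric_fit` for the original data with `ci_mu` filled
#'   in, `n_boot` and the number of dropped refits in `n_failed`.
#' @export
bootstrap_ci <- function(trials, n_boot = 1000, seed = 1L) {
  if (!is.numeric(n_boot) || n_boot < 1)
    stop("n_boot must be >= 1")
  n_boot <- as.integer(n_boot)
  fit <- fit_ml(trials) # errors propagate if the base fit fails
  agg <- fit$data
  n <- sum(agg$n)
  nlev <- nrow(agg)
  # expand to per-trial (level, correct) for trial-level resampling
  lev_all <- rep(seq_len(nlev), agg$n)
  c_all <- unlist(mapply(function(k, n) c(rep(TRUE, k), rep(FALSE, n - k)),
                         agg$k, agg$n, SIMPLIFY = FALSE))
  mus <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      lv <- lev_all[idx]
      bagg <- data.frame(x = agg$x,
                         n = tabulate(lv, nlev),
                         k = tabulate(lv[c_all[idx]], nlev))
      bagg <- bagg[bagg$n > 0, ]
      kt <- sum(bagg$k)
      if (nrow(bagg) < 2 || kt == 0 || kt == sum(bagg$n))
        return(NA_real_) # degenerate resample
      # refit warm-started from the original fit (deterministic)
      opt <- tryCatch(refine_fit(bagg, fit$mu, fit$sigma),
                      error = function(e) NULL)
      if (is.null(opt)) NA_real_ else opt$par[1]
    }, numeric(1))
  })
  n_failed <- sum(is.na(mus))
  if (n_failed > 0.2 * n_boot)
    stop(sprintf("unstable fit: %d of %d bootstrap refits failed",
                 n_failed, n_boot))
  fit$ci_mu <- unname(stats::quantile(mus, c(0.025, 0.975), na.rm = TRUE))
  fit$n_boot <- n_boot
  fit$n_failed <- n_failed
  fit$seed <- as.integer(seed)
  fit
}

#' Synthetic trial records from a known psychometric function
#'
#' Generates per-trial 4AFC correct/incorrect outcomes whose accuracy
#' follows the logistic psychometric function exactly — the synthetic
#' stand-in for what a human run produces, used for parameter-recovery and
#' coverage checks.
#'
#' @param x vector of gap sizes (arcmin), one per trial (use `rep()` for
#'   multiple trials per level).
#' @param mu,sigma true psychometric parameters.
#' @param seed integer seed.
#' @return a tibble with columns `gap_arcmin` and `correct`.
#' @export
simulate_logistic_trials <- function(x, mu, sigma, seed) {
  p <- psychometric_p(x, mu, sigma)
  correct <- with_seed(seed, runif(length(x)) < p)
  tibble::tibble(gap_arcmin = x, correct = correct)
}

#' Logistic responder for staircase simulations
#'
#' Returns a `function(gap, seed)` whose probability of a correct response
#' at each gap follows [psychometric_p()] with the given parameters;
#' responses are reproducible from the per-trial seed.
#'
#' @param mu,sigma psychometric parameters.
#' @return a responder function for [run_staircase()].
#' @export
make_logistic_responder <- function(mu, sigma) {
  force(mu); force(sigma)
  function(gap, seed) {
    with_seed(seed, runif(1)) < psychometric_p(gap, mu, sigma)
  }
}

#' Write a psychometric fit as JSON
#'
#' Serializes the fitted threshold and slope with their context
#' (subject, condition, density, CI, trial and bootstrap counts).
#'
#' @param fit a `psychometric_fit`.
#' @param path output file path.
#' @param subject,condition,density labels recorded alongside the fit.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, subject = NA, condition = NA,
                           density = NA) {
  stopifnot(inherits(fit, "psychometric_fit"))
  jsonlite::write_json(
    list(subject = subject, condition = condition, density = density,
         mu = fit$mu, sigma = fit$sigma, ci_mu = fit$ci_mu,
         n_trials = fit$n_trials, n_boot = fit$n_boot, seed = fit$seed),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
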