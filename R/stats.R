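#' Student's t test with degenerate-input guards
#'
#' Thin wrapper around [stats::t.test()] defaulting to the
#' pooled-variance (equal-variance) two-sample form, with explicit
#' handling of zero-variance inputs: equal means with no variance give
#' `t = 0, p = 1`; unequal means with no variance give `p = 0` flagged
#' `degenerate`.
#'
#' @param x,y numeric samples (length >= 2; equal lengths when paired).
#' @param paired paired test on differences.
#' @param welch use Welch's unequal-variance form (unpaired only).
#' @return list with `t`, `df`, `p`, `degenerate`.
#' @export
t_test <- function(x, y, paired = FALSE, welch = FALSE) {
  if (paired && length(x) != length(y))
    abort_clampresp("paired test needs equal-length samples", "format_error")
  if (length(x) < 2L || length(y) < 2L)
    abort_clampresp("each sample needs at least two values", "format_error")
  no_var <- if (paired) stats::sd(x - y) == 0 else
    stats::sd(x) == 0 && stats::sd(y) == 0
  if (no_var) {
    d <- mean(x) - mean(y)
    n <- if (paired) length(x) - 1L else length(x) + length(y) - 2L
    if (d == 0) return(list(t = 0, df = n, p = 1, degenerate = FALSE))
    return(list(t = sign(d) * Inf, df = n, p = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = paired, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Bonferroni correction
#'
#' @param p vector of p values in `[0, 1]`.
#' @return `min(1, p * length(p))` elementwise.
#' @export
bonferroni <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    abort_clampresp("p values must lie in [0, 1]", "domain_error")
  stats::p.adjust(p, method = "bonferroni")
}

perm_stat <- function(statistic) {
  switch(statistic,
         mean_diff = function(a, b) mean(a) - mean(b),
         sd_diff = function(a, b) stats::sd(a) - stats::sd(b))
}

#' Permutation test on the difference of group means or SDs
#'
#' Observed statistic is `stat(x) - stat(y)` (sample-SD denominator
#' `n - 1` for `sd_diff`). The null is built by reassigning the pooled
#' values to groups of the original sizes: exhaustively over all
#' `choose(nx+ny, nx)` assignments when that count is at most
#' `exhaustive_limit`, otherwise by Monte Carlo with the add-one
#' correction `p = (1 + #extreme) / (1 + n_perm)` so p is never 0.
#' Two-tailed tests use `|stat| >= |observed|`; one-tailed tests take the
#' tail in the direction of the observed statistic.
#'
#' @param x,y numeric samples (length >= 2).
#' @param statistic `"mean_diff"` or `"sd_diff"`.
#' @param tails `"two"` or `"one"`.
#' @param n_perm Monte Carlo permutation count.
#' @param seed integer seed for the Monte Carlo branch.
#' @param exhaustive_limit max number of assignments enumerated exactly.
#' @return object of class `perm_result` with `statistic`, `observed`,
#'   `tails`, `n_perm` (`"exhaustive"` or the count), `p_value`, `seed`.
#' @export
permutation_test <- function(x, y, statistic = c("mean_diff", "sd_diff"),
                             tails = c("two", "one"), n_perm = 10000,
                             seed = NULL, exhaustive_limit = 200000) {
  statistic <- match.arg(statistic)
  tails <- match.arg(tails)
  if (length(x) < 2L || length(y) < 2L)
    abort_clampresp("each group needs at least two values", "format_error")
  f <- perm_stat(statistic)
  observed <- f(x, y)
  pool <- c(x, y)
  n <- length(pool)
  nx <- length(x)
  eps <- 1e-12
  extreme <- function(d) {
    if (tails == "two") abs(d) >= abs(observed) - eps
    else if (observed >= 0) d >= observed - eps else d <= observed + eps
  }
  if (choose(n, nx) <= exhaustive_limit) {
    idx <- utils::combn(n, nx)
    d <- vapply(seq_len(ncol(idx)), function(j) {
      f(pool[idx[, j]], pool[-idx[, j]])
    }, numeric(1))
    p <- mean(extreme(d))
    n_perm_out <- "exhaustive"
  } else {
    d <- with_seed_if(seed, vapply(seq_len(n_perm), function(j) {
      take <- sample.int(n, nx)
      f(pool[take], pool[-take])
    }, numeric(1)))
    p <- (1 + sum(extreme(d))) / (1 + n_perm)
    n_perm_out <- n_perm
  }
  structure(list(statistic = statistic, observed = observed, tails = tails,
                 n_perm = n_perm_out, p_value = p, seed = seed),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result> %s = %.4g, %s-tailed, %s permutations, p = %.4g\n",
              x$statistic, x$observed, x$tails,
              format(x$n_perm), x$p_value))
  invisible(x)
}

#' Fit the Hill equation to concentration-response data
#'
#' Least-squares fit of `R(c) = Emax * c^n / (EC50^n + c^n)` with the
#' zero-concentration baseline fixed at 0 (effects are
#' baseline-subtracted by construction). The Hill coefficient is fitted
#' freely within `[0.2, 5]` unless fixed via `fix_hill_n`. The fit is
#' multi-started over log-spaced EC50 initial values spanning the tested
#' concentration range; the converged start with the lowest residual sum
#' of squares wins.
#'
#' @param conc_nM concentrations (nM, > 0); at least 3 distinct values.
#' @param response_pA responses (pA, outward positive).
#' @param fix_hill_n fix the Hill coefficient at this value (e.g. 1);
#'   `NULL` fits it.
#' @param n_starts number of EC50 initial values.
#' @return object of class `hill_fit`: `ec50_nM`, `emax_pA`, `hill_n`,
#'   `residual_ss`, `se_ec50` (from the fit covariance), `converged`.
#' @export
fit_hill <- function(conc_nM, response_pA, fix_hill_n = NULL, n_starts = 7) {
  if (any(conc_nM <= 0))
    abort_clampresp("concentrations must be > 0 nM", "domain_error")
  if (length(unique(conc_nM)) < 3L)
    abort_clampresp("need at least three distinct concentrations", "format_error")
  stopifnot(length(conc_nM) == length(response_pA))
  dat <- data.frame(conc = conc_nM, r = response_pA)
  ec50_grid <- 10^seq(log10(min(conc_nM)), log10(max(conc_nM)),
                      length.out = n_starts)
  emax0 <- response_pA[which.max(abs(response_pA))]
  best <- NULL
  for (ec0 in ec50_grid) {
    fit <- tryCatch({
      if (is.null(fix_hill_n)) {
        minpack.lm::nlsLM(r ~ emax * conc^n / (ec50^n + conc^n), data = dat,
                          start = list(emax = emax0, ec50 = ec0, n = 1),
                          lower = c(emax = -Inf, ec50 = 1e-9, n = 0.2),
                          upper = c(emax = Inf, ec50 = Inf, n = 5),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        n_fix <- fix_hill_n
        minpack.lm::nlsLM(r ~ emax * conc^n_fix / (ec50^n_fix + conc^n_fix),
                          data = dat,
                          start = list(emax = emax0, ec50 = ec0),
                          lower = c(emax = -Inf, ec50 = 1e-9),
                          upper = c(emax = Inf, ec50 = Inf),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      ss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || ss < best$ss - 1e-12) best <- list(fit = fit, ss = ss)
    }
  }
  if (is.null(best))
    return(structure(list(ec50_nM = NA_real_, emax_pA = NA_real_,
                          hill_n = fix_hill_n %||% NA_real_,
                          residual_ss = NA_real_, se_ec50 = NA_real_,
                          converged = FALSE), class = "hill_fit"))
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  structure(list(ec50_nM = unname(cf["ec50"]), emax_pA = unname(cf["emax"]),
                 hill_n = if (is.null(fix_hill_n)) unname(cf["n"]) else fix_hill_n,
                 residual_ss = best$ss,
                 se_ec50 = if (is.null(se)) NA_real_ else unname(se["ec50"]),
                 converged = TRUE),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> EC50 = %.3g nM (SE %.3g), Emax = %.3g pA, n = %.3g, SS = %.3g%s\n",
              x$ec50_nM, x$se_ec50, x$emax_pA, x$hill_n, x$residual_ss,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Predict from a Hill fit
#'
#' @param object a [fit_hill()] result.
#' @param conc_nM concentrations to evaluate.
#' @param ... unused.
#' @return predicted responses (pA).
#' @export
predict.hill_fit <- function(object, conc_nM, ...) {
  object$emax_pA * hill_factor(conc_nM, object$ec50_nM, object$hill_n)
}

#' Kernel density curve with Scott-factor bandwidth
#'
#' Gaussian-kernel density on an even grid spanning the data range plus
#' three bandwidths on each side. The bandwidth is the Scott factor
#' `n^(-1/5)` (overridable) times the sample SD. The returned curve is
#' renormalized to integrate (trapezoid rule) to exactly 1, the
#' equal-area convention used when several violins are drawn together.
#'
#' @param values numeric sample, length >= 2, SD > 0.
#' @param scott_factor_override replace the `n^(-1/5)` factor.
#' @param n_grid grid resolution.
#' @return object of class `density_curve`: `x` (support grid),
#'   `density`, `bandwidth`, `normalization = "equal_area"`.
#' @export
kde_violin <- function(values, scott_factor_override = NULL, n_grid = 512) {
  if (length(values) < 2L)
    abort_clampresp("need at least two values", "format_error")
  s <- stats::sd(values)
  if (s == 0)
    abort_clampresp("zero-SD sample: degenerate distribution", "domain_error")
  factor <- scott_factor_override %||% length(values)^(-1 / 5)
  bw <- factor * s
  d <- stats::density(values, bw = bw, kernel = "gaussian",
                      from = min(values) - 3 * bw, to = max(values) + 3 * bw,
                      n = n_grid)
  area <- trapz(d$x, d$y)
  structure(list(x = d$x, density = d$y / area, bandwidth = bw,
                 normalization = "equal_area"),
            class = "density_curve")
}
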