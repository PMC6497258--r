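# Maximum-likelihood calibration of growth-curve models against summary-
# statistic data, and AIC-based selection with a nonnegativity feasibility
# screen.
#
# The calibration input is a table of (covariate, mean, sd, n) records: a
# per-age (or per-mass) sample mean m_i and sample standard deviation s_i
# from n_i subjects.  Each record is treated as n_i Gaussian observations
# with mean y(x_i; theta) and known variance s_i^2, for which (m_i, s_i)
# are sufficient, giving the per-record log-likelihood contribution
#
#   -(n_i/2) log(2 pi s_i^2) - [(n_i - 1) s_i^2 + n_i (m_i - y_i)^2] / (2 s_i^2).
#
# Only the quadratic term depends on theta, so the MLE coincides with
# weighted least squares with weights n_i / s_i^2; the theta-free terms are
# kept so that log-likelihood magnitudes scale with the total number of
# subjects.  Records missing sd or n are imputed with a 20% coefficient of
# variation and a sample size of one (the convention used for observations
# digitized from published figures).

#' Construct a summary-statistic dataset
#'
#' @param covariate Numeric vector of gestational ages (weeks) or body
#'   masses.
#' @param mean Numeric vector of sample means.
#' @param sd Numeric vector of sample standard deviations; `NA` where
#'   unavailable.
#' @param n Integer vector of sample sizes; `NA` where unavailable.
#' @param covariate_kind `"age_weeks"` or `"body_mass"`.
#' @param label Optional quantity label.
#' @param units Optional units string.
#' @return A data.frame of class `"summary_dataset"` with columns
#'   `covariate`, `mean`, `sd`, `n`, `imputed_sd`, `imputed_n`.
#' @export
summary_dataset <- function(covariate, mean, sd = NA_real_, n = NA_integer_,
                            covariate_kind = c("age_weeks", "body_mass"),
                            label = NULL, units = NULL) {
  covariate_kind <- match.arg(covariate_kind)
  d <- data.frame(covariate = as.numeric(covariate),
                  mean = as.numeric(mean),
                  sd = as.numeric(rep_len(sd, length(covariate))),
                  n = as.integer(rep_len(n, length(covariate))),
                  imputed_sd = FALSE, imputed_n = FALSE)
  if (any(!is.finite(d$covariate)))
    stop("covariates must be finite", call. = FALSE)
  if (any(!is.na(d$sd) & d$sd < 0))
    stop("standard deviations must be nonnegative", call. = FALSE)
  if (any(!is.na(d$n) & d$n < 1))
    stop("sample sizes must be at least 1", call. = FALSE)
  structure(d, covariate_kind = covariate_kind, label = label, units = units,
            class = c("summary_dataset", "data.frame"))
}

#' Impute missing standard deviations and sample sizes
#'
#' Missing standard deviations are replaced by `cv * |mean|` (default 20%
#' coefficient of variation) and missing sample sizes by one, mirroring the
#' treatment of data points digitized from figures.  Records with a zero
#' mean and no reported standard deviation cannot enter a Gaussian
#' likelihood and are rejected.
#'
#' @param dataset A [summary_dataset()].
#' @param cv Coefficient of variation for imputed standard deviations.
#' @return The dataset with `sd`/`n` filled in and imputation flags set.
#' @export
impute_summary <- function(dataset, cv = 0.2) {
  stopifnot(inherits(dataset, "summary_dataset"))
  miss_sd <- is.na(dataset$sd)
  if (any(miss_sd & dataset$mean == 0))
    stop("cannot impute a standard deviation for a zero mean: ",
         "the implied variance is degenerate", call. = FALSE)
  dataset$sd[miss_sd] <- cv * abs(dataset$mean[miss_sd])
  dataset$imputed_sd <- dataset$imputed_sd | miss_sd
  miss_n <- is.na(dataset$n)
  dataset$n[miss_n] <- 1L
  dataset$imputed_n <- dataset$imputed_n | miss_n
  dataset
}

.assert_imputed <- function(dataset) {
  if (anyNA(dataset$sd) || anyNA(dataset$n))
    stop("dataset has missing sd or n; run impute_summary() first",
         call. = FALSE)
  if (any(dataset$sd <= 0))
    stop("degenerate variance: all standard deviations must be positive",
         call. = FALSE)
}

#' Summary-data Gaussian log-likelihood
#'
#' Log-likelihood of a model specification against an imputed summary
#' dataset, treating each record as `n_i` observations with sample mean
#' `m_i` and sample standard deviation `s_i` under a Gaussian with mean
#' `y(x_i; theta)` and known variance `s_i^2`.
#'
#' @param spec A [model_spec()].
#' @param dataset An imputed [summary_dataset()].
#' @return The log-likelihood (scalar).
#' @export
summary_loglik <- function(spec, dataset) {
  stopifnot(inherits(dataset, "summary_dataset"))
  .assert_imputed(dataset)
  y <- evaluate_model(spec, dataset$covariate)
  if (any(!is.finite(y))) return(-Inf)
  s2 <- dataset$sd^2
  nn <- dataset$n
  sum(-(nn / 2) * log(2 * pi * s2) -
        ((nn - 1) * s2 + nn * (dataset$mean - y)^2) / (2 * s2))
}

# ---- starting-value heuristics -------------------------------------------

.wls_poly <- function(x, m, w, degree, intercept) {
  X <- outer(x, seq_len(degree), `^`)
  if (intercept) X <- cbind(1, X)
  as.numeric(stats::lm.wfit(X, m, w)$coefficients)
}

# Gompertz on the log scale: log y = log th0 + (th1/th2)(1 - exp(-th2 x)).
# Profile over th2 on a coarse grid, solving the remaining linear problem.
.init_gompertz <- function(x, m, w) {
  ok <- m > 0
  if (sum(ok) < 3) return(c(max(mean(m), 1e-3), 0.5, 0.1))
  lx <- x[ok]; lm_ <- log(m[ok]); lw <- w[ok]
  best <- NULL; best_sse <- Inf
  for (r in exp(seq(log(0.005), log(0.6), length.out = 40))) {
    z <- 1 - exp(-r * lx)
    fit <- stats::lm.wfit(cbind(1, z), lm_, lw)
    sse <- sum(lw * fit$residuals^2)
    if (is.finite(sse) && sse < best_sse) {
      best_sse <- sse
      best <- c(exp(fit$coefficients[1]), fit$coefficients[2] * r, r)
    }
  }
  if (is.null(best)) c(max(mean(m), 1e-3), 0.5, 0.1) else best
}

.init_logistic <- function(x, m, w) {
  th0 <- 1.05 * max(m)
  p <- pmin(pmax(m / th0, 0.01), 0.99)
  fit <- stats::lm.wfit(cbind(1, x), stats::qlogis(p), w)
  th1 <- max(fit$coefficients[2], 1e-3)
  th2 <- -fit$coefficients[1] / th1
  c(th0, th1, th2)
}

.init_power <- function(x, m, w) {
  ok <- x > 0 & m > 0
  if (sum(ok) < 2) return(c(max(mean(m), 1e-3), 1))
  fit <- stats::lm.wfit(cbind(1, log(x[ok])), log(m[ok]), w[ok])
  c(exp(fit$coefficients[1]), fit$coefficients[2])
}

.init_luecke <- function(x, m, w) {
  ok <- x > 0 & m > 0
  if (sum(ok) < 3) return(c(max(mean(m), 1e-3), 1, 0))
  lx <- log(x[ok])
  fit <- stats::lm.wfit(cbind(1, lx, lx^2), log(m[ok]), w[ok])
  c(exp(fit$coefficients[1]), fit$coefficients[2], fit$coefficients[3])
}

# Heuristic initial parameter vector for a family given data (x, m, w).
# Modified families peel off a baseline (the smallest mean) first.
.heuristic_init <- function(family, x, m, w) {
  offset_init <- function(base_fn, m) {
    off <- min(m) - 0.05 * abs(min(m)) - 1e-6
    c(base_fn(x, pmax(m - off, 1e-8), w), off)
  }
  switch(family,
    linear           = .wls_poly(x, m, w, 1, TRUE),
    linear_growth    = .wls_poly(x, m, w, 1, FALSE),
    quadratic        = .wls_poly(x, m, w, 2, TRUE),
    quadratic_growth = .wls_poly(x, m, w, 2, FALSE),
    cubic            = .wls_poly(x, m, w, 3, TRUE),
    cubic_growth     = .wls_poly(x, m, w, 3, FALSE),
    gompertz          = .init_gompertz(x, m, w),
    modified_gompertz = offset_init(.init_gompertz, m),
    logistic          = .init_logistic(x, m, w),
    modified_logistic = offset_init(.init_logistic, m),
    power_law          = .init_power(x, m, w),
    modified_power_law = offset_init(.init_power, m),
    luecke_power_law          = .init_luecke(x, m, w),
    modified_luecke_power_law = offset_init(.init_luecke, m))
}

# Polynomial-type families are linear in theta: the weighted least-squares
# solution IS the MLE and no iterative search is needed.
.linear_families <- c("linear", "linear_growth", "quadratic",
                      "quadratic_growth", "cubic", "cubic_growth")

#' Fit a model family by maximum likelihood
#'
#' Maximizes [summary_loglik()] over the family's parameters.  Families
#' that are linear in their parameters are solved exactly by weighted least
#' squares.  Nonlinear families use multi-start local optimization:
#' a family-specific heuristic start plus Latin-hypercube perturbations of
#' it, each refined by Nelder-Mead and polished by BFGS; the best final
#' value wins.  All randomness derives from `seed`, so fits are
#' reproducible.
#'
#' @param family A family id (see [model_families()]).
#' @param dataset A [summary_dataset()]; imputed automatically if needed.
#' @param seed Integer seed for the multi-start perturbations.
#' @param n_starts Number of optimizer starts (default 20).
#' @param covariate_kind Covariate kind recorded in the result; defaults to
#'   the dataset's.
#' @return An object of class `"fit_result"`: list with `spec` (the fitted
#'   [model_spec()]), `loglik`, `k`, `aic`, `converged`, `n_starts`,
#'   `seed`.
#' @export
fit_mle <- function(family, dataset, seed = 1L, n_starts = 20L,
                    covariate_kind = NULL) {
  family <- match.arg(family, model_families())
  stopifnot(inherits(dataset, "summary_dataset"))
  if (anyNA(dataset$sd) || anyNA(dataset$n))
    dataset <- impute_summary(dataset)
  .assert_imputed(dataset)
  k <- .family_defs[[family]]$k
  if (nrow(dataset) <= k)
    stop(sprintf("need more than %d data points to fit '%s'", k, family),
         call. = FALSE)
  if (is.null(covariate_kind))
    covariate_kind <- attr(dataset, "covariate_kind")

  x <- dataset$covariate
  m <- dataset$mean
  w <- dataset$n / dataset$sd^2

  nll <- function(theta) {
    sp <- structure(list(family = family, theta = theta,
                         covariate = covariate_kind), class = "model_spec")
    ll <- tryCatch(summary_loglik(sp, dataset), error = function(e) -Inf)
    if (!is.finite(ll)) 1e12 else -ll
  }

  init <- .heuristic_init(family, x, m, w)
  converged <- TRUE

  if (family %in% .linear_families) {
    theta_hat <- init
  } else {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    # Latin-hypercube perturbations around the heuristic start: scale
    # parameters jittered multiplicatively, location/offset parameters
    # additively on the data scale
    u <- lhs::randomLHS(max(n_starts - 1L, 0L), k)
    starts <- c(list(init), lapply(seq_len(nrow(u)), function(i) {
      fac <- exp((u[i, ] - 0.5) * 2)          # in [e^-1, e^1]
      add <- (u[i, ] - 0.5) * stats::sd(m)
      ifelse(abs(init) > 1e-8, init * fac, add)
    }))
    best <- NULL
    for (st in starts) {
      o <- tryCatch(stats::optim(st, nll, method = "Nelder-Mead",
                                 control = list(maxit = 2000)),
                    error = function(e) NULL)
      if (is.null(o)) next
      o2 <- tryCatch(stats::optim(o$par, nll, method = "BFGS",
                                  control = list(maxit = 500)),
                     error = function(e) o)
      cand <- if (!is.null(o2) && o2$value <= o$value) o2 else o
      if (is.null(best) || cand$value < best$value) best <- cand
    }
    if (is.null(best) || !is.finite(best$value) || best$value >= 1e12) {
      theta_hat <- init
      converged <- FALSE
    } else {
      theta_hat <- best$par
      converged <- best$convergence == 0
    }
  }

  spec <- model_spec(family, theta_hat, covariate = covariate_kind)
  ll <- summary_loglik(spec, dataset)
  structure(list(spec = spec, loglik = ll, k = k, aic = 2 * k - 2 * ll,
                 converged = converged, n_starts = as.integer(n_starts),
                 seed = as.integer(seed)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s  logLik = %.4f  k = %d  AIC = %.4f%s\n",
              x$spec$family, x$loglik, x$k, x$aic,
              if (x$converged) "" else "  (NOT converged)"))
  cat("  theta =", paste(signif(x$spec$theta, 6), collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.fit_result <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' Akaike information criterion of a fit
#'
#' Exactly `2k - 2 * loglik`; the same value the standard [stats::AIC()]
#' generic returns through the `logLik` method.
#'
#' @param fit A `"fit_result"`.
#' @return The AIC (scalar).
#' @export
aic_score <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  2 * fit$k - 2 * fit$loglik
}

#' Select a preferred model by AIC with a nonnegativity screen
#'
#' Ranks converged fits by AIC and returns as preferred the lowest-AIC fit
#' whose predictions are nonnegative over the screening interval (the
#' quantities modelled here are masses, volumes, flows and percentages,
#' which cannot be negative).  Fits whose AIC lies within `delta_aic_tol`
#' of one another are treated as statistically indistinguishable, and the
#' tie is broken by preferring (in order) nonnegative fits, fewer
#' parameters, and an age-based over a mass-based covariate.
#'
#' @param fits List of `"fit_result"` objects.
#' @param lower,upper,step Screening grid in gestational weeks, passed to
#'   [feasibility_screen()].
#' @param delta_aic_tol AIC difference below which two fits are considered
#'   tied (default 0.1).
#' @return An object of class `"selection_report"`: list with `ranked`
#'   (fits ordered by AIC), `screened_out` (data.frame of infeasible
#'   families and their first violation), `preferred` (family id),
#'   `preferred_fit`, and `rationale` (`"lowest_aic"`,
#'   `"lowest_nonneg_aic"` or `"tiebreak"`).
#' @export
select_model <- function(fits, lower = 0, upper = 42, step = 0.1,
                         delta_aic_tol = 0.1) {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "fit_result")))
  fits <- Filter(function(f) f$converged, fits)
  if (!length(fits))
    stop("no converged fits to select from", call. = FALSE)
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  ord <- order(aics)
  fits <- fits[ord]; aics <- aics[ord]

  screens <- lapply(fits, function(f)
    feasibility_screen(f$spec, lower = lower, upper = upper, step = step))
  feasible <- vapply(screens, `[[`, logical(1), "nonnegative")
  screened_out <- data.frame(
    family = vapply(fits[!feasible], function(f) f$spec$family, character(1)),
    aic = aics[!feasible],
    first_violation = vapply(screens[!feasible], `[[`, numeric(1),
                             "first_violation"))
  if (!any(feasible))
    stop("all candidate models produce negative values on the screening ",
         "interval; no feasible model", call. = FALSE)

  best_feasible <- which(feasible)[1]
  rationale <- if (best_feasible == 1) "lowest_aic" else "lowest_nonneg_aic"

  # tie handling among feasible fits near the chosen AIC
  tied <- which(feasible & abs(aics - aics[best_feasible]) < delta_aic_tol)
  if (length(tied) > 1) {
    key <- vapply(tied, function(i)
      fits[[i]]$k * 10 + (fits[[i]]$spec$covariate != "age_weeks"),
      numeric(1))
    pick <- tied[order(key)][1]
    if (pick != best_feasible) rationale <- "tiebreak"
    best_feasible <- pick
  }

  structure(list(ranked = fits, screened_out = screened_out,
                 preferred = fits[[best_feasible]]$spec$family,
                 preferred_fit = fits[[best_feasible]],
                 rationale = rationale),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n  preferred:", x$preferred,
      sprintf("(%s)\n", x$rationale))
  for (f in x$ranked)
    cat(sprintf("  %-26s AIC = %.3f\n", f$spec$family, f$aic))
  if (nrow(x$screened_out))
    cat("  screened out (negative values):",
        paste(x$screened_out$family, collapse = ", "), "\n")
  invisible(x)
}
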