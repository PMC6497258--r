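# Candidate functional forms for growth-curve modelling of anatomical and
# physiological quantities during pregnancy.  Each family maps a covariate
# (gestational age in weeks, or a body mass) and a parameter vector theta to
# a predicted value.  Family ids are stable lowercase strings used in fit
# results, config files and the command-line interface.

.family_defs <- list(
  linear                    = list(k = 2L, growth = FALSE),
  linear_growth             = list(k = 1L, growth = TRUE),
  quadratic                 = list(k = 3L, growth = FALSE),
  quadratic_growth          = list(k = 2L, growth = TRUE),
  cubic                     = list(k = 4L, growth = FALSE),
  cubic_growth              = list(k = 3L, growth = TRUE),
  gompertz                  = list(k = 3L, growth = FALSE),
  modified_gompertz         = list(k = 4L, growth = FALSE),
  logistic                  = list(k = 3L, growth = FALSE),
  modified_logistic         = list(k = 4L, growth = FALSE),
  power_law                 = list(k = 2L, growth = FALSE),
  modified_power_law        = list(k = 3L, growth = FALSE),
  luecke_power_law          = list(k = 3L, growth = FALSE),
  modified_luecke_power_law = list(k = 4L, growth = FALSE)
)

#' Model family identifiers
#'
#' @return Character vector of the fourteen supported family ids.
#' @export
model_families <- function() names(.family_defs)

#' Number of free parameters in a model family
#'
#' @param family A family id (see [model_families()]).
#' @return Integer parameter count.
#' @export
family_k <- function(family) {
  family <- match.arg(family, model_families())
  .family_defs[[family]]$k
}

#' Construct a model specification
#'
#' Binds a functional-form family to a concrete parameter vector.  The
#' covariate is either a gestational age in weeks (`"age_weeks"`) or a body
#' mass (`"body_mass"`, used by the allometric power-law families).
#'
#' @param family A family id (see [model_families()]).
#' @param theta Numeric parameter vector; its length must equal the family's
#'   parameter count.
#' @param covariate One of `"age_weeks"` or `"body_mass"`.
#' @return An object of class `"model_spec"`.
#' @examples
#' spec <- model_spec("gompertz", c(0.0018282, 1.1735, 0.077577))
#' evaluate_model(spec, c(0, 20, 40))
#' @export
model_spec <- function(family, theta,
                       covariate = c("age_weeks", "body_mass")) {
  family <- match.arg(family, model_families())
  covariate <- match.arg(covariate)
  theta <- as.numeric(theta)
  k <- .family_defs[[family]]$k
  if (length(theta) != k)
    stop(sprintf("family '%s' takes %d parameters, got %d",
                 family, k, length(theta)), call. = FALSE)
  if (!all(is.finite(theta)))
    stop("all parameters must be finite", call. = FALSE)
  structure(list(family = family, theta = theta, covariate = covariate),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s(%s) on %s\n", x$family,
              paste(signif(x$theta, 6), collapse = ", "), x$covariate))
  invisible(x)
}

# Numerically stable logistic: theta0 * plogis(theta1 * (x - theta2)).
# plogis is computed on the log scale internally, so exponents far beyond
# +/-700 neither overflow nor underflow to NaN.
.stable_logistic <- function(x, theta0, theta1, theta2) {
  theta0 * stats::plogis(theta1 * (x - theta2))
}

.gompertz <- function(x, theta0, theta1, theta2) {
  if (theta2 == 0)
    stop("Gompertz rate parameter theta2 must be nonzero", call. = FALSE)
  theta0 * exp(theta1 / theta2 * (1 - exp(-theta2 * x)))
}

# x^theta1 with a continuity extension at x = 0 for positive exponents
# (the fetal-mass covariate is 0 at conception).  Negative or fractional
# exponents at x <= 0 are a domain error.
.power_term <- function(x, theta1) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos]^theta1
  if (any(!pos)) {
    if (any(x < 0))
      stop("power-law families require a nonnegative covariate", call. = FALSE)
    if (theta1 < 0)
      stop("power law at covariate 0 with negative exponent is undefined",
           call. = FALSE)
    out[!pos] <- if (theta1 == 0) 1 else 0
  }
  out
}

.luecke_term <- function(x, theta0, theta1, theta2) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- theta0 * x[pos]^(theta1 + theta2 * log(x[pos]))
  if (any(!pos)) {
    if (any(x < 0))
      stop("power-law families require a nonnegative covariate", call. = FALSE)
    # limit of x^(theta1 + theta2 log x) as x -> 0+ is 0 when the curve is
    # ultimately growing (theta2 > 0 dominates, or theta2 == 0 and theta1 > 0)
    lim <- if (theta2 > 0 || (theta2 == 0 && theta1 > 0)) 0 else NA_real_
    if (is.na(lim))
      stop("Luecke power law at covariate 0 is undefined for these parameters",
           call. = FALSE)
    out[!pos] <- theta0 * lim
  }
  out
}

#' Evaluate a model specification
#'
#' Evaluates `y(x; theta)` for the family held in `spec` at covariate values
#' `x`, exactly per the family's closed form.  Logistic families are
#' evaluated in a sign-split numerically stable form so that extreme
#' exponents do not overflow.
#'
#' @param spec A [model_spec()].
#' @param x Numeric vector of covariate values (gestational age in weeks or
#'   body mass, per `spec$covariate`).
#' @return Numeric vector of predicted values, same length as `x`.
#' @export
evaluate_model <- function(spec, x) {
  stopifnot(inherits(spec, "model_spec"))
  x <- as.numeric(x)
  th <- spec$theta
  switch(spec$family,
    linear           = th[1] + th[2] * x,
    linear_growth    = th[1] * x,
    quadratic        = th[1] + th[2] * x + th[3] * x^2,
    quadratic_growth = th[1] * x + th[2] * x^2,
    cubic            = th[1] + th[2] * x + th[3] * x^2 + th[4] * x^3,
    cubic_growth     = th[1] * x + th[2] * x^2 + th[3] * x^3,
    gompertz          = .gompertz(x, th[1], th[2], th[3]),
    modified_gompertz = .gompertz(x, th[1], th[2], th[3]) + th[4],
    logistic          = .stable_logistic(x, th[1], th[2], th[3]),
    modified_logistic = .stable_logistic(x, th[1], th[2], th[3]) + th[4],
    power_law          = th[1] * .power_term(x, th[2]),
    modified_power_law = th[1] * .power_term(x, th[2]) + th[3],
    luecke_power_law          = .luecke_term(x, th[1], th[2], th[3]),
    modified_luecke_power_law = .luecke_term(x, th[1], th[2], th[3]) + th[4]
  )
}

#' Screen a model for negative predictions over an interval
#'
#' Evaluates the model on the inclusive grid `lower, lower + step, ...,
#' upper` and reports whether every value is nonnegative.  Models selected
#' purely on information-criterion grounds can dip below zero early in
#' gestation (e.g. cubic growth curves for fetal organ masses); this screen
#' is the feasibility check used during model selection.
#'
#' Mass-covariate specifications are screened through the composed
#' age-to-fetal-mass map (the fetal total-mass Gompertz curve), so the
#' interval is always expressed in gestational weeks.
#'
#' @param spec A [model_spec()].
#' @param lower,upper Interval endpoints in gestational weeks
#'   (default 0 to 42).
#' @param step Grid resolution in weeks (default 0.1).
#' @return A list with elements `nonnegative` (logical) and
#'   `first_violation` (smallest grid age with a negative value, or `NA`).
#' @examples
#' # a cubic growth curve for fetal brain mass goes negative early:
#' feasibility_screen(model_spec("cubic_growth", c(-2.1208, 0.15645, 0.0034746)))
#' @export
feasibility_screen <- function(spec, lower = 0, upper = 42, step = 0.1) {
  stopifnot(lower < upper, step > 0)
  grid <- seq(lower, upper, by = step)
  x <- if (spec$covariate == "body_mass") fetal_mass(grid) else grid
  y <- evaluate_model(spec, x)
  bad <- which(y < 0)
  list(nonnegative = length(bad) == 0,
       first_violation = if (length(bad)) grid[bad[1]] else NA_real_)
}
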