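# Synthetic summary-statistic data with the structure the calibration
# engine expects: per-covariate sample means, standard deviations and
# sample sizes drawn around a known generating curve.  Used to test
# parameter recovery and model selection without external data.

#' Define a sampling design for synthetic summary data
#'
#' The default design mirrors the visible spread of typical curated
#' pregnancy datasets: 16 gestational ages from 10 to 40 weeks, 25 subjects
#' per age, and 10% coefficient of variation around the curve.
#'
#' @param ages Strictly increasing numeric vector of covariate values.
#' @param n Subjects per point (single value or per-point vector).
#' @param cv Coefficient of variation of the Gaussian subject noise; the
#'   per-point noise SD is `cv * |y(x)|`.  Ignored when `sd` is given.
#' @param sd Absolute noise SD (single value or per-point); overrides `cv`.
#' @param truncate_at_zero Clamp drawn subject values at zero (off by
#'   default; relevant only for early-gestation designs where the noise is
#'   comparable to the curve).
#' @param seed Integer seed.
#' @return A list of class `"sampling_design"`.
#' @export
sampling_design <- function(ages = seq(10, 40, by = 2), n = 25L, cv = 0.1,
                            sd = NULL, truncate_at_zero = FALSE, seed = 1L) {
  ages <- as.numeric(ages)
  if (any(diff(ages) <= 0))
    stop("ages must be strictly increasing", call. = FALSE)
  n <- as.integer(rep_len(n, length(ages)))
  if (any(n < 1)) stop("n must be at least 1", call. = FALSE)
  if (is.null(sd) && cv < 0) stop("cv must be nonnegative", call. = FALSE)
  if (!is.null(sd)) {
    sd <- rep_len(as.numeric(sd), length(ages))
    if (any(sd < 0)) stop("sd must be nonnegative", call. = FALSE)
  }
  structure(list(ages = ages, n = n, cv = cv, sd = sd,
                 truncate_at_zero = isTRUE(truncate_at_zero),
                 seed = as.integer(seed)),
            class = "sampling_design")
}

#' Generate a synthetic summary dataset from a known model
#'
#' For each design point, draws `n` subject values from a Gaussian centred
#' on the model curve with the design's noise SD, and records the sample
#' mean, sample SD (`NA` when `n = 1`, as a single observation has no
#' spread) and `n`.  Identical seed, design and spec give a byte-identical
#' dataset.
#'
#' @param spec A [model_spec()]; the generating curve.
#' @param design A [sampling_design()].
#' @return A [summary_dataset()].
#' @export
generate_summary_dataset <- function(spec, design) {
  stopifnot(inherits(spec, "model_spec"), inherits(design, "sampling_design"))
  y <- evaluate_model(spec, design$ages)
  if (any(!is.finite(y)))
    stop("generating model is not evaluable on the design grid",
         call. = FALSE)
  sigma <- if (!is.null(design$sd)) design$sd else design$cv * abs(y)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(design$seed)

  m <- s <- numeric(length(y))
  for (i in seq_along(y)) {
    draws <- stats::rnorm(design$n[i], mean = y[i], sd = sigma[i])
    if (design$truncate_at_zero) draws <- pmax(draws, 0)
    m[i] <- mean(draws)
    s[i] <- if (design$n[i] > 1) stats::sd(draws) else NA_real_
  }
  summary_dataset(design$ages, m, sd = s, n = design$n,
                  covariate_kind = spec$covariate)
}

#' Generate digitized-style summary data
#'
#' Emulates observations extracted from published figures: one subject per
#' point with no reported spread or sample size.  Downstream,
#' [impute_summary()] assigns these points a 20% coefficient of variation
#' and a sample size of one.
#'
#' @param spec A [model_spec()]; the generating curve.
#' @param ages Covariate grid.
#' @param cv Coefficient of variation of the single-draw noise
#'   (default 0.2, matching the imputation convention).
#' @param seed Integer seed.
#' @return A [summary_dataset()] with all `sd` and `n` missing.
#' @export
generate_digitized_style <- function(spec, ages, cv = 0.2, seed = 1L) {
  design <- sampling_design(ages = ages, n = 1L, cv = cv, seed = seed)
  d <- generate_summary_dataset(spec, design)
  d$n <- NA_integer_
  d
}
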