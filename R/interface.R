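# Registry-driven evaluation: every modelled quantity is registered under
# its conventional symbol together with its units, compartment code,
# subject and validity window, and tables of any subset of quantities can
# be evaluated over a gestational-age grid and exported to CSV/JSON.
#
# Validity classes:
#   always     - defined on the whole modelled range [0, 42] weeks
#   conceptus  - products of conception: nonexistent before 2 weeks
#                (pre_conception), extrapolated from 2 to the first
#                calibration observation at 9 weeks
#   fetal      - fetal quantity: nonexistent before 2 weeks
#   composite  - fetal composite: additionally flagged pre_recommended
#                before 13 weeks (no first-trimester calibration data)

.registry_rows <- function() {
  r <- function(symbol, quantity, units, compartment, subject, validity,
                fun, preferred = NA_character_)
    list(symbol = symbol, quantity = quantity, units = units,
         compartment = compartment, subject = subject, validity = validity,
         preferred = preferred, fun = fun)
  list(
    r("W^m", "Maternal mass", "kg", NA, "maternal", "always",
      maternal_mass, "cubic"),
    r("W_adip^m", "Maternal adipose tissue mass", "kg", "adip", "maternal",
      "always", maternal_adipose_mass, "linear"),
    r("V_adip^m", "Maternal adipose tissue volume", "L", "adip", "maternal",
      "always", maternal_adipose_volume, "linear/density"),
    r("V_plas^m", "Maternal plasma volume", "L", "plas", "maternal",
      "always", maternal_plasma_volume, "modified_logistic"),
    r("V_rbcs^m", "Maternal red blood cell volume", "L", "rbcs", "maternal",
      "always", function(t) maternal_rbc_volume(t), "hematocrit_ratio"),
    r("V_plac^m", "Placenta volume", "mL", "plac", "maternal", "conceptus",
      placenta_volume, "cubic_growth"),
    r("V_amnf^m", "Amniotic fluid volume", "mL", "amnf", "maternal",
      "conceptus", amniotic_fluid_volume, "logistic"),
    r("V_rest^m", "Maternal rest-of-body volume", "L", "rest", "maternal",
      "always", function(t) maternal_rest_of_body_volume(t), "mass_balance"),
    r("Q_artb^m", "Maternal cardiac output", "L/h", "artb", "maternal",
      "always", maternal_cardiac_output, "cubic"),
    r("Q_adip^m", "Maternal blood flow to adipose", "L/h", "adip",
      "maternal", "always", function(t) maternal_transition_flow("adip", t),
      "linear_transition"),
    r("Q_bran^m", "Maternal blood flow to brain", "L/h", "bran", "maternal",
      "always", function(t) maternal_transition_flow("bran", t),
      "linear_transition"),
    r("Q_kidn^m", "Maternal blood flow to kidneys", "L/h", "kidn",
      "maternal", "always", function(t) maternal_kidney_flow(t), "cubic"),
    r("Q_gutx^m", "Maternal blood flow to gut", "L/h", "gutx", "maternal",
      "always", function(t) maternal_transition_flow("gutx", t),
      "linear_transition"),
    r("Q_livr^m", "Maternal blood flow to liver", "L/h", "livr", "maternal",
      "always", function(t) maternal_transition_flow("livr", t),
      "linear_transition"),
    r("Q_thyr^m", "Maternal blood flow to thyroid", "L/h", "thyr",
      "maternal", "always", function(t) maternal_transition_flow("thyr", t),
      "linear_transition"),
    r("Q_plac^m", "Maternal blood flow to placenta", "L/h", "plac",
      "maternal", "always", function(t) maternal_placenta_flow(t),
      "proportional_to_volume"),
    r("Q_rest^m", "Maternal blood flow to rest of body", "L/h", "rest",
      "maternal", "always", maternal_rest_of_body_flow,
      "flow_conservation"),
    r("H^m", "Maternal hematocrit", "percent", NA, "maternal", "always",
      function(t) maternal_hematocrit(t), "quadratic"),
    r("k_kidn^m", "Maternal glomerular filtration rate", "mL/min", "kidn",
      "maternal", "always", function(t) maternal_gfr(t), "quadratic"),

    r("W^f", "Fetal mass or volume", "g", NA, "fetal", "fetal",
      fetal_mass, "gompertz"),
    r("W_bran^f", "Fetal brain mass", "g", "bran", "fetal", "fetal",
      function(t) fetal_organ_mass("bran", t), "gompertz"),
    r("V_bran^f", "Fetal brain volume", "mL", "bran", "fetal", "fetal",
      function(t) fetal_organ_volume("bran", t), "gompertz/density"),
    r("W_livr^f", "Fetal liver mass", "g", "livr", "fetal", "fetal",
      function(t) fetal_organ_mass("livr", t), "gompertz"),
    r("V_livr^f", "Fetal liver volume", "mL", "livr", "fetal", "fetal",
      function(t) fetal_organ_volume("livr", t), "gompertz/density"),
    r("W_kidn^f", "Fetal kidney mass", "g", "kidn", "fetal", "fetal",
      function(t) fetal_organ_mass("kidn", t), "gompertz"),
    r("V_kidn^f", "Fetal kidney volume", "mL", "kidn", "fetal", "fetal",
      function(t) fetal_organ_volume("kidn", t), "gompertz/density"),
    r("W_lung^f", "Fetal lung mass", "g", "lung", "fetal", "fetal",
      function(t) fetal_organ_mass("lung", t), "gompertz"),
    r("V_lung^f", "Fetal lung volume", "mL", "lung", "fetal", "fetal",
      function(t) fetal_organ_volume("lung", t), "gompertz/density"),
    r("W_thyr^f", "Fetal thyroid mass", "g", "thyr", "fetal", "fetal",
      function(t) fetal_organ_mass("thyr", t), "gompertz"),
    r("V_thyr^f", "Fetal thyroid volume", "mL", "thyr", "fetal", "fetal",
      function(t) fetal_organ_volume("thyr", t), "gompertz/density"),
    r("W_gutx^f", "Fetal gut mass", "g", "gutx", "fetal", "fetal",
      function(t) fetal_organ_mass("gutx", t), "gompertz"),
    r("V_gutx^f", "Fetal gut volume", "mL", "gutx", "fetal", "fetal",
      function(t) fetal_organ_volume("gutx", t), "gompertz/density"),
    r("V_rest^f", "Fetal rest-of-body volume", "mL", "rest", "fetal",
      "composite", fetal_rest_of_body_volume, "mass_balance"),
    r("Q_rvtl^f", "Fetal right-ventricle flow", "mL/min", "rvtl", "fetal",
      "fetal", function(t) fetal_flow("rvtl", t), "logistic"),
    r("Q_lvtl^f", "Fetal left-ventricle flow", "mL/min", "lvtl", "fetal",
      "fetal", function(t) fetal_flow("lvtl", t), "logistic"),
    r("Q_DA^f", "Fetal ductus arteriosus flow", "mL/min", NA, "fetal",
      "fetal", function(t) fetal_flow("DA", t), "logistic"),
    r("Q_artb^f", "Fetal arterial blood flow", "mL/min", "artb", "fetal",
      "composite", function(t) fetal_flow("artb", t), "flow_conservation"),
    r("Q_lung^f", "Fetal blood flow to lung", "mL/min", "lung", "fetal",
      "composite", function(t) fetal_flow("lung", t), "flow_conservation"),
    r("Q_FO^f", "Fetal foramen ovale flow", "mL/min", NA, "fetal",
      "composite", function(t) fetal_flow("FO", t), "flow_conservation"),
    r("Q_plac^f", "Fetal blood flow to placenta", "mL/min", "plac", "fetal",
      "fetal", function(t) fetal_flow("plac", t), "logistic"),
    r("Q_DV^f", "Fetal ductus venosus flow", "mL/min", NA, "fetal", "fetal",
      function(t) fetal_flow("DV", t), "gompertz"),
    r("Q_gutx^f", "Fetal blood flow to gut", "mL/min", "gutx", "fetal",
      "composite", function(t) fetal_flow("gutx", t), "flow_fraction"),
    r("Q_kidn^f", "Fetal blood flow to kidneys", "mL/min", "kidn", "fetal",
      "composite", function(t) fetal_flow("kidn", t), "flow_fraction"),
    r("Q_bran^f", "Fetal blood flow to brain", "mL/min", "bran", "fetal",
      "composite", function(t) fetal_flow("bran", t), "flow_fraction"),
    r("Q_livr^f", "Fetal blood flow to liver", "mL/min", "livr", "fetal",
      "composite", function(t) fetal_flow("livr", t), "flow_fraction"),
    r("Q_thyr^f", "Fetal blood flow to thyroid", "mL/min", "thyr", "fetal",
      "composite", function(t) fetal_flow("thyr", t), "flow_fraction"),
    r("Q_rest^f", "Fetal blood flow to rest of body", "mL/min", "rest",
      "fetal", "composite", fetal_rest_of_body_flow, "flow_conservation"),
    r("H^f", "Fetal hematocrit", "percent", NA, "fetal", "fetal",
      function(t) fetal_hematocrit(t), "cubic_growth")
  )
}

.registry_env <- new.env(parent = emptyenv())

.registry <- function() {
  if (is.null(.registry_env$rows))
    .registry_env$rows <- .registry_rows()
  .registry_env$rows
}

#' The quantity registry
#'
#' One row per modelled quantity, keyed by its conventional symbol.
#'
#' @return A data.frame with columns `symbol`, `quantity`, `units`,
#'   `compartment`, `subject`, `validity`, `preferred`.
#' @export
quantity_registry <- function() {
  rows <- .registry()
  do.call(rbind, lapply(rows, function(x)
    data.frame(symbol = x$symbol, quantity = x$quantity, units = x$units,
               compartment = x$compartment, subject = x$subject,
               validity = x$validity, preferred = x$preferred)))
}

.validity_flags <- function(validity, t) {
  flags <- rep("valid", length(t))
  if (validity %in% c("conceptus", "fetal", "composite"))
    flags[t < 2] <- "pre_conception"
  if (validity == "composite")
    flags[t >= 2 & t < 13] <- "pre_recommended"
  if (validity == "conceptus")
    flags[t >= 2 & t < 9] <- "extrapolated"
  flags
}

#' Evaluate registered quantities over a gestational-age grid
#'
#' @param symbols Character vector of registry symbols, or `"all"`.
#' @param start,stop Grid endpoints in weeks (inclusive).
#' @param step Grid step in weeks.
#' @param strict If `TRUE`, cells flagged `pre_conception` or
#'   `pre_recommended` are blanked to `NA` rather than reporting the raw
#'   curve value.
#' @return A data.frame of class `"physiology_table"` with column `t` and
#'   one column per symbol; attributes `units` (named character vector) and
#'   `flags` (character matrix, one column per symbol, values `valid`,
#'   `extrapolated`, `pre_conception`, `pre_recommended`).
#' @examples
#' tab <- evaluate_table(c("W^m", "V_plac^m"), 0, 40, step = 10)
#' attr(tab, "flags")
#' @export
evaluate_table <- function(symbols = "all", start = 0, stop = 42, step = 1,
                           strict = FALSE) {
  stopifnot(start >= 0, start < stop, stop <= 42, step > 0)
  rows <- .registry()
  all_syms <- vapply(rows, `[[`, character(1), "symbol")
  if (identical(symbols, "all")) symbols <- all_syms
  missing <- setdiff(symbols, all_syms)
  if (length(missing))
    stop("unknown symbol(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  grid <- seq(start, stop, by = step)
  out <- data.frame(t = grid)
  units <- character(0)
  flags <- matrix(character(0), nrow = length(grid), ncol = 0)
  for (sym in symbols) {
    row <- rows[[match(sym, all_syms)]]
    vals <- row$fun(grid)
    fl <- .validity_flags(row$validity, grid)
    if (strict) vals[fl %in% c("pre_conception", "pre_recommended")] <- NA
    out[[sym]] <- vals
    units[sym] <- row$units
    flags <- cbind(flags, fl)
  }
  colnames(flags) <- symbols
  structure(out, units = units, flags = flags,
            class = c("physiology_table", "data.frame"))
}

#' Convert between gestational and fetal age
#'
#' Gestational age (weeks since the last menstrual period) equals fetal age
#' (weeks since fertilization) plus two weeks.
#'
#' @param value Age in weeks.
#' @param from,to `"gestational"` or `"fetal"`.
#' @return Converted age in weeks; an error if the result would be
#'   negative (before conception).
#' @export
convert_age <- function(value, from = c("gestational", "fetal"),
                        to = c("gestational", "fetal")) {
  from <- match.arg(from); to <- match.arg(to)
  value <- as.numeric(value)
  shift <- (from == "fetal") - (to == "fetal")
  out <- value + 2 * shift
  if (any(out < 0))
    stop("age conversion yields a negative (pre-conception) age",
         call. = FALSE)
  out
}

# ---- file formats ---------------------------------------------------------

#' Read and write physiology tables and summary datasets
#'
#' CSV dialects: a physiology table is written with a leading comment line
#' `# units: t=weeks,<symbol>=<unit>,...` followed by a standard CSV with a
#' `t` column; a summary dataset has columns `covariate,mean,sd,n` with
#' empty cells for missing values and `#` comment lines.  JSON round-trips
#' preserve units and validity flags.  Values survive a write/read
#' round-trip to 15 significant digits.
#'
#' @param x Object to write.
#' @param path File path.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @name physiology-io
NULL

#' @rdname physiology-io
#' @export
write_physiology_csv <- function(x, path) {
  stopifnot(inherits(x, "physiology_table"))
  units <- attr(x, "units")
  hdr <- paste0("# units: t=weeks,",
                paste0(names(units), "=", units, collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(format(as.data.frame(x), digits = 15, trim = TRUE,
                          scientific = NA),
                   con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname physiology-io
#' @export
read_physiology_csv <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "# units:"))
    stop("malformed physiology CSV: missing '# units:' header line",
         call. = FALSE)
  spec <- strsplit(sub("^# units:\\s*", "", first), ",")[[1]]
  kv <- strsplit(spec, "=")
  units <- stats::setNames(vapply(kv, `[`, character(1), 2),
                           vapply(kv, `[`, character(1), 1))
  d <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (names(d)[1] != "t")
    stop("malformed physiology CSV: first column must be 't'", call. = FALSE)
  if (any(diff(d$t) <= 0))
    stop("non-monotone age grid in physiology CSV", call. = FALSE)
  syms <- setdiff(names(d), "t")
  if (!setequal(c("t", syms), names(units)))
    stop("unit mismatch between header and columns", call. = FALSE)
  for (cn in names(d)) d[[cn]] <- as.numeric(d[[cn]])
  rows <- .registry()
  all_syms <- vapply(rows, `[[`, character(1), "symbol")
  flags <- vapply(syms, function(sym) {
    i <- match(sym, all_syms)
    if (is.na(i)) rep("valid", nrow(d))
    else .validity_flags(rows[[i]]$validity, d$t)
  }, character(nrow(d)))
  flags <- matrix(flags, nrow = nrow(d), dimnames = list(NULL, syms))
  structure(d, units = units[syms], flags = flags,
            class = c("physiology_table", "data.frame"))
}

#' @rdname physiology-io
#' @export
write_physiology_json <- function(x, path) {
  stopifnot(inherits(x, "physiology_table"))
  units <- attr(x, "units"); flags <- attr(x, "flags")
  payload <- list(
    grid_weeks = x$t,
    quantities = stats::setNames(lapply(names(units), function(sym) {
      list(units = units[[sym]], values = x[[sym]],
           flags = unname(flags[, sym]))
    }), names(units)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname physiology-io
#' @export
read_physiology_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  syms <- names(payload$quantities)
  d <- data.frame(t = payload$grid_weeks)
  units <- character(0)
  flags <- matrix(character(0), nrow = nrow(d), ncol = 0)
  for (sym in syms) {
    q <- payload$quantities[[sym]]
    d[[sym]] <- as.numeric(q$values)
    units[sym] <- q$units
    flags <- cbind(flags, q$flags)
  }
  colnames(flags) <- syms
  structure(d, units = units, flags = flags,
            class = c("physiology_table", "data.frame"))
}

#' @rdname physiology-io
#' @export
read_summary_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#",
                       colClasses = c("numeric", "numeric", "numeric",
                                      "integer"))
  if (!identical(names(d), c("covariate", "mean", "sd", "n")))
    stop("summary CSV must have columns covariate,mean,sd,n", call. = FALSE)
  summary_dataset(d$covariate, d$mean, sd = d$sd, n = d$n)
}

#' @rdname physiology-io
#' @export
write_summary_csv <- function(x, path) {
  stopifnot(inherits(x, "summary_dataset"))
  utils::write.csv(
    data.frame(covariate = x$covariate, mean = x$mean, sd = x$sd, n = x$n),
    path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write or read a fit result as JSON
#'
#' @param fit A `"fit_result"`.
#' @param path File path.
#' @return `read_fit_json` returns a reconstructed `"fit_result"`.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  jsonlite::write_json(
    list(family = fit$spec$family, theta = fit$spec$theta,
         covariate = fit$spec$covariate, loglik = fit$loglik, k = fit$k,
         aic = fit$aic, converged = fit$converged,
         n_starts = fit$n_starts, seed = fit$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(spec = model_spec(p$family, p$theta, covariate = p$covariate),
                 loglik = p$loglik, k = as.integer(p$k), aic = p$aic,
                 converged = p$converged, n_starts = as.integer(p$n_starts),
                 seed = as.integer(p$seed)),
            class = "fit_result")
}

#' Run the internal consistency checks
#'
#' Evaluates the structural invariants of the model repository on a
#' 0.1-week grid: flow conservation in the maternal and fetal circulations,
#' the shunt flow identities, positivity of the lung and foramen ovale
#' flows from 13 weeks, the ductus venosus flow staying below the placental
#' flow after 12 weeks, mutual consistency of the plasma/RBC/hematocrit
#' models, and the bounds on the rest-of-body composites.
#'
#' @return A named logical vector of check results.
#' @export
check_invariants <- function() {
  tt <- seq(0, 42, by = 0.1)
  t13 <- tt[tt >= 13]
  t12 <- tt[tt > 12]
  hf <- fetal_heart_flows(tt)
  pf <- fetal_placental_flows(tt)
  of <- fetal_organ_flows(tt)
  m_named <- maternal_transition_flow("adip", tt) +
    maternal_transition_flow("bran", tt) + maternal_kidney_flow(tt) +
    maternal_transition_flow("gutx", tt) +
    maternal_transition_flow("livr", tt) +
    maternal_transition_flow("thyr", tt) + maternal_placenta_flow(tt)
  h <- maternal_hematocrit(tt) / 100
  vr <- maternal_rbc_volume(tt)
  vp <- maternal_plasma_volume(tt)
  rest_v <- maternal_rest_of_body_volume(tt[tt <= 40])
  c(
    maternal_flow_conservation = isTRUE(all.equal(
      maternal_cardiac_output(tt),
      m_named + maternal_rest_of_body_flow(tt), tolerance = 1e-12)),
    fetal_flow_conservation = isTRUE(all.equal(
      hf$artb,
      pf$plac + of$gutx + of$kidn + of$bran + of$livr + of$thyr +
        fetal_rest_of_body_flow(tt), tolerance = 1e-12)),
    shunt_algebra = isTRUE(all.equal(hf$FO + hf$rvtl, hf$artb,
                                     tolerance = 1e-12)) &&
      isTRUE(all.equal(hf$lung + hf$DA, hf$rvtl, tolerance = 1e-12)),
    lung_FO_positive = all(fetal_heart_flows(t13)$lung > 0) &&
      all(fetal_heart_flows(t13)$FO > 0),
    DV_below_placental = all(fetal_placental_flows(t12)$DV <
                               fetal_placental_flows(t12)$plac),
    blood_model_consistency = isTRUE(all.equal(
      100 * vr / (vp + vr), maternal_hematocrit(tt), tolerance = 1e-12)),
    maternal_rest_volume_band = all(rest_v > 30 & rest_v < 35),
    fetal_rest_volume_positive = all(fetal_rest_of_body_volume(t13) > 0)
  )
}
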