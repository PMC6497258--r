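# Preferred empirical models for the maternal side of pregnancy: body and
# adipose mass, blood component volumes, conceptus volumes, cardiac output
# and regional blood flows, hematocrit and glomerular filtration.  All
# curves take gestational age t in weeks (0 = first day of the last
# menstrual period); "maternal mass" includes the products of conception.
#
# Units follow the source models: masses kg, maternal volumes L except the
# conceptus volumes (mL), flows L/h, hematocrit percent, GFR mL/min.

# Tissue densities (kg/L) and the percent of a non-pregnant woman's body
# mass held by each tissue, used for the static compartment volumes and the
# fat-free-mass balance.
.densities <- c(adip = 0.95, bran = 1.04, thyr = 1.05, kidn = 1.05,
                gutx = 1.045, livr = 1.05, lung = 1.05, blood = 1.06,
                plac = 1.02, amnf = 1.01, ffmx = 1.1)

.female_pct <- c(adip = 37.5, bran = 2.17, thyr = 0.0283, kidn = 0.458,
                 gutx = 1.90, livr = 2.33, lung = 1.58)

# Linear transitions of regional flow as percent of cardiac output, from
# the non-pregnant share at 0 weeks to the near-term share at 40 weeks.
.flow_transition <- list(
  adip = c(8.5, 7.8), bran = c(12.0, 8.8), kidn = c(17.0, 16.6),
  gutx = c(17.0, 12.5), livr = c(27.0, 20.0), thyr = c(1.5, 1.1),
  utpl = c(0.4, 12.0))

#' Tissue densities used throughout the package
#'
#' @return Named numeric vector of densities in kg/L, including the
#'   fat-free-mass average density (`ffmx`).
#' @export
tissue_densities <- function() .densities

.check_age <- function(t) {
  t <- as.numeric(t)
  if (any(!is.finite(t)))
    stop("gestational age must be finite", call. = FALSE)
  if (any(t < 0 | t > 42))
    warning("gestational age outside the modelled range [0, 42] weeks; ",
            "values are extrapolations", call. = FALSE)
  t
}

#' Maternal body mass
#'
#' Cubic model for the mass of an average pregnant woman, including the
#' fetus, placenta and amniotic fluid.
#'
#' @param t Gestational age in weeks.
#' @return Mass in kg.
#' @examples
#' maternal_mass(c(0, 20, 40))
#' @export
maternal_mass <- function(t) {
  t <- .check_age(t)
  61.103 - 0.010614 * t + 0.029161 * t^2 - 5.0203e-4 * t^3
}

#' Maternal adipose tissue mass and volume
#'
#' Linear model for total maternal fat mass; volume follows from the
#' adipose density of 0.950 kg/L.
#'
#' @param t Gestational age in weeks.
#' @return `maternal_adipose_mass`: kg; `maternal_adipose_volume`: L.
#' @export
maternal_adipose_mass <- function(t) {
  t <- .check_age(t)
  17.067 + 0.14937 * t
}

#' @rdname maternal_adipose_mass
#' @export
maternal_adipose_volume <- function(t) {
  maternal_adipose_mass(t) / .densities[["adip"]]
}

#' Maternal plasma volume
#'
#' Modified logistic model: a sigmoid rise of 1.2406 L centred at 17.813
#' weeks on a 2.4958 L non-pregnant baseline (asymptote 3.7364 L).
#'
#' @param t Gestational age in weeks.
#' @return Plasma volume in L.
#' @export
maternal_plasma_volume <- function(t) {
  t <- .check_age(t)
  .stable_logistic(t, 1.2406, 0.31338, 17.813) + 2.4958
}

#' Maternal red blood cell volume
#'
#' Two models are available.  The default, `"hematocrit"`, derives RBC
#' volume from the plasma-volume and hematocrit models via
#' `V_rbc = H/(1 - H) * V_plas` (hematocrit as a fraction), which keeps the
#' three blood quantities mutually consistent.  `"logistic"` is the modified
#' logistic curve fitted directly to RBC volume data; it is retained for
#' comparison and for the rest-of-body mass balance.
#'
#' @param t Gestational age in weeks.
#' @param method `"hematocrit"` (default) or `"logistic"`.
#' @return RBC volume in L.
#' @export
maternal_rbc_volume <- function(t, method = c("hematocrit", "logistic")) {
  method <- match.arg(method)
  t <- .check_age(t)
  if (method == "logistic")
    return(.stable_logistic(t, 0.32704, 0.62555, 21.452) + 1.5169)
  h <- maternal_hematocrit(t) / 100
  h / (1 - h) * maternal_plasma_volume(t)
}

#' Placenta and amniotic fluid volumes
#'
#' Cubic growth model for placenta volume and logistic model for amniotic
#' fluid volume.  Neither the placenta nor the amniotic fluid exists before
#' conception at 2 weeks of gestational age, and the fitted curves are not
#' considered accurate before 9 weeks (the earliest observation in the
#' calibration data); the raw curves are returned here and validity gating
#' is applied by [evaluate_table()].  The placenta curve is negative below
#' about 1.97 weeks.
#'
#' @param t Gestational age in weeks.
#' @return Volume in mL.
#' @export
placenta_volume <- function(t) {
  t <- .check_age(t)
  -1.7646 * t + 0.91775 * t^2 - 0.011543 * t^3
}

#' @rdname placenta_volume
#' @export
amniotic_fluid_volume <- function(t) {
  t <- .check_age(t)
  .stable_logistic(t, 822.34, 0.26988, 20.150)
}

#' Smallest positive age at which the placenta volume model is positive
#'
#' Root of the placenta cubic growth curve near 2 weeks, located
#' numerically; the curve is negative between 0 and this age.
#'
#' @return Gestational age in weeks.
#' @export
placenta_positivity_threshold <- function() {
  stats::uniroot(placenta_volume, c(0.5, 5), tol = 1e-12)$root
}

#' Static maternal compartment volumes
#'
#' Volumes of maternal compartments that do not change appreciably during
#' pregnancy, computed as the non-pregnant body mass (61.103 kg) times the
#' female percent-of-body-mass for the tissue, divided by its density.
#'
#' @return Named numeric vector (L) with elements `bran`, `thyr`, `kidn`,
#'   `gutx`, `livr`, `lung`.
#' @export
maternal_static_volumes <- function() {
  w0 <- maternal_mass(0)
  organs <- c("bran", "thyr", "kidn", "gutx", "livr", "lung")
  vols <- w0 * .female_pct[organs] / 100 / .densities[organs]
  stats::setNames(as.numeric(vols), organs)
}

#' Maternal fat-free-mass volume
#'
#' Mass balance for the volume of everything in the maternal body except
#' adipose tissue, assuming a fat-free density of 1.1 kg/L.  From 2 weeks
#' the products of conception (fetal mass in g/1000, placenta and amniotic
#' fluid scaled by their densities) are removed, since they are not part of
#' the mother's own fat-free mass.
#'
#' @param t Gestational age in weeks.
#' @return Volume in L.
#' @export
maternal_fat_free_volume <- function(t) {
  t <- .check_age(t)
  base <- maternal_mass(t) - maternal_adipose_mass(t)
  conceptus <- ifelse(t < 2, 0,
    (fetal_mass(t) +
       .densities[["plac"]] * placenta_volume(t) +
       .densities[["amnf"]] * amniotic_fluid_volume(t)) / 1000)
  (base - conceptus) / .densities[["ffmx"]]
}

#' Maternal rest-of-body volume
#'
#' Mass-balance composite: fat-free-mass volume minus plasma, RBC and the
#' six static compartment volumes.  With the directly fitted (logistic) RBC
#' curve this fluctuates between roughly 31 and 34 L over pregnancy.  The
#' hematocrit-consistent RBC curve may be substituted; the two versions
#' differ by under 0.1 L.
#'
#' @param t Gestational age in weeks.
#' @param rbc_method RBC model used inside the balance, `"logistic"`
#'   (default) or `"hematocrit"`; see [maternal_rbc_volume()].
#' @return Volume in L.
#' @export
maternal_rest_of_body_volume <- function(t,
                                         rbc_method = c("logistic",
                                                        "hematocrit")) {
  rbc_method <- match.arg(rbc_method)
  v_all <- maternal_plasma_volume(t) +
    maternal_rbc_volume(t, method = rbc_method) +
    sum(maternal_static_volumes())
  maternal_fat_free_volume(t) - v_all
}

#' Maternal cardiac output
#'
#' Cubic model for total cardiac output, taken to equal both the total
#' arterial and total venous flow.
#'
#' @param t Gestational age in weeks.
#' @return Flow in L/h.
#' @export
maternal_cardiac_output <- function(t) {
  t <- .check_age(t)
  301.78 + 3.2512 * t + 0.15947 * t^2 - 0.0047059 * t^3
}

.transition_fraction <- function(compartment, t) {
  p <- .flow_transition[[compartment]]
  (p[1] + (p[2] - p[1]) / 40 * t) / 100
}

#' Maternal regional blood flow (linear transition models)
#'
#' Flow to a maternal compartment expressed as a percentage of cardiac
#' output that transitions linearly from the non-pregnant share at 0 weeks
#' to the near-term share at 40 weeks (adipose 8.5 to 7.8, brain 12.0 to
#' 8.8, kidneys 17.0 to 16.6, gut 17.0 to 12.5, liver 27.0 to 20.0, thyroid
#' 1.5 to 1.1 percent).  Beyond 40 weeks the percentage extrapolates
#' linearly.
#'
#' @param compartment One of `"adip"`, `"bran"`, `"kidn"`, `"gutx"`,
#'   `"livr"`, `"thyr"`.
#' @param t Gestational age in weeks.
#' @return Flow in L/h.
#' @export
maternal_transition_flow <- function(compartment, t) {
  compartment <- match.arg(compartment,
                           c("adip", "bran", "kidn", "gutx", "livr", "thyr"))
  t <- .check_age(t)
  .transition_fraction(compartment, t) * maternal_cardiac_output(t)
}

#' Maternal kidney blood flow
#'
#' The preferred model is a cubic fitted directly to renal flow data; the
#' linear transition model (17.0 to 16.6 percent of cardiac output) is
#' available for comparison.
#'
#' @param t Gestational age in weeks.
#' @param method `"cubic"` (default) or `"transition"`.
#' @return Flow in L/h.
#' @export
maternal_kidney_flow <- function(t, method = c("cubic", "transition")) {
  method <- match.arg(method)
  t <- .check_age(t)
  if (method == "transition")
    return(maternal_transition_flow("kidn", t))
  53.248 + 3.6447 * t - 0.15357 * t^2 + 0.0016968 * t^3
}

#' Maternal blood flow to the placenta
#'
#' Zero before the establishment of the uteroplacental circulation at 3.6
#' weeks.  The preferred model sets the flow proportional to placenta
#' volume with constant 0.059176 (L/h per mL), chosen so that flow at term
#' (40 weeks) is 39 L/h, the midpoint of reported term flows.  The
#' alternative `"transition"` model ramps the uteroplacental share of
#' cardiac output (0.4 to 12.0 percent) by the fraction reaching the
#' placenta (0 at 3.6 weeks to 80 percent at 40 weeks); it is retained
#' verbatim but under-predicts flow near term.
#'
#' @param t Gestational age in weeks.
#' @param method `"volume"` (default, proportional to placenta volume) or
#'   `"transition"`.
#' @return Flow in L/h.
#' @export
maternal_placenta_flow <- function(t, method = c("volume", "transition")) {
  method <- match.arg(method)
  t <- .check_age(t)
  if (method == "volume") {
    ifelse(t < 3.6, 0, 0.059176 * placenta_volume(t))
  } else {
    ifelse(t < 3.6, 0,
           (0.8 / 36.4) * (t - 3.6) *
             .transition_fraction("utpl", t) * maternal_cardiac_output(t))
  }
}

#' Maternal rest-of-body blood flow
#'
#' Flow-conservation composite: cardiac output minus the flows to adipose,
#' brain, kidneys (cubic), gut, liver, thyroid and placenta
#' (proportional-to-volume).  Fluctuates between roughly 47 and 97 L/h over
#' pregnancy.
#'
#' @param t Gestational age in weeks.
#' @return Flow in L/h.
#' @export
maternal_rest_of_body_flow <- function(t) {
  maternal_cardiac_output(t) -
    (maternal_transition_flow("adip", t) +
       maternal_transition_flow("bran", t) +
       maternal_kidney_flow(t) +
       maternal_transition_flow("gutx", t) +
       maternal_transition_flow("livr", t) +
       maternal_transition_flow("thyr", t) +
       maternal_placenta_flow(t))
}

#' Maternal hematocrit
#'
#' The preferred model is a quadratic in gestational age, returned as a
#' percentage.  The `"ratio"` model instead forms
#' `V_rbc / (V_plas + V_rbc)` from the independently fitted plasma and RBC
#' (logistic) volume curves; it runs consistently below the quadratic
#' because the two fits are not mutually constrained.
#'
#' @param t Gestational age in weeks.
#' @param method `"quadratic"` (default) or `"ratio"`.
#' @return Hematocrit in percent.
#' @export
maternal_hematocrit <- function(t, method = c("quadratic", "ratio")) {
  method <- match.arg(method)
  t <- .check_age(t)
  if (method == "quadratic")
    return(39.192 - 0.10562 * t - 7.1045e-4 * t^2)
  vr <- maternal_rbc_volume(t, method = "logistic")
  vp <- maternal_plasma_volume(t)
  100 * vr / (vp + vr)
}

#' Maternal glomerular filtration rate
#'
#' The preferred model is a quadratic in gestational age.  The
#' `"allometric"` alternative scales a 125 mL/min reference GFR for a 70 kg
#' human by body mass to the 3/4 power, using the maternal mass curve.
#'
#' @param t Gestational age in weeks.
#' @param method `"quadratic"` (default) or `"allometric"`.
#' @return GFR in mL/min.
#' @export
maternal_gfr <- function(t, method = c("quadratic", "allometric")) {
  method <- match.arg(method)
  t <- .check_age(t)
  if (method == "quadratic")
    return(113.73 + 3.5784 * t - 0.067272 * t^2)
  125 * (maternal_mass(t) / 70)^0.75
}
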