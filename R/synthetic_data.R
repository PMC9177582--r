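#' Default true dissemination rates for simulation
#'
#' Per-year rates used as the generator's truth: the whole-dataset estimates
#' for tumor-to-lung (0.00269), lung-to-liver (0.126) and lung-to-brain
#' (0.0404), together with tumor-to-bone 0.006, tumor-to-liver 0.0015 and
#' tumor-to-brain 0.0004, which preserve the estimated ordering
#' \code{luli > lubr > tubo > tulu > tuli > tubr} and give site prevalences
#' of the order seen in registry data (bone ~2\%, lung ~1\%, liver ~0.8\%,
#' brain ~0.2\% at diagnosis).
#'
#' @return A [rate_vector()].
#' @export
default_theta_true <- function() {
  rate_vector(tubo = 0.006, tulu = 0.00269, tuli = 0.0015, tubr = 0.0004,
              luli = 0.126, lubr = 0.0404)
}

#' Registry-like diameter bin weights
#'
#' Proportions of patients in the diameter bins
#' [0,20), [20,40), [40,60), [60,80), [80,100) mm, as printed for the full
#' registry cohort (57.4, 25.9, 6.2, 2.2, 0.9 percent; normalized over the
#' five bins).
#' @export
table1_bin_weights <- function() {
  w <- c(0.574, 0.259, 0.062, 0.022, 0.009)
  w / sum(w)
}

#' Registry-like subtype weights
#'
#' Cohort shares of the four subtypes HR-/HER2+, HR+/HER2+, HR+/HER2-,
#' HR-/HER2- (13,406 / 32,504 / 235,828 / 35,428 of 317,166).
#' @export
table1_subtype_weights <- function() {
  w <- c(13406, 32504, 235828, 35428)
  stats::setNames(w / sum(w), subtype_levels())
}

#' Configuration of a synthetic cohort
#'
#' Describes the generative model of a registry-like diagnosis-time cohort:
#' diameters from either empirical bin weights (default: the printed
#' diameter-bin proportions) or a truncated lognormal; tumor ages imputed
#' from diameters under the growth law; metastasis states simulated from the
#' seeding chain at those ages; subtypes drawn independently with registry
#' weights.
#'
#' @param n_patients Number of patients.
#' @param theta_true True [rate_vector()] driving state simulation.
#' @param growth A [gompertz_params()].
#' @param diameter_dist Either
#'   \code{list(family = "bins", breaks, weights)} with \code{breaks} of
#'   length \code{length(weights) + 1} (uniform within bins), or
#'   \code{list(family = "lognormal", log_mean, log_sd, min_mm, max_mm)}
#'   (inverse-CDF truncated sampling).
#' @param subtype_weights Probabilities of the four subtypes, in
#'   [subtype_levels()] order.
#' @param seed Integer seed; sub-seeds \code{seed + 1/2/3} drive the
#'   diameter, state and subtype draws so each component is independently
#'   reproducible.
#' @return A \code{sim_config}.
#' @export
sim_config <- function(n_patients,
                       theta_true = default_theta_true(),
                       growth = gompertz_params(),
                       diameter_dist = list(family = "bins",
                                            breaks = c(0, 20, 40, 60, 80, 100),
                                            weights = table1_bin_weights()),
                       subtype_weights = table1_subtype_weights(),
                       seed = 1L) {
  stopifnot(n_patients >= 1)
  theta_true <- as_rate_vector(theta_true)
  stopifnot(inherits(growth, "gompertz_params"))
  subtype_weights <- subtype_weights / sum(subtype_weights)
  stopifnot(length(subtype_weights) == 4L, all(subtype_weights >= 0))
  fam <- diameter_dist$family
  if (identical(fam, "bins")) {
    stopifnot(length(diameter_dist$breaks) == length(diameter_dist$weights) + 1L,
              all(diff(diameter_dist$breaks) > 0),
              all(diameter_dist$weights >= 0),
              sum(diameter_dist$weights) > 0)
    diameter_dist$weights <- diameter_dist$weights / sum(diameter_dist$weights)
    if (max(diameter_dist$breaks) > 100)
      stop("diameter distribution must be bounded by 100 mm")
  } else if (identical(fam, "lognormal")) {
    stopifnot(diameter_dist$log_sd > 0,
              diameter_dist$min_mm < diameter_dist$max_mm,
              diameter_dist$max_mm <= 100)
  } else stop("unknown diameter distribution family: ", fam)
  structure(list(n_patients = as.integer(n_patients),
                 theta_true = theta_true, growth = growth,
                 diameter_dist = diameter_dist,
                 subtype_weights = subtype_weights,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Sample tumor diameters
#'
#' Draws \code{n_patients} diameters from the configured distribution,
#' truncated to exceed the single-cell diameter. Deterministic given the
#' config seed.
#'
#' @param cfg A [sim_config()].
#' @return Numeric vector of diameters, mm.
#' @export
sample_diameters <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- cfg$n_patients
  d0_mm <- cfg$growth$d0_um / 1000
  dd <- cfg$diameter_dist
  if (dd$family == "bins") {
    bin <- sample.int(length(dd$weights), n, replace = TRUE,
                      prob = dd$weights)
    lo <- pmax(dd$breaks[bin], d0_mm * (1 + 1e-6))
    hi <- dd$breaks[bin + 1L]
    stats::runif(n, lo, hi)
  } else {
    plo <- stats::plnorm(max(dd$min_mm, d0_mm * (1 + 1e-6)),
                         dd$log_mean, dd$log_sd)
    phi <- stats::plnorm(dd$max_mm, dd$log_mean, dd$log_sd)
    if (phi - plo < 1e-12) stop("degenerate truncated lognormal")
    stats::qlnorm(stats::runif(n, plo, phi), dd$log_mean, dd$log_sd)
  }
}

#' Simulate metastasis states by exact stochastic simulation
#'
#' Gillespie simulation of the 4-site seeding chain from the metastasis-free
#' state for a duration equal to each patient's tumor age: exponential
#' waiting times at the current total exit rate, the added site chosen
#' proportionally to its current rate (secondary lung contributions
#' included).
#'
#' @param theta A [rate_vector()], per year.
#' @param ages Tumor ages, years (one simulation per element).
#' @return Integer matrix with columns \code{bone, lung, liver, brain}.
#' @examples
#' set.seed(1)
#' simulate_patient_states(default_theta_true(), c(2.4, 2.9, 4.9))
#' @export
simulate_patient_states <- function(theta, ages) {
  theta <- as_rate_vector(theta)
  stopifnot(all(ages >= 0))
  gillespie_states(as.numeric(ages), as.numeric(theta))
}

#' @rdname simulate_patient_states
#' @param t A single tumor age, years.
#' @return For \code{simulate_patient_state}: a named 0/1 vector of the four
#'   site flags.
#' @export
simulate_patient_state <- function(theta, t) {
  drop(simulate_patient_states(theta, t))
}

#' Generate a synthetic registry-like cohort
#'
#' For each patient: sample a diameter, impute the tumor age from the growth
#' law, simulate the metastasis state from the seeding chain at that age, and
#' draw a subtype (receptor statuses set consistently with it). The result is
#' a prepared [cohort]; provenance records the seed and true rates, making
#' the generator the engine for parametric bootstrap resampling.
#'
#' @param cfg A [sim_config()].
#' @return A prepared [cohort] of \code{cfg$n_patients} records.
#' @examples
#' coh <- generate_cohort(sim_config(100, seed = 7))
#' cohort_summary(coh)$n
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_patients
  diam <- sample_diameters(cfg)
  ages <- withCallingHandlers(
    diameter_to_age(diam, cfg$growth),
    warning = function(w) invokeRestart("muffleWarning"))
  set.seed(cfg$seed + 2L)
  flags <- simulate_patient_states(cfg$theta_true, ages)
  set.seed(cfg$seed + 3L)
  sub <- sample(subtype_levels(), n, replace = TRUE,
                prob = cfg$subtype_weights)
  hr_pos <- startsWith(sub, "HR+")
  df <- data.frame(
    patient_id = sprintf("S%06d", seq_len(n)),
    diameter_mm = diam,
    bone = flags[, "bone"], lung = flags[, "lung"],
    liver = flags[, "liver"], brain = flags[, "brain"],
    er = ifelse(hr_pos, "pos", "neg"),
    pr = ifelse(hr_pos, "pos", "neg"),
    her2 = ifelse(endsWith(sub, "HER2+"), "pos", "neg"),
    subtype = sub,
    state_index = state_index(flags[, "bone"], flags[, "lung"],
                              flags[, "liver"], flags[, "brain"]),
    tumor_age_years = ages,
    stringsAsFactors = FALSE
  )
  as_cohort(df, provenance = list(
    source = "synthetic (seeding-chain simulation)",
    seed = cfg$seed,
    theta_true = as.list(unclass(cfg$theta_true)),
    growth = unclass(cfg$growth),
    n_clamped = sum(3 * log(diam / (cfg$growth$d0_um / 1000)) >=
                      cfg$growth$alpha / cfg$growth$beta)
  ))
}
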