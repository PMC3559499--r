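#' Inhibitor registry
#'
#' Maps each repair inhibitor studied on the minichromosome to its effect
#' on the kinetic model:
#'
#' * NU7441, wortmannin (DNA-PKcs inhibitors): complete arrest of
#'   double-strand-break repair, `s_inh = 0`.
#' * KU55933, caffeine (ATM kinase inhibition): ~30% slower loss of linear
#'   DNA, `hr_factor = 0.70`.
#' * mirin (blocks ATM activation): ~26% slowing, `hr_factor = 0.74`.
#' * Rad51-siRNA (Rad51 depletion): ~20% slowing, `hr_factor = 0.80`.
#' * NU1025, 1,5-IQD (PARP-1), ICRF-193 (topoisomerase II), F11782
#'   (topoisomerases I and II): no significant effect, identity scenario.
#' * none / control: identity scenario.
#'
#' @format Named list of `list(s_inh, hr_factor)` entries.
#' @export
INHIBITOR_REGISTRY <- list(
  none          = list(s_inh = 1, hr_factor = 1),
  control       = list(s_inh = 1, hr_factor = 1),
  NU7441        = list(s_inh = 0, hr_factor = 1),
  wortmannin    = list(s_inh = 0, hr_factor = 1),
  KU55933       = list(s_inh = 1, hr_factor = 0.70),
  caffeine      = list(s_inh = 1, hr_factor = 0.70),
  mirin         = list(s_inh = 1, hr_factor = 0.74),
  `Rad51-siRNA` = list(s_inh = 1, hr_factor = 0.80),
  NU1025        = list(s_inh = 1, hr_factor = 1),
  `1,5-IQD`     = list(s_inh = 1, hr_factor = 1),
  `ICRF-193`    = list(s_inh = 1, hr_factor = 1),
  F11782        = list(s_inh = 1, hr_factor = 1)
)

inhibitor_scenario <- function(name) {
  entry <- INHIBITOR_REGISTRY[[name]]
  if (is.null(entry)) {
    stop("unknown inhibitor/condition '", name, "'; known: ",
         paste(names(INHIBITOR_REGISTRY), collapse = ", "), call. = FALSE)
  }
  scenario(name, s_inh = entry$s_inh, hr_factor = entry$hr_factor)
}

#' Apply an inhibitor to the model
#'
#' Looks an inhibitor up in the registry and returns the corresponding
#' scenario together with the (unchanged) rate constants: inhibitors act
#' through the scenario switch `s_inh` or the `hr_factor` scaling, never
#' by rewriting the fitted rates.
#'
#' @param rates A [rate_constants()] object.
#' @param inhibitor Inhibitor name (see [INHIBITOR_REGISTRY]).
#' @return List with `scenario` and `rates`.
#' @examples
#' apply_inhibitor(rate_constants(0.21, 0.74), "NU7441")$scenario
#' @export
apply_inhibitor <- function(rates, inhibitor) {
  stopifnot(inherits(rates, "repair_rates"))
  list(scenario = inhibitor_scenario(inhibitor), rates = rates)
}

#' Configuration of the synthetic time-course generator
#'
#' Bundles everything needed to emulate a PFGE repair time course: the
#' generating rate constants and initial state, the sampling times,
#' replicate count, additive Gaussian noise level on the fraction scale,
#' the scenarios (conditions), and a seed.
#'
#' @param rates A [rate_constants()] object.
#' @param init Initial [compartment_state()].
#' @param times Sampling times in hours; must include 0.
#' @param n_replicates Replicates per (condition, time, observable).
#' @param noise_sd Gaussian noise standard deviation on the fraction
#'   scale.
#' @param scenarios List of [scenario()] objects, one per condition.
#' @param seed Integer seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(rates, init, times = c(0, 0.5, 1, 1.5, 2),
                             n_replicates = 3, noise_sd = 0.03,
                             scenarios = list(scenario("control")),
                             seed = 1) {
  stopifnot(inherits(rates, "repair_rates"))
  validate_state(init)
  if (!0 %in% times) stop("times must include 0", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE) || any(times < 0)) {
    stop("times must be strictly increasing and >= 0", call. = FALSE)
  }
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!length(scenarios) ||
      !all(vapply(scenarios, inherits, TRUE, "repair_scenario"))) {
    stop("scenarios must be a non-empty list of scenario objects",
         call. = FALSE)
  }
  structure(list(rates = rates, init = init, times = times,
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd, scenarios = scenarios,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Canonical two-condition reference configuration
#'
#' The fixture on which the whole analysis is exercised: tied rates
#' `k_s = k_sd = 0.21` and `k_d = k_ds = 0.74` per hour, initial state
#' dominated by linear molecules still carrying single-strand breaks
#' (`LSSB = 0.95`, `L = 0.05`), and the two conditions actually used for
#' fitting — normal repair (`control`) and DSB-repair arrest (`NU7441`).
#'
#' @param ... Overrides passed to [generator_config()] (e.g. `noise_sd`,
#'   `seed`, `n_replicates`).
#' @return A `generator_config`.
#' @examples
#' reference_config(noise_sd = 0)
#' @export
reference_config <- function(...) {
  defaults <- list(
    rates = rate_constants(k_s = 0.21, k_d = 0.74),
    init = compartment_state(S = 0, L = 0.05, LSSB = 0.95, CSSB = 0),
    scenarios = list(inhibitor_scenario("control"),
                     inhibitor_scenario("NU7441")))
  override <- list(...)
  defaults[names(override)] <- override
  do.call(generator_config, defaults)
}

#' Generate a synthetic measurement table
#'
#' For each scenario the model is solved exactly, the observation operator
#' applied, and i.i.d. Gaussian noise (sd `noise_sd`) added independently
#' to every replicate value, truncated at 0 (band intensities cannot be
#' negative). With `noise_sd = 0` the output is the exact forward model.
#'
#' @param cfg A [generator_config()].
#' @return A validated measurement table (`condition`, `time_h`,
#'   `replicate`, `observable`, `value`).
#' @examples
#' head(generate_dataset(reference_config(noise_sd = 0)))
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  blocks <- lapply(cfg$scenarios, function(scn) {
    obs <- observe(solve_repair(cfg$rates, scn, cfg$init, cfg$times))
    long <- data.frame(
      condition = scn$name,
      time_h = rep(obs$time_h, 2L),
      observable = rep(OBSERVABLES, each = nrow(obs)),
      truth = c(obs$linear_total, obs$supercoiled))
    long[rep(seq_len(nrow(long)), each = cfg$n_replicates), , drop = FALSE]
  })
  tbl <- do.call(rbind, blocks)
  tbl$replicate <- rep_len(seq_len(cfg$n_replicates), nrow(tbl))
  # band fractions cannot be negative; the upper clip keeps rare overshoots
  # of saturated bands inside the validated measurement range
  tbl$value <- with_seed(cfg$seed, {
    pmin(1.1, pmax(0, tbl$truth + stats::rnorm(nrow(tbl), sd = cfg$noise_sd)))
  })
  tbl <- tbl[, c("condition", "time_h", "replicate", "observable", "value")]
  rownames(tbl) <- NULL
  validate_measurements(tbl)
  tbl
}
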