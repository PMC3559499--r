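#' Rate constants of the four-compartment repair model
#'
#' The model tracks four forms of a circular minichromosome after ionising
#' irradiation: supercoiled (`S`), full-length linear (`L`), linear with
#' single-strand breaks (`LSSB`) and nicked circular (`CSSB`). Molecules are
#' transferred between compartments by first-order processes:
#'
#' * `k_d`: repair of the double-strand break in molecules carrying only a
#'   DSB (`L -> S`), per hour;
#' * `k_s`: repair of all single-strand breaks in molecules carrying only
#'   SSBs (`CSSB -> S`), per hour;
#' * `k_ds`: repair of the DSB in molecules carrying both kinds of break
#'   (`LSSB -> CSSB`), per hour;
#' * `k_sd`: repair of all SSBs in molecules carrying both kinds of break
#'   (`LSSB -> L`), per hour.
#'
#' Rates are *fractions of molecules transferred per hour*, not numbers of
#' breaks repaired per hour: a single first-order step moves a molecule with
#' all of its SSBs repaired, so the constants are averages over molecules
#' with different break burdens.
#'
#' With `tied = TRUE` the constraints `k_sd = k_s` and `k_ds = k_d` are
#' enforced; the two-band read-out does not separately identify the four
#' rates (see [identifiability_scan()]), and the tied model is the default.
#'
#' @param k_s,k_sd,k_d,k_ds Non-negative per-hour rate constants. When
#'   `tied = TRUE`, `k_sd` and `k_ds` default to `k_s` and `k_d`.
#' @param tied Logical; enforce `k_s == k_sd` and `k_d == k_ds`.
#' @return An object of class `repair_rates`.
#' @examples
#' rate_constants(k_s = 0.21, k_d = 0.74)
#' @seealso [scenario()], [solve_repair()]
#' @export
rate_constants <- function(k_s, k_d, k_sd = if (tied) k_s else k_sd,
                           k_ds = if (tied) k_d else k_ds, tied = TRUE) {
  k <- c(k_s = k_s, k_sd = k_sd, k_d = k_d, k_ds = k_ds)
  if (!is.numeric(k) || length(k) != 4L || any(!is.finite(k))) {
    stop("rate constants must be four finite numbers", call. = FALSE)
  }
  if (any(k < 0)) {
    stop("rate constants must be >= 0", call. = FALSE)
  }
  if (isTRUE(tied) && (k[["k_s"]] != k[["k_sd"]] || k[["k_d"]] != k[["k_ds"]])) {
    stop("tied rates require k_s == k_sd and k_d == k_ds", call. = FALSE)
  }
  structure(as.list(k), tied = isTRUE(tied), class = "repair_rates")
}

#' @export
print.repair_rates <- function(x, ...) {
  cat("Repair rate constants (per hour)",
      if (attr(x, "tied")) "[tied: k_s = k_sd, k_d = k_ds]", "\n")
  print(unlist(x))
  invisible(x)
}

#' Experimental scenario: DSB-repair arrest and partial HR inhibition
#'
#' A scenario modifies how the rate constants act without changing their
#' fitted values. `s_inh` is a binary switch: 1 under normal repair, 0 when
#' double-strand-break repair is pharmacologically arrested (DNA-PKcs
#' inhibitors NU7441 or wortmannin), which zeroes the effective `k_d` and
#' `k_ds`. `hr_factor` scales `k_d` and `k_ds` multiplicatively to model
#' partial slowing of DSB repair when homologous recombination is
#' suppressed (e.g. ATM inhibition or Rad51 depletion).
#'
#' @param name Scenario label (used as the condition name in measurement
#'   tables).
#' @param s_inh Either 1 (normal) or 0 (DSB repair arrested).
#' @param hr_factor Multiplier in (0, 1] applied to `k_d` and `k_ds`.
#' @return An object of class `repair_scenario`.
#' @examples
#' scenario("control")
#' scenario("NU7441", s_inh = 0)
#' @export
scenario <- function(name, s_inh = 1, hr_factor = 1) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("scenario name must be a non-empty string", call. = FALSE)
  }
  if (!s_inh %in% c(0, 1)) {
    stop("s_inh must be 0 or 1", call. = FALSE)
  }
  if (!is.numeric(hr_factor) || length(hr_factor) != 1L ||
      !is.finite(hr_factor) || hr_factor <= 0 || hr_factor > 1) {
    stop("hr_factor must lie in (0, 1]", call. = FALSE)
  }
  structure(list(name = name, s_inh = as.numeric(s_inh),
                 hr_factor = as.numeric(hr_factor)),
            class = "repair_scenario")
}

#' @export
print.repair_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': s_inh = %g, hr_factor = %g\n",
              x$name, x$s_inh, x$hr_factor))
  invisible(x)
}

#' Compartment state of the minichromosome population
#'
#' Fractions of the total minichromosome DNA (hybridisation signal) in each
#' of the four forms. Fractions must be in \[0, 1\] and sum to 1 (mass
#' conservation) within `1e-9`.
#'
#' @param S,L,LSSB,CSSB Fractions of molecules that are supercoiled,
#'   full-length linear, linear with SSBs, and nicked circular.
#' @return A named numeric vector of class `repair_state`.
#' @examples
#' compartment_state(LSSB = 0.95, L = 0.05)
#' @export
compartment_state <- function(S = 0, L = 0, LSSB = 0, CSSB = 0) {
  x <- c(S = S, L = L, LSSB = LSSB, CSSB = CSSB)
  validate_state(x)
  structure(x, class = "repair_state")
}

validate_state <- function(x) {
  if (!is.numeric(x) || length(x) != 4L || any(!is.finite(x))) {
    stop("state must be four finite fractions", call. = FALSE)
  }
  if (any(x < -1e-12) || any(x > 1 + 1e-12)) {
    stop("compartment fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(x) - 1) > 1e-9) {
    stop(sprintf("compartment fractions must sum to 1 (got %.12f)", sum(x)),
         call. = FALSE)
  }
  invisible(x)
}

# effective kappa_d, kappa_ds after applying the scenario switch/scaling
effective_rates <- function(rates, scn) {
  mod <- scn$s_inh * scn$hr_factor
  list(k_s = rates$k_s, k_sd = rates$k_sd,
       kd = rates$k_d * mod, kds = rates$k_ds * mod)
}

#' Time derivatives of the four compartments
#'
#' Evaluates the right-hand side of the kinetic system at one state. With
#' effective rates `kappa_d = k_d * hr_factor * s_inh` and
#' `kappa_ds = k_ds * hr_factor * s_inh`:
#' \deqn{dS/dt = \kappa_d L + k_s CSSB}
#' \deqn{dL/dt = k_{sd} LSSB - \kappa_d L}
#' \deqn{dLSSB/dt = -(k_{sd} + \kappa_{ds}) LSSB}
#' \deqn{dCSSB/dt = \kappa_{ds} LSSB - k_s CSSB}
#' The four derivatives always sum to zero (no molecules are created or
#' destroyed; repair only interconverts forms).
#'
#' @param state A [compartment_state()].
#' @param rates A [rate_constants()] object.
#' @param scn A [scenario()].
#' @return Named numeric vector of d/dt values in per hour.
#' @examples
#' derivatives(compartment_state(LSSB = 1),
#'             rate_constants(k_s = 0.21, k_d = 0.74),
#'             scenario("control"))
#' @export
derivatives <- function(state, rates, scn) {
  validate_state(state)
  stopifnot(inherits(rates, "repair_rates"), inherits(scn, "repair_scenario"))
  e <- effective_rates(rates, scn)
  c(S    = e$kd * state[["L"]] + e$k_s * state[["CSSB"]],
    L    = e$k_sd * state[["LSSB"]] - e$kd * state[["L"]],
    LSSB = -(e$k_sd + e$kds) * state[["LSSB"]],
    CSSB = e$kds * state[["LSSB"]] - e$k_s * state[["CSSB"]])
}

# (exp(-a t) - exp(-b t)) / (b - a), computed stably via expm1 so that
# near-degenerate rate pairs (b -> a) lose no precision; exact limit t exp(-a t).
exp_diff_ratio <- function(t, a, b) {
  d <- b - a
  if (d == 0) {
    t * exp(-a * t)
  } else {
    exp(-a * t) * (-expm1(-d * t)) / d
  }
}

# closed-form cascade solution; times vector -> matrix [time, compartment]
solve_exact <- function(rates, scn, init, times) {
  e <- effective_rates(rates, scn)
  beta <- e$k_sd + e$kds            # LSSB exit rate
  P0 <- init[["LSSB"]]; L0 <- init[["L"]]; C0 <- init[["CSSB"]]
  lssb <- P0 * exp(-beta * times)
  l <- L0 * exp(-e$kd * times) +
    e$k_sd * P0 * vapply(times, exp_diff_ratio, 0, a = e$kd, b = beta)
  cssb <- C0 * exp(-e$k_s * times) +
    e$kds * P0 * vapply(times, exp_diff_ratio, 0, a = e$k_s, b = beta)
  s <- 1 - lssb - l - cssb
  cbind(S = s, L = l, LSSB = lssb, CSSB = cssb)
}

solve_numeric <- function(rates, scn, init, times, rtol = 1e-9, atol = 1e-12) {
  e <- effective_rates(rates, scn)
  rhs <- function(t, y, p) {
    list(c(e$kd * y[2] + e$k_s * y[4],
           e$k_sd * y[3] - e$kd * y[2],
           -(e$k_sd + e$kds) * y[3],
           e$kds * y[3] - e$k_s * y[4]))
  }
  # lsoda needs the initial time in the grid; prepend times[1] context via 0
  grid <- times
  prepend <- grid[1] > 0
  if (prepend) grid <- c(0, grid)
  out <- deSolve::ode(y = unclass(init), times = grid, func = rhs,
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  m <- out[, c("S", "L", "LSSB", "CSSB"), drop = FALSE]
  if (prepend) m <- m[-1, , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Solve the repair model over a time grid
#'
#' The system is linear with constant coefficients and triangular structure
#' (LSSB feeds L and CSSB, which feed S), so it admits a closed-form
#' cascade-of-exponentials solution; this is the default and is exact up to
#' floating point. A numerical integration route (`deSolve`, lsoda, rtol
#' 1e-9 / atol 1e-12) is provided as an independent cross-check and agrees
#' with the closed form to better than 1e-8.
#'
#' @param rates A [rate_constants()] object.
#' @param scn A [scenario()].
#' @param init Initial [compartment_state()].
#' @param times Sorted vector of times in hours, first element >= 0.
#' @param method `"exact"` (closed form) or `"numeric"` (lsoda).
#' @return A `repair_trajectory`: a data frame with columns `time_h`, `S`,
#'   `L`, `LSSB`, `CSSB`.
#' @examples
#' tr <- solve_repair(rate_constants(k_s = 0.21, k_d = 0.74),
#'                    scenario("control"),
#'                    compartment_state(LSSB = 0.95, L = 0.05),
#'                    times = seq(0, 2, by = 0.5))
#' tr
#' @export
solve_repair <- function(rates, scn, init, times, method = c("exact", "numeric")) {
  method <- match.arg(method)
  stopifnot(inherits(rates, "repair_rates"), inherits(scn, "repair_scenario"))
  validate_state(init)
  if (!is.numeric(times) || length(times) < 1L || any(!is.finite(times))) {
    stop("times must be finite numbers", call. = FALSE)
  }
  if (times[1] < 0 || is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing and >= 0", call. = FALSE)
  }
  m <- switch(method,
              exact = solve_exact(rates, scn, init, times),
              numeric = solve_numeric(rates, scn, init, times))
  if (times[1] == 0) m[1, ] <- unclass(init)  # exact return of init at t = 0
  structure(data.frame(time_h = times, m), class = c("repair_trajectory",
                                                     "data.frame"))
}

#' Observation operator: latent compartments to PFGE bands
#'
#' Pulsed-field gels resolve two quantitated bands: the full-length linear
#' band, in which `L` and `LSSB` co-migrate (`linear_total = L + LSSB`), and
#' the supercoiled band (`supercoiled = S`). Nicked circles (`CSSB`) are not
#' quantitated directly; by conservation
#' `linear_total + supercoiled = 1 - CSSB`.
#'
#' @param traj A `repair_trajectory` from [solve_repair()].
#' @return Data frame with columns `time_h`, `linear_total`, `supercoiled`.
#' @export
observe <- function(traj) {
  stopifnot(inherits(traj, "repair_trajectory"))
  data.frame(time_h = traj$time_h,
             linear_total = traj$L + traj$LSSB,
             supercoiled = traj$S)
}

#' Half-time of a first-order process
#'
#' Converts a per-hour rate constant to the half-time `ln(2)/k`, reported in
#' minutes. Note that first-order half-times of the fitted rate constants
#' need not coincide with half-times read off the raw band intensities,
#' because the rates are per-molecule transfer rates averaged over variable
#' break burdens.
#'
#' @param k Positive per-hour rate constant.
#' @return Half-time in minutes.
#' @examples
#' half_time(0.74)  # ~56.2 min
#' @export
half_time <- function(k) {
  if (!is.numeric(k) || any(!is.finite(k)) || any(k <= 0)) {
    stop("half_time requires k > 0", call. = FALSE)
  }
  log(2) / k * 60
}

#' Average repair time per single-strand break
#'
#' Divides an overall half-time for repairing all SSBs in a molecule by the
#' average number of breaks per molecule, giving the average time spent per
#' break.
#'
#' @param half_time_min Overall SSB-repair half-time in minutes.
#' @param n_breaks Average SSB count per molecule.
#' @return Minutes per break.
#' @examples
#' per_break_repair_time(140, 8.5)  # ~16.5 min/break
#' @export
per_break_repair_time <- function(half_time_min, n_breaks) {
  if (!is.numeric(half_time_min) || half_time_min <= 0) {
    stop("half_time_min must be > 0", call. = FALSE)
  }
  if (!is.numeric(n_breaks) || n_breaks <= 0) {
    stop("n_breaks must be > 0", call. = FALSE)
  }
  half_time_min / n_breaks
}

#' Extrapolate the fitted kinetics over a long horizon
#'
#' Solves the model on a dense grid out to `horizon` hours, assuming the
#' rate constants estimated over the first two hours persist. Under normal
#' repair the nicked-circle pool rises transiently and then drains into
#' supercoiled DNA, which approaches 1; under DSB-repair arrest no nicked
#' circles form from linear molecules and SSB-free linear DNA accumulates.
#'
#' @inheritParams solve_repair
#' @param horizon Positive horizon in hours (default 20).
#' @param n_grid Number of grid points.
#' @return A `repair_trajectory`.
#' @export
extrapolate_repair <- function(rates, scn, init, horizon = 20, n_grid = 401) {
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0) {
    stop("horizon must be > 0", call. = FALSE)
  }
  solve_repair(rates, scn, init, times = seq(0, horizon, length.out = n_grid))
}

#' @export
print.repair_trajectory <- function(x, ...) {
  cat(sprintf("Repair trajectory: %d time points, %.3g-%.3g h\n",
              nrow(x), min(x$time_h), max(x$time_h)))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Plot a repair trajectory
#'
#' @param x A `repair_trajectory`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.repair_trajectory <- function(x, ...) {
  graphics::matplot(x$time_h, as.matrix(x[, c("S", "L", "LSSB", "CSSB")]),
                    type = "l", lty = 1, lwd = 2,
                    col = c("black", "firebrick", "darkorange", "steelblue"),
                    xlab = "time (h)", ylab = "fraction of minichromosome DNA",
                    ylim = c(0, 1), ...)
  graphics::legend("right", legend = c("S", "L", "LSSB", "CSSB"), lty = 1,
                   lwd = 2, col = c("black", "firebrick", "darkorange",
                                    "steelblue"), bty = "n")
  invisible(x)
}
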