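test_that("derivatives implement the compartment topology and conserve mass", {
  r <- ref_rates()
  ctrl <- scenario("control")
  arrest <- scenario("NU7441", s_inh = 0)

  # supercoiled is absorbing
  d <- derivatives(compartment_state(S = 1), r, ctrl)
  expect_equal(unname(d), c(0, 0, 0, 0))

  # with DSB repair arrested, pure-L has no exit
  d <- derivatives(compartment_state(L = 1), r, arrest)
  expect_equal(unname(d), c(0, 0, 0, 0))

  # all-LSSB state: hand arithmetic at the published rates
  d <- derivatives(compartment_state(LSSB = 1), r, ctrl)
  expect_equal(d[["LSSB"]], -0.95)
  expect_equal(d[["L"]], 0.21)
  expect_equal(d[["CSSB"]], 0.74)
  expect_equal(d[["S"]], 0)

  # mass conservation of the vector field on random states
  set.seed(42)
  for (i in 1:20) {
    st <- random_setup()
    expect_equal(sum(derivatives(st$init, st$rates, ctrl)), 0,
                 tolerance = 1e-12)
  }

  expect_error(rate_constants(k_s = -0.1, k_d = 1), ">= 0")
  expect_error(compartment_state(S = 0.5, L = 0.6), "sum to 1")
  expect_error(scenario("x", s_inh = 0.5), "s_inh")
  expect_error(scenario("x", hr_factor = 0), "hr_factor")
})

test_that("closed-form solution matches hand-derived cascade values", {
  r <- ref_rates()
  init <- compartment_state(LSSB = 1)
  tr <- solve_repair(r, scenario("control"), init, times = c(0, 1))
  expect_equal(tr$LSSB[2], exp(-0.95), tolerance = 1e-12)
  expect_equal(tr$L[2], exp(-0.74) - exp(-0.95), tolerance = 1e-12)

  # DSB repair arrested: L(2h) = 1 - exp(-k_sd * 2)
  tr0 <- solve_repair(r, scenario("NU7441", s_inh = 0), init, times = c(0, 2))
  expect_equal(tr0$L[2], 1 - exp(-0.42), tolerance = 1e-12)
  expect_equal(tr0$CSSB[2], 0)

  # t = 0 returns the initial state exactly
  tr1 <- solve_repair(r, scenario("control"), ref_init(), times = 0)
  expect_identical(unname(unlist(tr1[1, c("S", "L", "LSSB", "CSSB")])),
                   unname(unclass(ref_init())))

  expect_error(solve_repair(r, scenario("control"), init, times = c(1, 0.5)),
               "increasing")
  expect_error(solve_repair(r, scenario("control"), init, times = -1), ">= 0")
})

test_that("exact and numerical solutions agree on random draws", {
  set.seed(7)
  ctrl <- scenario("control")
  times <- seq(0, 4, by = 0.25)
  for (i in 1:25) {
    st <- random_setup()
    scn <- if (i %% 3 == 0) scenario("NU7441", s_inh = 0) else ctrl
    a <- solve_repair(st$rates, scn, st$init, times, method = "exact")
    b <- solve_repair(st$rates, scn, st$init, times, method = "numeric")
    expect_lt(max(abs(as.matrix(a[, -1]) - as.matrix(b[, -1]))), 1e-8)
  }
  # near-degenerate rate pair must not lose precision to cancellation
  r <- rate_constants(k_s = 0.5, k_sd = 0.5 + 1e-9, k_d = 1, k_ds = 1,
                      tied = FALSE)
  a <- solve_repair(r, ctrl, compartment_state(LSSB = 1), times)
  b <- solve_repair(r, ctrl, compartment_state(LSSB = 1), times,
                    method = "numeric")
  expect_lt(max(abs(as.matrix(a[, -1]) - as.matrix(b[, -1]))), 1e-8)
})

test_that("trajectories conserve mass, stay nonnegative, and are monotone", {
  set.seed(11)
  times <- seq(0, 20, by = 0.5)
  for (i in 1:25) {
    st <- random_setup()
    scn <- scenario("s", s_inh = i %% 2, hr_factor = stats::runif(1, 0.5, 1))
    tr <- solve_repair(st$rates, scn, st$init, times)
    m <- as.matrix(tr[, c("S", "L", "LSSB", "CSSB")])
    expect_lt(max(abs(rowSums(m) - 1)), 1e-9)
    expect_gt(min(m), -1e-12)
    expect_true(all(diff(tr$LSSB) <= 1e-12))   # LSSB only drains
    expect_true(all(diff(tr$S) >= -1e-12))     # S only accumulates
  }
})

test_that("the arrest switch is continuous in k_ds -> 0", {
  times <- seq(0, 2, by = 0.1)
  init <- ref_init()
  on_tiny <- solve_repair(
    rate_constants(k_s = 0.21, k_sd = 0.21, k_d = 1e-12, k_ds = 1e-12,
                   tied = FALSE),
    scenario("control"), init, times)
  off <- solve_repair(ref_rates(), scenario("NU7441", s_inh = 0), init, times)
  expect_equal(on_tiny$LSSB, off$LSSB, tolerance = 1e-9)
  expect_equal(on_tiny$L, off$L, tolerance = 1e-9)
})

test_that("observation operator maps compartments to the two PFGE bands", {
  tr <- structure(data.frame(time_h = 0, S = 0.3, L = 0.2, LSSB = 0.4,
                             CSSB = 0.1),
                  class = c("repair_trajectory", "data.frame"))
  obs <- observe(tr)
  expect_equal(obs$linear_total, 0.6)
  expect_equal(obs$supercoiled, 0.3)

  # conservation identity along a real trajectory
  traj <- solve_repair(ref_rates(), scenario("control"), ref_init(),
                       seq(0, 2, 0.25))
  o <- observe(traj)
  expect_equal(o$linear_total + o$supercoiled, 1 - traj$CSSB,
               tolerance = 1e-12)
  expect_true(all(o$linear_total <= 1 & o$supercoiled <= 1))
})

test_that("half-times and per-break times follow first-order arithmetic", {
  expect_equal(half_time(0.74), log(2) / 0.74 * 60, tolerance = 1e-12)
  expect_equal(round(half_time(0.74), 1), 56.2)
  expect_equal(round(half_time(0.21), 1), 198.0)
  expect_equal(half_time(log(2)), 60)
  expect_error(half_time(0), "k > 0")
  expect_equal(per_break_repair_time(140, 8.5), 140 / 8.5)
  expect_error(per_break_repair_time(140, 0), "> 0")
})

test_that("20 h extrapolation reproduces the predicted qualitative shapes", {
  r <- ref_rates()
  init <- compartment_state(LSSB = 1)
  ctrl <- extrapolate_repair(r, scenario("control"), init, horizon = 20)
  # nicked circles rise transiently, then drain; supercoiled nearly complete
  i_max <- which.max(ctrl$CSSB)
  expect_gt(i_max, 1)
  expect_lt(i_max, nrow(ctrl))
  expect_lt(ctrl$CSSB[nrow(ctrl)], max(ctrl$CSSB))
  expect_gt(ctrl$S[nrow(ctrl)], 0.95)

  arr <- extrapolate_repair(r, scenario("NU7441", s_inh = 0), init,
                            horizon = 20)
  expect_true(all(arr$CSSB == 0))               # no inflow to nicked circles
  expect_true(all(diff(arr$L) >= 0))            # SSB-free linear accumulates
  expect_gt(arr$L[nrow(arr)], 0.98)
  expect_error(extrapolate_repair(r, scenario("control"), init, horizon = -1),
               "> 0")
})
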