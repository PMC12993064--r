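test_that("synaptic current follows the exponential-kernel sum", {
  expect_equal(synaptic_current(0.5, numeric(0)), 0)
  expect_equal(synaptic_current(1.0, spike_times = 1.0, I0 = 0.1), 0.1)
  expect_equal(synaptic_current(1e-3, spike_times = 0, I0 = 0.1, tau_d = 1e-3),
               0.1 * exp(-1), tolerance = 1e-12)
  # superposition of two spikes
  expect_equal(synaptic_current(0.02, spike_times = c(0, 0.01),
                                I0 = 0.1, tau_d = 1e-3),
               0.1 * (exp(-20) + exp(-10)), tolerance = 1e-12)
  expect_error(synaptic_current(1, c(2, 1)), "sorted")
})

test_that("an all-zero state with no input is a fixed point", {
  arr <- two_spine_arrangement(1)
  st <- calcium_state(rep(0, arr$geometry$n_segments), c(0, 0))
  out <- step_calcium(st, c(0, 0), arr, default_parameters())
  expect_equal(out$C_d, st$C_d)
  expect_equal(out$C_s, st$C_s)
})

test_that("uniform decay matches the implicit-step closed form", {
  p <- default_parameters()
  arr <- spine_arrangement(geometry(10, 0.5), integer(0))
  st <- calcium_state(rep(1, 20), numeric(0))
  cfg <- solver_config(dt = 1e-4)
  out <- step_calcium(st, numeric(0), arr, p, cfg)
  expect_equal(out$C_d, rep(1 / (1 + 1e-4 / 0.08), 20), tolerance = 1e-12)
})

test_that("Neumann diffusion conserves total calcium to 1e-10", {
  p <- default_parameters(); p$tau_decay <- Inf
  geom <- geometry(80, 0.5)
  arr <- spine_arrangement(geom, integer(0))
  C0 <- rep(0, geom$n_segments); C0[80] <- 1
  sim <- simulate_calcium(protocol(list(), 1, 1), arr, p, T = 0.02,
                          cfg = solver_config(dt = 2e-5, store_every = 500),
                          plasticity = FALSE,
                          initial_state = calcium_state(C0, numeric(0)))
  mass <- rowSums(sim$C_d) * geom$dx
  expect_lt(max(abs(mass - mass[1])) / mass[1], 1e-10)
})

test_that("an impulse matches the Gaussian Green's function to <2% of peak", {
  geom <- geometry(80, 0.5)
  arr <- spine_arrangement(geom, integer(0))
  C0 <- rep(0, geom$n_segments); C0[80] <- 1
  x <- segment_centers(geom); x0 <- x[80]; t_end <- 0.02
  run <- function(tau) {
    p <- default_parameters(); p$tau_decay <- tau
    sim <- simulate_calcium(protocol(list(), 1, 1), arr, p, T = t_end,
                            cfg = solver_config(dt = 2e-5, store_every = 1000),
                            plasticity = FALSE,
                            initial_state = calcium_state(C0, numeric(0)))
    sim$C_d[nrow(sim$C_d), ]
  }
  gauss <- 0.5 * exp(-(x - x0)^2 / (4 * 220 * t_end)) /
    sqrt(4 * pi * 220 * t_end)
  num <- run(Inf)
  expect_lt(max(abs(num - gauss)) / max(gauss), 0.02)
  # with leak: the same Gaussian damped by exp(-t/tau_decay)
  num_decay <- run(0.08)
  expect_lt(max(abs(num_decay - gauss * exp(-t_end / 0.08))) / max(gauss),
            0.02)
})

test_that("with D = 0 the stimulated spine follows the isolated closed form", {
  p <- default_parameters(); p$D <- 0
  arr <- two_spine_arrangement(1)
  cfg <- solver_config(dt = 5e-6, store_every = 200)
  sim <- simulate_calcium(single_spike(1, repetitions = 1), arr, p, T = 0.2,
                          cfg = cfg, plasticity = FALSE)
  A <- synaptic_calcium_flux(p$I0, p)
  a <- 1 / p$tau_d; b <- 1 / p$tau_decay
  expected <- A * (exp(-b * sim$t) - exp(-a * sim$t)) / (a - b)
  expect_lt(max(abs(sim$C_s[, 1] - expected)) / max(expected), 5e-3)
  expect_equal(max(sim$C_s[, 2]), 0)   # no route to the neighbour
})

test_that("concentrations stay non-negative for random protocols", {
  set.seed(11)
  arr <- generate_arrangement(5)
  for (k in 1:3) {
    ids <- sample(16, 3)
    prot <- protocol(setNames(lapply(ids, function(i) sort(runif(3, 0, 0.2))),
                              as.character(ids)), repetitions = 1)
    sim <- simulate_calcium(prot, arr, default_parameters("fig3"), T = 0.4,
                            cfg = solver_config(store_every = 50))
    expect_true(all(sim$C_d >= 0))
    expect_true(all(sim$C_s >= 0))
  }
})

test_that("volume-corrected mode conserves moles across the spine neck", {
  p <- default_parameters(); p$tau_decay <- Inf
  geom <- geometry(20, 0.5)
  arr <- spine_arrangement(geom, c(10, 25))
  vol <- compartment_volumes(p, geom$dx)
  st <- calcium_state(rep(0, geom$n_segments), c(1, 0.5))
  cfg <- solver_config(dt = 5e-5, store_every = 100,
                       flux_mode = "volume-corrected")
  sim <- simulate_calcium(protocol(list(), 1, 1), arr, p, T = 0.05, cfg = cfg,
                          plasticity = FALSE, initial_state = st)
  fin <- sim$final_state
  moles <- function(cd, cs) sum(cd) * vol$V_d + sum(cs) * vol$V_s
  expect_equal(moles(fin$C_d, fin$C_s), moles(st$C_d, st$C_s),
               tolerance = 1e-10)
})

test_that("halving dt leaves final weights essentially unchanged", {
  arr <- two_spine_arrangement(1)
  p <- default_parameters("fig2", gamma_p = 1, gamma_d = 0.5)  # moderate rates
  run <- function(dt) {
    simulate_calcium(paired_timing(1, 2, 0.015, repetitions = 2), arr, p,
                     T = 1.6, cfg = fast_cfg(dt = dt))$final_weights
  }
  w1 <- run(5e-5); w2 <- run(2.5e-5)
  expect_lt(max(abs(w1 - w2) / w1), 1e-3)
})

test_that("a single spike peaks at the stimulated spine before its neighbour", {
  arr <- two_spine_arrangement(1)
  sim <- simulate_calcium(single_spike(1, repetitions = 1), arr,
                          default_parameters(), T = 0.3,
                          cfg = solver_config(store_every = 10))
  expect_gt(max(sim$C_s[, 1]), max(sim$C_s[, 2]))
  expect_lt(sim$t[which.max(sim$C_s[, 1])], sim$t[which.max(sim$C_s[, 2])])
})

test_that("simulation input contracts are enforced", {
  arr <- two_spine_arrangement(1)
  p <- default_parameters()
  expect_error(simulate_calcium(single_spike(1), arr, p, T = 1),
               "within \\[0, T\\]")
  expect_error(simulate_calcium(single_spike(5, repetitions = 1), arr, p,
                                T = 1), "unknown spine")
  expect_error(solver_config(dt = 0), "dt")
  expect_error(step_calcium(calcium_state(rep(0, 10), c(0, 0)), c(0, 0),
                            arr, p), "match the arrangement")
  expect_error(simulate_calcium(single_spike(1, repetitions = 1), arr, p,
                                T = 1, cfg = solver_config(dt = 5e-3)),
               "tau_d/5")
})

test_that("long-format CSV export is parseable and complete", {
  arr <- two_spine_arrangement(1)
  sim <- simulate_calcium(single_spike(1, repetitions = 1), arr,
                          default_parameters(), T = 0.1,
                          cfg = solver_config(store_every = 500))
  path <- tempfile(fileext = ".csv")
  write_simulation_csv(sim, path)
  df <- read.csv(path)
  expect_setequal(unique(df$variable), c("C_s", "w", "C_d"))
  expect_equal(sum(df$variable == "C_d"),
               length(sim$t) * arr$geometry$n_segments)
})
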