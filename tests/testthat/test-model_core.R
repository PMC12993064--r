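test_that("default parameters carry the standard physical constants", {
  p <- default_parameters()
  expect_equal(p$D, 220)
  expect_equal(p$tau_decay, 0.08)
  expect_equal(p$l_n, 0.5)
  expect_equal(p$a_s, 0.1)
  expect_equal(p$r_s, 0.34)
  expect_equal(p$r_d, 1)
  expect_equal(p$gamma, 0.11)
  expect_equal(p$z, 2)
  expect_equal(p$F, 96485)
  expect_equal(p$I0, 0.1)
  expect_equal(p$tau_d, 1e-3)
  # two-spine preset thresholds
  expect_equal(p$theta_d, 2e-3)
  expect_equal(p$theta_p, 4e-3)
})

test_that("parameter validation enforces the invariants", {
  expect_error(model_parameters(D = -1), "D")
  expect_error(model_parameters(gamma = 0), "gamma")
  expect_error(model_parameters(gamma = 1.2), "gamma")
  expect_error(model_parameters(theta_d = 5e-3, theta_p = 4e-3), "theta")
  expect_error(model_parameters(tau_decay = 0), "tau_decay")
  expect_s3_class(default_parameters("fig3"), "ca_parameters")
  ps <- plasticity_presets()
  expect_setequal(names(ps), c("fig2", "fig3", "fig4-grid"))
})

test_that("compartment volumes follow the cylinder/sphere formulas", {
  p <- default_parameters()
  v <- compartment_volumes(p, dx = 1)
  expect_equal(v$V_d, pi, tolerance = 1e-12)             # pi * 1^2 * 1
  expect_equal(v$V_s, 4 / 3 * pi * 0.34^3, tolerance = 1e-12)
  expect_equal(v$V_s, 0.16462, tolerance = 1e-4)
  # degenerate limit: V_d ~ r_d^2
  p2 <- default_parameters(); p2$r_d <- 1e-6
  expect_lt(compartment_volumes(p2, 1)$V_d, 1e-11)
  expect_error(compartment_volumes(p, dx = 0), "dx")
})

test_that("coupling rates match the mean-first-passage arithmetic", {
  p <- default_parameters()
  r <- coupling_rates(p, dx = 1)
  expect_equal(r$k_d, 88 / pi, tolerance = 1e-9)
  tau_prime <- (4 / 3 * pi * 0.34^3) / 88 + 0.25 / 440
  expect_equal(r$k_s, 1 / tau_prime, tolerance = 1e-9)
  expect_equal(r$k_s, 410.0, tolerance = 1e-3)
  # D = 0: both rates vanish, flagged as isolated
  p0 <- default_parameters(); p0$D <- 0
  r0 <- coupling_rates(p0, dx = 1)
  expect_equal(r0$k_d, 0)
  expect_equal(r0$k_s, 0)
  expect_true(attr(r0, "isolated"))
})

test_that("k_d * V_d is discretization-independent and rates increase with D", {
  p <- default_parameters()
  for (dx in c(0.1, 0.25, 0.5, 1, 2)) {
    r <- coupling_rates(p, dx)
    v <- compartment_volumes(p, dx)
    expect_equal(r$k_d * v$V_d, 4 * p$D * p$a_s, tolerance = 1e-12)
  }
  Ds <- c(1, 30, 140, 220, 440)
  ks <- sapply(Ds, function(D) {
    p$D <- D; unlist(coupling_rates(p, 0.5))
  })
  expect_true(all(diff(ks["k_d", ]) > 0))
  expect_true(all(diff(ks["k_s", ]) > 0))
})

test_that("current-to-flux conversion gives ~346 uM/s for 0.1 pA", {
  p <- default_parameters()
  # independent SI-unit arithmetic: A / (C/mol * L) -> mol/L/s -> uM/s
  V_s_l <- 4 / 3 * pi * 0.34^3 * 1e-15
  expected <- 0.11 * 0.1e-12 / (2 * 96485 * V_s_l) * 1e6
  expect_equal(synaptic_calcium_flux(0.1, p), expected, tolerance = 1e-12)
  expect_equal(synaptic_calcium_flux(0.1, p), 346.2, tolerance = 1e-3)
  expect_equal(synaptic_calcium_flux(0, p), 0)
  expect_equal(synaptic_calcium_flux(0.2, p),
               2 * synaptic_calcium_flux(0.1, p))
})

test_that("generated arrangements satisfy every stated constraint", {
  for (seed in 1:25) {
    arr <- generate_arrangement(seed)
    expect_equal(n_spines(arr), 16)
    tab <- table(arr$groups)
    expect_equal(unname(tab["Stim"]), 7)
    expect_equal(unname(tab["Un_in"]), 3)
    expect_equal(unname(tab["Un_out"]), 6)
    pos <- spine_positions(arr)
    inside <- pos > arr$cluster$start_um &
      pos < arr$cluster$start_um + arr$cluster$length_um
    expect_equal(sum(inside), 10)                 # 7 Stim + 3 Un_in confined
    expect_true(all(arr$groups[inside] %in% c("Stim", "Un_in")))
    out_pos <- pos[arr$groups == "Un_out"]
    expect_gte(sum(out_pos < arr$cluster$start_um), 3)
    expect_gte(sum(out_pos > arr$cluster$start_um + arr$cluster$length_um), 3)
    expect_true(all(arr$initial_weights >= 0.3 & arr$initial_weights <= 0.7))
    expect_equal(cluster_density(arr), 10 / 7, tolerance = 1e-12)
  }
})

test_that("the generator is deterministic and leaves the caller's RNG alone", {
  a1 <- generate_arrangement(42)
  set.seed(7); x_before <- runif(1)
  a2 <- generate_arrangement(42)
  set.seed(7); x_after <- runif(1)
  expect_identical(a1, a2)
  expect_identical(x_before, x_after)
})

test_that("unsatisfiable constraints raise a generation error", {
  cfg <- arrangement_config(length = 8, cluster_length = 7)
  expect_error(generate_arrangement(1, cfg), "generation error")
  expect_error(generate_arrangement(1, arrangement_config(n_spines = 12)),
               "outer spines")
})

test_that("arrangements round-trip through JSON", {
  arr <- generate_arrangement(3)
  path <- tempfile(fileext = ".json")
  write_arrangement(arr, path)
  back <- read_arrangement(path)
  expect_equal(back$spine_segments, arr$spine_segments)
  expect_equal(back$groups, arr$groups)
  expect_equal(back$initial_weights, arr$initial_weights, tolerance = 1e-12)
  expect_equal(back$cluster$start_um, arr$cluster$start_um)
})

test_that("arrangement validation rejects bad inputs", {
  g <- geometry(10, 0.5)
  expect_error(spine_arrangement(g, c(3, 3)), "one spine per segment")
  expect_error(spine_arrangement(g, 25), "within the geometry")
  expect_error(spine_arrangement(g, 3, groups = "Weird"), "unknown group")
  expect_error(spine_arrangement(g, 3, initial_weights = 1.5), "\\[0, 1\\]")
  expect_error(geometry(10, 0.3), "integer multiple")
})
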