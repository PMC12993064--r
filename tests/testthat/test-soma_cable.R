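test_that("the somatic integrator has the correct fixed points", {
  p <- soma_params()
  expect_equal(step_soma(-70, -70, 1e-4, p), -70, tolerance = 1e-12)
  # dendrite clamped at -58 mV: steady state (-70 + 5 * -58) / 6 = -60 mV
  u <- -70
  for (k in 1:5000) u <- step_soma(u, -58, 1e-4, p)
  expect_equal(u, (-70 + 5 * -58) / 6, tolerance = 1e-9)
})

test_that("the soma relaxes with effective time constant tau/(1+R_ratio)", {
  p <- soma_params()
  dt <- 1e-5
  u <- -60  # displaced, dendrite at rest
  us <- numeric(2000)
  for (k in seq_along(us)) { u <- step_soma(u, p$u_rest, dt, p); us[k] <- u }
  # log-linear decay rate of the deviation
  dev <- us - p$u_rest
  rate <- -coef(lm(log(dev) ~ seq_along(dev)))[2] / dt
  expect_equal(unname(rate), (1 + p$R_ratio) / p$tau, tolerance = 1e-2)
})

test_that("the passive cable rests without input and decays monotonically from a source", {
  arr <- spine_arrangement(geometry(20, 0.5), c(10, 30))
  cab <- cable_params()
  st <- cable_state(rep(-70, 40), -70)
  out <- step_cable(st, c(0, 0), arr, 1e-4, cab)
  expect_equal(out$u_dend, rep(-70, 40), tolerance = 1e-12)
  expect_equal(out$u_soma, -70, tolerance = 1e-12)
  # steady injection at segment 10: monotone spatial decay on both sides
  for (k in 1:3000) st <- step_cable(st, c(0.05, 0), arr, 1e-4, cab)
  prof <- st$u_dend
  expect_true(all(diff(prof[1:10]) > 0))
  expect_true(all(diff(prof[10:40]) < 0))
  # mirrored arrangement gives the mirrored profile
  arr_m <- spine_arrangement(geometry(20, 0.5), c(11, 31))
  st_m <- cable_state(rep(-70, 40), -70)
  for (k in 1:3000) st_m <- step_cable(st_m, c(0, 0.05), arr_m, 1e-4, cab)
  expect_equal(st_m$u_dend, rev(prof), tolerance = 1e-9)
})

test_that("the compiled voltage path agrees with the R cable stepper", {
  arr <- spine_arrangement(geometry(20, 0.5), c(10, 30),
                           initial_weights = c(0.6, 0.4))
  p <- default_parameters()
  cab <- cable_params(); som <- soma_params()
  dt <- 1e-4
  prot <- paired_timing(1, 2, 0.002, repetitions = 1)
  sim <- simulate_with_soma(prot, arr, p, T = 0.01,
                            cfg = solver_config(dt = dt, store_every = 1,
                                                store_field = FALSE),
                            plasticity = FALSE, soma = som, cable = cab)
  spikes <- expand_protocol(prot, 2)
  st <- cable_state(rep(cab$u_rest, 40), som$u_rest)
  usoma_r <- numeric(length(sim$t)); usoma_r[1] <- som$u_rest
  for (n in seq_len(length(sim$t) - 1)) {
    t_n <- (n - 1) * dt
    inputs <- arr$initial_weights *
      c(synaptic_current(t_n, spikes[[1]], p$I0, p$tau_d),
        synaptic_current(t_n, spikes[[2]], p$I0, p$tau_d))
    st <- step_cable(st, inputs, arr, dt, cab, som)
    usoma_r[n + 1] <- st$u_soma
  }
  expect_equal(sim$u_soma, usoma_r, tolerance = 1e-9)
})

test_that("voltage stays bounded between rest and the drive maximum", {
  rep <- sequence_experiment("inward", plasticity = FALSE)
  for (tr in rep$u_soma) {
    expect_true(all(tr >= -70 - 1e-9))
    expect_true(all(tr < 0))
  }
})

test_that("zero-amplitude input gives equal peaks and ratio 1", {
  p <- default_parameters("fig2"); p$I0 <- 1e-300
  rep <- sequence_experiment("inward", params = p, plasticity = FALSE)
  expect_equal(unname(rep$test_peaks["inward"]), -70, tolerance = 1e-9)
  expect_equal(unname(rep$test_peaks["outward"]), -70, tolerance = 1e-9)
  expect_equal(rep$ratio, 1, tolerance = 1e-6)
})

test_that("sequence experiment rejects non two-spine layouts", {
  expect_error(sequence_experiment("inward", arrangement = generate_arrangement(1)),
               "two-spine")
})

test_that("sequence reports serialize to JSON", {
  rep <- sequence_experiment("inward", plasticity = FALSE)
  path <- tempfile(fileext = ".json")
  write_sequence_report(rep, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$learned_order, "inward")
  expect_length(obj$test_peaks, 2)
  expect_true(is.numeric(obj$ratio))
})
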