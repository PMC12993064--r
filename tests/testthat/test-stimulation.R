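test_that("single-spike protocols have one spike per presentation", {
  prot <- single_spike(1)
  ex <- expand_protocol(prot, 2)
  expect_length(ex[[1]], 5)
  expect_length(ex[[2]], 0)
  expect_equal(diff(ex[[1]]), rep(1, 4))     # spaced by the repetition interval
  expect_length(expand_protocol(single_spike(1, repetitions = 1), 2)[[1]], 1)
})

test_that("burst spacing and degenerate cases are correct", {
  ex <- expand_protocol(burst(1, n_spikes = 4, isi = 0.01, repetitions = 1), 1)
  expect_equal(ex[[1]], c(0, 0.01, 0.02, 0.03))   # spans 30 ms
  expect_equal(expand_protocol(burst(2, n_spikes = 1, repetitions = 5), 2),
               expand_protocol(single_spike(2), 2))
  expect_length(expand_protocol(burst(1, 3, 0.01, repetitions = 2), 1)[[1]], 6)
  expect_error(burst(1, n_spikes = 0), "n_spikes")
})

test_that("paired timing places and reverses the two spikes", {
  ex <- expand_protocol(paired_timing(1, 2, 0.015, repetitions = 1), 2)
  expect_equal(ex[[2]] - ex[[1]], 0.015)
  ex0 <- expand_protocol(paired_timing(1, 2, 0, repetitions = 1), 2)
  expect_equal(ex0[[1]], ex0[[2]])
  exm <- expand_protocol(paired_timing(1, 2, -0.015, repetitions = 1), 2)
  expect_equal(exm[[1]] - exm[[2]], 0.015)     # order reversed
  expect_error(paired_timing(3, 3, 0.01), "distinct")
})

test_that("paired_timing(a,b,dt) equals paired_timing(b,a,-dt) after relabelling", {
  p1 <- paired_timing(1, 2, 0.02)
  p2 <- remap_protocol(paired_timing(2, 1, -0.02), c(1, 2))
  expect_equal(expand_protocol(p1, 2), expand_protocol(p2, 2))
})

test_that("triplet structure follows its timing contract", {
  ex <- expand_protocol(triplet(1, 2, 0.012, repetitions = 1), 2)
  expect_equal(diff(ex[[1]]), 0.02)               # default inter-input 20 ms
  expect_equal(ex[[2]] - ex[[1]][1], 0.012)       # referenced to first spike
  ex0 <- expand_protocol(triplet(1, 2, 0, repetitions = 1), 2)
  expect_equal(ex0[[2]], ex0[[1]][1])
  expect_error(triplet(1, 1, 0.01), "distinct")
  expect_error(triplet(1, 2, 0.01, inter_input = 0), "inter_input")
})

test_that("frequency protocols are synchronous and regularly spaced", {
  prot <- frequency_protocol(c(1, 3), rate = 1, n_pulses = 5)
  ex <- expand_protocol(prot, 3)
  expect_equal(ex[[1]], 0:4)
  expect_identical(ex[[1]], ex[[3]])
  expect_length(ex[[2]], 0)
  # doubling the rate halves the span
  span <- function(r) max(expand_protocol(
    frequency_protocol(1, r, 5), 1)[[1]])
  expect_equal(span(2), span(1) / 2)
  expect_error(frequency_protocol(integer(0), 1), "non-empty")
  fp <- frequency_presets()
  expect_setequal(names(fp), c("low", "medium", "high"))
  expect_lt(fp$low$rate, fp$medium$rate)
  expect_lt(fp$medium$rate, fp$high$rate)
})

test_that("all generated protocols expand to sorted non-negative times", {
  set.seed(21)
  protos <- list(single_spike(2), burst(1, 3, 0.004),
                 paired_timing(2, 1, -0.05), triplet(1, 2, -0.03),
                 frequency_protocol(1:3, 17, 7))
  for (prot in protos) {
    ex <- expand_protocol(prot, 3)
    for (v in ex) {
      expect_true(all(v >= 0))
      expect_false(is.unsorted(v))
    }
  }
})

test_that("protocols round-trip losslessly through JSON", {
  protos <- list(single_spike(1), burst(2, 3, 0.007),
                 triplet(1, 2, -0.02, 0.025), frequency_protocol(c(2, 3), 40, 4))
  for (prot in protos) {
    path <- tempfile(fileext = ".json")
    write_protocol(prot, path)
    back <- read_protocol(path)
    expect_equal(back$spikes, prot$spikes, tolerance = 1e-12)
    expect_equal(back$repetitions, prot$repetitions)
    expect_equal(back$repetition_interval, prot$repetition_interval)
  }
})
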