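test_that("the cortical example has the reference structure", {
  spec <- build_cortical_example(J = 1.4, g = 4)
  expect_identical(nrow(validate_model(spec)), 0L)
  expect_identical(resolve_attribute(spec$populations[[1]]$number)$value,
                   10000)
  expect_identical(resolve_attribute(spec$populations[[2]]$number)$value,
                   2500)
  # PSP amplitudes J on AMPA and g*J on GABA, common 0.5 ms rise time
  for (p in spec$populations) {
    ampa <- p$receptors[[1]]
    gaba <- p$receptors[[2]]
    expect_identical(resolve_attribute(ampa$psp_amplitude_mv)$value, 1.4)
    expect_identical(resolve_attribute(gaba$psp_amplitude_mv)$value, 5.6)
    expect_identical(resolve_attribute(ampa$rise_time_ms)$value, 0.5)
  }
  sim <- spec$simulations[[1]]
  expect_identical(sim$dt_ms, 0.1)
  expect_identical(sim$duration_ms, 2000)
  expect_identical(sim$stimuli[[1]]$stop_ms, 1000)
})

test_that("changing J alters only the PSP-amplitude entries", {
  a <- build_cortical_example(J = 1.1, g = 4)
  b <- build_cortical_example(J = 1.4, g = 4)
  # align the receptor amplitudes, then the specs must be identical
  for (i in seq_along(a$populations)) {
    for (j in seq_along(a$populations[[i]]$receptors)) {
      a$populations[[i]]$receptors[[j]]$psp_amplitude_mv <-
        b$populations[[i]]$receptors[[j]]$psp_amplitude_mv
    }
  }
  expect_identical(save_model(a), save_model(b))
})

test_that("the striatal example matches its printed specification", {
  spec <- build_striatal_example()
  expect_identical(nrow(validate_model(spec)), 0L)
  counts <- vapply(spec$populations, function(p)
    resolve_attribute(p$number)$value, numeric(1))
  names(counts) <- vapply(spec$populations, `[[`, character(1), "name")
  expect_identical(counts,
                   c(dSPN = 38237, iSPN = 38237, FS = 1047, LTS = 644,
                     ChIN = 886))
  # generic 0.2 ms delay on every connection
  for (pr in spec$projections)
    expect_identical(resolve_attribute(pr$delay_ms)$value, 0.2)
  # two-stage stimulation: continuing 300 Hz baseline, 1200 Hz overlay
  sim <- spec$simulations[[1]]
  rates <- vapply(sim$stimuli, `[[`, numeric(1), "rate_hz")
  starts <- vapply(sim$stimuli, `[[`, numeric(1), "start_ms")
  stops <- vapply(sim$stimuli, `[[`, numeric(1), "stop_ms")
  expect_identical(sort(unique(rates)), c(300, 1200))
  expect_true(all(stops[rates == 300] == 1500))   # baseline continues
  expect_true(all(starts[rates == 1200] == 1000))
  expect_identical(sim$space_dim, 3)
})

test_that("every fixture builds and emits end-to-end", {
  for (spec in list(build_cortical_example(), build_striatal_example())) {
    expect_identical(nrow(validate_model(spec)), 0L)
    real <- realize_model(spec, scale = 1, seed = 1)
    s <- emit_script(real)
    expect_gt(nchar(s), 1000)
  }
})

test_that("random models are valid, reproducible and build end-to-end", {
  for (seed in c(1, 7, 2024)) {
    spec <- random_model(seed, n_pops = 3, connectivity_density = 0.6)
    expect_identical(nrow(validate_model(spec)), 0L)
    expect_identical(save_model(random_model(seed, 3, 0.6)),
                     save_model(spec))
    real <- suppressWarnings(realize_model(spec, seed = seed))
    expect_length(real$populations, 3)
    s <- emit_script(real)
    expect_match(s, "nest.Simulate", fixed = TRUE)
    # round-trip through the file form as well
    expect_true(model_specs_equal(load_model(save_model(spec)), spec))
  }
})

test_that("zero connectivity density yields no projections", {
  spec <- random_model(5, n_pops = 2, connectivity_density = 0)
  expect_length(spec$projections, 0)
})
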