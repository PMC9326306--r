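test_that("neuron placement is uniform-in-bounds and reproducible", {
  b <- list(c(0, 1), c(-2, 2))
  expect_identical(nrow(place_neurons(0, b, 2, 1)), 0L)
  p <- place_neurons(100, b, 2, seed = 5)
  expect_identical(dim(p), c(100L, 2L))
  expect_true(all(p[, 1] >= 0 & p[, 1] <= 1))
  expect_true(all(p[, 2] >= -2 & p[, 2] <= 2))
  expect_identical(place_neurons(100, b, 2, seed = 5), p)
  expect_error(place_neurons(10, b, 4, 1), "dim")
})

test_that("scoped stimulus target selection is exact geometry", {
  pos <- rbind(c(0.1, 0), c(0.5, 0), c(0.9, 0))
  expect_identical(select_stimulus_targets(pos, c(0, 0), 0.5), c(1L, 2L))
  expect_identical(select_stimulus_targets(pos, c(0, 0), 10), 1:3)
  expect_identical(select_stimulus_targets(pos, c(0.3, 0.3), 1e-9),
                   integer(0))
  expect_error(select_stimulus_targets(pos, c(0, 0, 0), 1), "dimension")
})

test_that("population realization scales counts and overlays overrides", {
  spec <- build_cortical_example()
  sim <- spec$simulations[[1]]
  pop <- spec$populations[[1]]
  r1 <- realize_population(pop, spec, 1.0, 1, sim)
  expect_identical(r1$n_scaled, 10000L)
  r2 <- realize_population(pop, spec, 0.1, 1, sim)
  expect_identical(r2$n_scaled, 1000L)
  # override wins; untouched parameters keep template defaults
  pop$param_overrides <- list(tau_m = entries(17.5))
  r3 <- realize_population(pop, spec, 1.0, 1, sim)
  expect_identical(r3$resolved_params$tau_m, 17.5)
  expect_identical(r3$resolved_params$C_m, 250)
  # unresolved overrides (all deactivated) keep the default
  pop$param_overrides <- list(tau_m = entries(99, flag = "deactivated"))
  r4 <- realize_population(pop, spec, 1.0, 1, sim)
  expect_identical(r4$resolved_params$tau_m, 10)
})

test_that("population realization errors name the failing population", {
  spec <- build_cortical_example()
  sim <- spec$simulations[[1]]
  pop <- spec$populations[[1]]
  pop$number <- list()
  expect_error(realize_population(pop, spec, 1, 1, sim),
               "'exc' has no active number entry")
  pop2 <- spec$populations[[1]]
  pop2$template_ref <- NULL
  expect_error(realize_population(pop2, spec, 1, 1, sim),
               "references no neuron template")
})

test_that("projection weights carry the source-regime sign", {
  real <- suppressWarnings(realize_model(mini_balanced_model(),
                                         scale = 1, seed = 2))
  for (pr in real$projections) {
    src_regime <- real$populations[[pr$source]]$regime
    if (src_regime == "inhibitory") expect_lte(pr$weight, 0)
    else expect_gte(pr$weight, 0)
  }
})

test_that("receptor-location None removes attenuation from the weight", {
  spec <- mini_balanced_model()
  spec$projections[[1]]$receptor_location <- list()
  real <- realize_model(spec, scale = 1, seed = 2)
  pr <- real$projections[[1]]
  # base weight must then be exactly the PSP conversion (no attenuation)
  el <- neuron_electrical(10, 250)
  expect_equal(pr$weight, psp_to_weight(1.4, 0.5, el))
})

test_that("missing receptors and conductance templates are build errors", {
  spec <- mini_balanced_model()
  # strip the GABA port from exc: inhibitory afferents cannot attach
  spec$populations[[1]]$receptors <- spec$populations[[1]]$receptors[1]
  expect_error(realize_model(spec, scale = 1, seed = 1),
               "no GABA receptor .* no weight_override")
  # conductance-based target template refuses PSP conversion
  spec2 <- mini_balanced_model()
  tmpl <- spec2$templates[[1]]
  tmpl$name <- "iaf_cond_alpha"
  spec2$templates[[1]] <- tmpl
  for (i in seq_along(spec2$populations))
    spec2$populations[[i]]$template_ref <- "iaf_cond_alpha"
  expect_error(realize_model(spec2, scale = 1, seed = 1),
               "conductance-based")
})

test_that("delays fall back to the synapse template default with warning", {
  spec <- mini_balanced_model()
  spec$projections[[1]]$delay_ms <- list()
  real <- realize_model(spec, scale = 1, seed = 1)
  expect_identical(real$projections[[1]]$delay_ms, 1.5)  # template default
  # no entries and no template: 1 ms with a warning
  spec$projections[[1]]$synapse_template_ref <- NULL
  expect_warning(real2 <- realize_model(spec, scale = 1, seed = 1),
                 "using 1 ms")
  expect_identical(real2$projections[[1]]$delay_ms, 1)
})

test_that("axon organization controls the spatial mask", {
  spec <- mini_balanced_model()
  # diffuse + domain wider than the arena: no mask
  real <- realize_model(spec, scale = 1, seed = 1)
  expect_null(real$projections[[1]]$mask_radius)
  # diffuse with a finite small domain keeps the mask
  spec$projections[[1]]$axon_domain_radius <- list(value = 0.25,
                                                   unit = "coord")
  real2 <- realize_model(spec, scale = 1, seed = 1)
  expect_identical(real2$projections[[1]]$mask_radius, 0.25)
  # focused always masks at the domain radius
  spec$projections[[1]]$axon_organization <- entries("focused")
  real3 <- realize_model(spec, scale = 1, seed = 1)
  expect_identical(real3$projections[[1]]$mask_radius, 0.25)
})

test_that("realize_model is a pure function of (spec, scale, seed)", {
  spec <- mini_balanced_model()
  a <- realize_model(spec, scale = 1, seed = 42)
  b <- realize_model(spec, scale = 1, seed = 42)
  expect_identical(a, b)
  c <- realize_model(spec, scale = 1, seed = 43)
  expect_false(identical(a$populations$exc$positions,
                         c$populations$exc$positions))
})

test_that("realization has the fixture's declared structure", {
  real <- realize_model(build_cortical_example(), scale = 1, seed = 7)
  expect_length(real$populations, 2)
  expect_length(real$projections, 4)
  expect_length(real$stimuli, 2)
  expect_error(
    realize_model(snn_model("nosim",
                            populations = list(),
                            simulations = list()), seed = 1),
    "defines no simulation")
})

test_that("population-size ratios are preserved under any scale", {
  spec <- build_cortical_example()
  for (s in c(0.01, 0.1, 0.5)) {
    real <- suppressWarnings(realize_model(spec, scale = s, seed = 1))
    n_exc <- real$populations$exc$n_scaled
    n_inh <- real$populations$inh$n_scaled
    expect_identical(n_exc, scale_count(10000, s))
    expect_identical(n_inh, scale_count(2500, s))
    expect_equal(n_exc / n_inh, 4, tolerance = 2 / n_inh)
  }
  expect_warning(realize_model(spec, scale = 0.1, seed = 1),
                 "not .*equivalent")
})

test_that("fixed-indegree realizations instantiate to exact afferent counts", {
  real <- realize_model(mini_balanced_model(), scale = 1, seed = 3)
  for (pr in real$projections) {
    n_src <- real$populations[[pr$source]]$n_scaled
    n_tgt <- real$populations[[pr$target]]$n_scaled
    k <- pr$rule_value
    counts <- instantiate_indegree_counts(n_src, n_tgt, k, seed = 9)
    expect_true(all(counts == k))
  }
})

test_that("scoped stimuli and recordables resolve deterministically", {
  spec <- mini_balanced_model()
  spec$simulations[[1]]$stimuli[[1]]$scope <-
    list(center = c(0.5, 0.5), radius = 0.2)
  spec$simulations[[1]]$recordables <-
    list(recordable_spec("exc", "membrane_potential"))
  a <- realize_model(spec, scale = 1, seed = 10)
  b <- realize_model(spec, scale = 1, seed = 10)
  idx <- a$stimuli[[1]]$target_indices
  expect_gt(length(idx), 0)
  pos <- a$populations$exc$positions[idx, , drop = FALSE]
  expect_true(all(sqrt(rowSums((pos - 0.5)^2)) <= 0.2))
  expect_identical(idx, b$stimuli[[1]]$target_indices)
  ni <- a$recordables[[1]]$neuron_index
  expect_true(ni >= 1 && ni <= a$populations$exc$n_scaled)
  expect_identical(ni, b$recordables[[1]]$neuron_index)
})
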