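test_that("the resolved description applies aggregation and flag routing", {
  spec <- load_model('{"model": {"name": "m"},
    "populations": [{"name": "a", "regime": "excitatory",
      "number": [{"value": 2}, {"value": 4}],
      "dendrite_extent_um": [{"value": 500, "flag": "deactivated"}],
      "firing_targets": [{"state": "resting", "lo_hz": 1, "hi_hz": 5}]}]}')
  desc <- build_description(spec)
  pop <- desc$populations[[1]]
  expect_identical(pop$number$value, 3)
  expect_identical(pop$number$n_contributions, 2L)
  # deactivated-only attribute resolves to None
  expect_true(is.na(pop$dendrite_extent_um$value))
  expect_identical(pop$dendrite_extent_um$n_contributions, 0L)
  # objective firing-rate range lives under objectives, not parameters
  expect_identical(pop$objectives[[1]]$target_range_hz, c(1, 5))
  txt <- build_description(spec, as_json = TRUE)
  expect_match(txt, '"value": null')
})

test_that("per-attribute references survive into the description", {
  spec <- build_cortical_example()
  desc <- build_description(spec)
  expect_match(desc$populations[[1]]$number$references[1], "doi.org")
})

test_that("emitted scripts are byte-deterministic with four ordered sections", {
  real <- realize_model(mini_balanced_model(), scale = 1, seed = 4)
  s1 <- emit_script(real)
  s2 <- emit_script(realize_model(mini_balanced_model(), scale = 1,
                                  seed = 4))
  expect_identical(s1, s2)
  sections <- c("# Initialization",
                "# Creation of neural populations",
                "# Network building",
                "# Stimuli, recordables, and simulation")
  pos <- vapply(sections, function(h) regexpr(h, s1, fixed = TRUE)[1],
                numeric(1))
  expect_true(all(pos > 0))
  expect_true(all(diff(pos) > 0))
  expect_match(s1, "nest.resolution = 0.1", fixed = TRUE)
  expect_match(s1, "nest.Simulate(2000.0)", fixed = TRUE)
})

test_that("emitted scripts parse as python source", {
  real <- realize_model(mini_balanced_model(), scale = 1, seed = 4)
  expect_parses_as_python(emit_script(real))
  # gaussian + scoped + membrane recordable paths also parse
  spec <- random_model(99, n_pops = 3, connectivity_density = 0.8)
  spec$simulations[[1]]$recordables <-
    list(recordable_spec("pop1", "membrane_potential"))
  spec$simulations[[1]]$stimuli[[1]]$scope <-
    list(center = c(0.5, 0.5), radius = 0.3)
  expect_parses_as_python(
    emit_script(suppressWarnings(realize_model(spec, seed = 5))))
})

test_that("recordables map one-to-one onto recording devices", {
  real <- realize_model(mini_balanced_model(), scale = 1, seed = 4)
  s <- emit_script(real)
  expect_identical(
    lengths(regmatches(s, gregexpr('nest.Create("spike_recorder")', s,
                                   fixed = TRUE))),
    2L)
  expect_match(s, "nest.Connect(exc, rec_1)", fixed = TRUE)
})

test_that("an empty model emits initialization and the simulate call only", {
  spec <- snn_model("empty", simulations = list(simulation_spec(
    duration_ms = 100, active = TRUE)))
  real <- realize_model(spec, seed = 1)
  s <- emit_script(real)
  expect_match(s, "nest.ResetKernel()", fixed = TRUE)
  expect_match(s, "nest.Simulate(100.0)", fixed = TRUE)
  expect_false(grepl("nest.Create", s, fixed = TRUE))
  expect_parses_as_python(s)
})

test_that("objectives are emitted as script comments", {
  real <- realize_model(build_striatal_example(), scale = 0.01, seed = 1) |>
    suppressWarnings()
  s <- emit_script(real)
  expect_match(s, "#   population dSPN: resting firing rate target",
               fixed = TRUE)
})

test_that("no resolved parameter silently drops out of the outputs", {
  spec <- mini_balanced_model()
  real <- realize_model(spec, scale = 1, seed = 6)
  s <- emit_script(real)
  desc <- build_description(spec, as_json = TRUE)
  both <- paste(s, desc)
  for (pr in real$projections) {
    expect_match(s, paste0('"indegree": ', pr$rule_value), fixed = TRUE)
    expect_match(s, substr(fmt <- format(pr$weight, digits = 10), 1, 8),
                 fixed = TRUE)
    expect_match(both, format(pr$delay_ms), fixed = TRUE)
  }
  for (p in real$populations) {
    expect_match(s, paste0('"', p$template, '", ', p$n_scaled),
                 fixed = TRUE)
    for (nm in names(p$resolved_params))
      expect_match(s, paste0('"', nm, '":'), fixed = TRUE)
  }
  for (st in real$stimuli)
    expect_match(s, paste0('"rate": ', format(st$rate_hz)), fixed = TRUE)
})

test_that("outputs pack into a two-member zip with exact contents", {
  real <- realize_model(mini_balanced_model(), scale = 1, seed = 4)
  script <- emit_script(real)
  desc <- build_description(mini_balanced_model(), as_json = TRUE)
  zp <- tempfile(fileext = ".zip")
  package_outputs(desc, script, zp)
  listing <- utils::unzip(zp, list = TRUE)
  expect_identical(sort(listing$Name),
                   c("model_description.json", "simulation.py"))
  exdir <- tempfile()
  utils::unzip(zp, exdir = exdir)
  expect_identical(
    readChar(file.path(exdir, "simulation.py"),
             file.size(file.path(exdir, "simulation.py"))),
    script)
  expect_identical(
    readChar(file.path(exdir, "model_description.json"),
             file.size(file.path(exdir, "model_description.json"))),
    desc)
  # re-packing the extracted members reproduces the archive byte-for-byte
  zp2 <- tempfile(fileext = ".zip")
  package_outputs(
    readChar(file.path(exdir, "model_description.json"),
             file.size(file.path(exdir, "model_description.json"))),
    readChar(file.path(exdir, "simulation.py"),
             file.size(file.path(exdir, "simulation.py"))),
    zp2)
  expect_identical(readBin(zp, "raw", file.size(zp)),
                   readBin(zp2, "raw", file.size(zp2)))
})

test_that("description and script regenerate identically from a reloaded file", {
  spec <- mini_balanced_model()
  tf <- tempfile(fileext = ".json")
  save_model(spec, tf)
  spec2 <- load_model(tf)
  expect_identical(build_description(spec, as_json = TRUE),
                   build_description(spec2, as_json = TRUE))
  expect_identical(emit_script(realize_model(spec, scale = 1, seed = 8)),
                   emit_script(realize_model(spec2, scale = 1, seed = 8)))
})

test_that("build_model writes the artifact files", {
  dir <- tempfile()
  res <- build_model(mini_balanced_model(), scale = 1, seed = 1,
                     out_dir = dir, zip = TRUE)
  expect_true(all(file.exists(file.path(
    dir, c("model_description.json", "simulation.py",
           "model_outputs.zip")))))
})
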