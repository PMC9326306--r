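nodes_json <- '[
  {"name": "M1", "number": 1200, "regime": "excitatory", "layer": "L5"},
  {"name": "S1", "regime": "excitatory"}
]'
edges_json <- '[
  {"source": "M1", "target": "S1", "delay": 2.5, "weight": 0.8,
   "tract": "cortico-cortical"}
]'

test_that("connectome nodes and edges map to populations and projections", {
  spec <- suppressWarnings(import_connectome(nodes_json, edges_json))
  expect_length(spec$populations, 2)
  expect_length(spec$projections, 1)
  expect_identical(resolve_attribute(spec$populations[[1]]$number)$value,
                   1200)
  # absent attributes stay unresolved for later entry
  expect_length(spec$populations[[2]]$number, 0)
  pr <- spec$projections[[1]]
  expect_identical(resolve_attribute(pr$delay_ms)$value, 2.5)
  expect_identical(resolve_attribute(pr$weight_override)$value, 0.8)
  # extra keys are preserved as annotations, never interpreted
  expect_identical(spec$populations[[1]]$annotations$layer, "L5")
  expect_identical(pr$annotations$tract, "cortico-cortical")
})

test_that("edge weights trigger the unverified-units warning", {
  expect_warning(import_connectome(nodes_json, edges_json),
                 "units .* not verified")
})

test_that("imports never invent values", {
  spec <- suppressWarnings(import_connectome(nodes_json, edges_json))
  # nothing beyond the documents' fields resolves to a value
  expect_null(resolve_attribute(spec$populations[[2]]$number)$value)
  expect_length(spec$projections[[1]]$bouton_count, 0)
  expect_length(spec$projections[[1]]$pct_projecting, 0)
  expect_length(spec$templates, 0)
})

test_that("broken connectome documents fail with the offending entity", {
  bad_edge <- '[{"source": "Z", "target": "M1"}]'
  expect_error(suppressWarnings(import_connectome(nodes_json, bad_edge)),
               "unknown node 'Z'")
  dup_nodes <- '[{"name": "A"}, {"name": "A"}]'
  expect_error(import_connectome(dup_nodes, "[]"),
               "duplicate node name 'A'")
})

test_that("imported fragments round-trip through save and load", {
  spec <- suppressWarnings(import_connectome(nodes_json, edges_json))
  txt <- save_model(spec)
  expect_true(model_specs_equal(load_model(txt), spec))
})

template_json <- sprintf(
  '{"name": "iaf_psc_alpha", "kind": "neuron", "parameters": {%s}}',
  paste(sprintf('"p%02d": {"default": %d, "description": "param %d"}',
                1:12, 1:12, 1:12), collapse = ", "))

test_that("simulator templates import all parameters and defaults", {
  tmpl <- import_simulator_template(template_json)
  expect_length(tmpl$parameters, 12)
  expect_identical(tmpl$parameters$p07$default, 7)
  expect_identical(tmpl$parameters$p07$description, "param 7")
  # re-import is idempotent
  expect_identical(import_simulator_template(template_json), tmpl)
})

test_that("template import rejects missing kinds and duplicate parameters", {
  expect_error(import_simulator_template('{"name": "x"}'), "kind")
  dup <- '{"name": "x", "kind": "neuron", "parameters":
           [{"name": "a", "default": 1}, {"name": "a", "default": 2}]}'
  expect_error(import_simulator_template(dup), "duplicate parameter")
})

test_that("model-level overrides never mutate the imported template", {
  tmpl <- import_simulator_template(template_json)
  spec <- snn_model("m", templates = list(tmpl),
                    populations = list(snn_population(
                      "a", "excitatory", number = entries(10),
                      template_ref = "iaf_psc_alpha",
                      param_overrides = list(p01 = entries(99)))),
                    simulations = list(simulation_spec(active = TRUE)))
  real <- realize_model(spec, seed = 1)
  expect_identical(real$populations$a$resolved_params$p01, 99)
  expect_identical(spec$templates[[1]]$parameters$p01$default, 1)
})
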