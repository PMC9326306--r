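test_that("psp_to_weight matches the integrated membrane response", {
  for (tau_m in c(5, 10, 20)) {
    for (rise in c(0.2, 0.5, 2)) {
      el <- neuron_electrical(tau_m_ms = tau_m, c_m_pf = 250)
      w <- psp_to_weight(1, rise, el)
      peak <- ode_psp_peak(w, tau_m, 250, rise)
      expect_lt(abs(peak - 1), 0.005)
    }
  }
})

test_that("psp_to_weight handles the degenerate tau_m == tau_syn case", {
  el <- neuron_electrical(tau_m_ms = 10, c_m_pf = 250)
  w <- psp_to_weight(1, 10, el)
  peak <- ode_psp_peak(w, 10, 250, 10)
  expect_lt(abs(peak - 1), 0.005)
})

test_that("psp_to_weight is linear and sign-preserving", {
  el <- neuron_electrical(10, 250)
  expect_identical(psp_to_weight(0, 0.5, el), 0)
  w1 <- psp_to_weight(1, 0.5, el)
  expect_equal(psp_to_weight(2, 0.5, el), 2 * w1)
  expect_equal(psp_to_weight(-1.4, 0.5, el), -1.4 * w1)
  expect_error(psp_to_weight(1, -1, el), "rise_ms")
  expect_error(neuron_electrical(-5, 250), "positive")
})

test_that("dendritic attenuation follows the passive cable closed form", {
  # independent evaluation of lambda = sqrt(d * Rm / (4 Ra)), in cm
  lam_um <- sqrt((1.6e-4) * 20000 / (4 * 150)) * 1e4
  expect_equal(lam_um, 730.2967433, tolerance = 1e-9)
  got <- dendritic_attenuation(0.1, 600, 1.6)
  expect_equal(got, exp(-60 / lam_um), tolerance = 1e-12)
})

test_that("attenuation is 1 at r in {None, 0} and strictly decreasing", {
  expect_identical(dendritic_attenuation(NULL, 600, 1.6), 1.0)
  expect_equal(dendritic_attenuation(0, 600, 1.6), 1.0)
  rs <- seq(0, 1, by = 0.05)
  f <- vapply(rs, dendritic_attenuation, numeric(1),
              extent_um = 600, diameter_um = 1.6)
  expect_true(all(diff(f) < 0))
  # also strictly decreasing in extent
  ext <- c(100, 300, 600, 1200)
  g <- vapply(ext, function(e) dendritic_attenuation(0.5, e, 1.6),
              numeric(1))
  expect_true(all(diff(g) < 0))
  expect_error(dendritic_attenuation(1.2, 600, 1.6), "\\[0, 1\\]")
  # swappable strategy
  expect_identical(
    dendritic_attenuation(0.5, 600, 1.6,
                          factor_fn = function(x, lam) 0.25),
    0.25)
})

test_that("categorical receptor locations map to interval midpoints", {
  expect_identical(categorical_receptor_location("proximal"), 0.1)
  expect_identical(categorical_receptor_location("medial"), 0.4)
  expect_identical(categorical_receptor_location("distal"), 0.8)
  expect_error(categorical_receptor_location("apical"), "unknown")
})

test_that("indegree matches the bouton-allocation oracle", {
  # 100x smaller instance of the reference parameterization
  k <- compute_indegree(100, 100, 10, 100, 1)
  expect_identical(k, 10L)
  oracle <- bouton_allocation_mean(100, 100, 10, 100, 1, seed = 11)
  expect_identical(as.integer(round(oracle)), k)
  # redundancy divides the connection count
  expect_identical(compute_indegree(100, 10000, 1000, 10000, 2), 500L)
  oracle2 <- bouton_allocation_mean(100, 100, 10, 100, 2, seed = 12)
  expect_identical(as.integer(round(oracle2)),
                   compute_indegree(100, 100, 10, 100, 2))
  expect_identical(compute_indegree(0, 100, 10, 100, 1), 0L)
  expect_error(compute_indegree(100, 100, 10, 0, 1), "n_target")
})

test_that("outdegree and scaling transfer functions are exact", {
  expect_identical(compute_outdegree(100, 1000, 1), 1000L)
  expect_identical(compute_outdegree(50, 1000, 1), 500L)
  expect_identical(compute_outdegree(100, 1000, 4), 250L)
  expect_identical(scale_count(10000, 0.1), 1000L)
  expect_identical(scale_count(3, 0.1), 1L)       # clamp to >= 1
  expect_identical(scale_count(10000, 1.0), 10000L)
  # monotone in n
  ns <- c(1, 10, 500, 20000)
  expect_true(!is.unsorted(vapply(ns, scale_count, integer(1),
                                  scale = 0.37)))
  expect_error(scale_count(100, 0), "scale")
})

test_that("effective weight composes attenuation, redundancy, gain, sign", {
  expect_identical(effective_weight(10, "excitatory", 1, 1, 1), 10)
  expect_identical(effective_weight(10, "inhibitory", 1, 1, 1), -10)
  expect_identical(effective_weight(10, "excitatory", 0.5, 2, 1), 10)
  expect_identical(effective_weight(-10, "excitatory", 1, 1, 2), 20)
  expect_error(effective_weight(1, "excitatory", 1.5, 1, 1), "attenuation")
})

test_that("poisson aggregation is additive superposition", {
  expect_identical(aggregate_poisson_rate(7, 0), 0)
  expect_identical(aggregate_poisson_rate(0, 100), 0)
  expect_identical(aggregate_poisson_rate(10, 2.5), 25)
})

test_that("cable constants load from the packaged key=value file", {
  path <- system.file("extdata", "cable_constants.conf",
                      package = "snnweaver")
  cc <- read_cable_constants(path)
  expect_identical(cc$membrane_resistivity, 20000)
  expect_identical(cc$axial_resistivity, 150)
  expect_error(cable_constants(-1, 150), "positive")
})
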