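# Independent oracles and small model builders shared across tests.

# Numerically integrate the LIF membrane ODE driven by an alpha-shaped
# PSC of peak amplitude w_pa and time constant tau_s:
#   i(t) = w * e * t/tau_s * exp(-t/tau_s);  C dV/dt = -C/tau_m V + i(t)
# Euler at dt = 1e-3 ms (1 us), long enough to capture the peak.
# Independent of the closed form used by the package.
ode_psp_peak <- function(w_pa, tau_m, c_m, tau_s, dt = 1e-3,
                         t_end = 30 * max(tau_m, tau_s)) {
  t <- seq(0, t_end, by = dt)
  i <- w_pa * exp(1) * t / tau_s * exp(-t / tau_s)
  v <- stats::filter(dt * i / c_m, 1 - dt / tau_m, method = "recursive")
  if (w_pa >= 0) max(v) else min(v)
}

# Explicitly instantiate a fixed-indegree rule: each target draws K
# distinct sources; returns the per-target afferent counts.
instantiate_indegree_counts <- function(n_source, n_target, K, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n_target), function(tgt)
    length(sample.int(n_source, K, replace = FALSE)), integer(1))
}

# Brute-force anatomical oracle: allocate the projecting axons' boutons
# uniformly over the target dendrites and measure the mean number of
# afferent synapses per target, divided by the redundancy.  The mean is
# an exact consequence of the allocation, independent of the draw.
bouton_allocation_mean <- function(pct, n_source, boutons, n_target,
                                   redundancy, seed = 1) {
  set.seed(seed)
  n_axons <- round(pct / 100 * n_source)
  total <- n_axons * boutons
  owners <- sample.int(n_target, total, replace = TRUE)
  counts <- tabulate(owners, nbins = n_target)
  mean(counts) / redundancy
}

# A miniature two-population balanced network with the same wiring
# conventions as the cortical example but 100x smaller: 100 excitatory
# and 50 inhibitory neurons, bouton counts eps * N_target.
mini_balanced_model <- function(J = 1.4, g = 4, eps = 0.1,
                                n_exc = 100, n_inh = 50) {
  spec <- build_cortical_example(J = J, g = g, epsilon = eps)
  spec$populations[[1]]$number <- entries(n_exc)
  spec$populations[[2]]$number <- entries(n_inh)
  sizes <- c(exc = n_exc, inh = n_inh)
  for (i in seq_along(spec$projections)) {
    tgt <- spec$projections[[i]]$target
    spec$projections[[i]]$bouton_count <- entries(eps * sizes[[tgt]])
  }
  spec
}

# Parse check for emitted python source, via the python ast module.
expect_parses_as_python <- function(script) {
  tf <- tempfile(fileext = ".py")
  on.exit(unlink(tf))
  writeLines(script, tf)
  out <- suppressWarnings(system2(
    "python",
    c("-c", shQuote(sprintf("import ast; ast.parse(open(%s).read())",
                            deparse(tf)))),
    stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  expect_identical(status, 0L,
                   label = paste("python parse:", paste(out, collapse = " ")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
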