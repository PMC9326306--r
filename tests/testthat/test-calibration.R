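test_that("interval error is 0 at centre, 1 at bounds, linear beyond", {
  expect_identical(interval_error(3, 2, 4), 0)
  expect_identical(interval_error(4, 2, 4), 1)
  expect_identical(interval_error(2, 2, 4), 1)
  expect_identical(interval_error(5, 2, 4), 2)   # centre + 2 half-widths
  # degenerate point target: relative distance
  expect_identical(interval_error(10, 10, 10), 0)
  expect_equal(interval_error(11, 10, 10), 0.1)
  expect_error(interval_error(1, 5, 2), "lo <= hi")
})

test_that("the total objective sums pair errors and is permutation-invariant", {
  targets <- setNames(
    list(firing_target("resting", 2, 4), firing_target("excitation", 10, 20)),
    c(calibration_target_key("a", "base"),
      calibration_target_key("a", "stim")))
  obs <- list(rate_observation("a", "base", 3),
              rate_observation("a", "stim", 15))
  expect_identical(total_objective(obs, targets), 0)
  obs2 <- list(rate_observation("a", "base", 4),
               rate_observation("a", "stim", 20))
  expect_identical(total_objective(obs2, targets), 2)
  expect_identical(total_objective(rev(obs2), targets),
                   total_objective(obs2, targets))
  expect_identical(total_objective(obs2[1], targets),
                   interval_error(4, 2, 4))
  expect_identical(total_objective(obs2, targets, combine = "mean"), 1)
  expect_identical(total_objective(obs2, targets, combine = "max"), 1)
  expect_error(
    total_objective(list(rate_observation("b", "base", 1)), targets),
    "no calibration target")
})

quad_evaluator <- function(centers) {
  # rates deviate from the target centre by a quadratic in the parameters
  function(params) {
    list(rate_observation("pop", "base",
                          10 + sum((unlist(params[names(centers)]) -
                                      centers)^2)))
  }
}
quad_targets <- setNames(list(firing_target("resting", 8, 12)),
                         calibration_target_key("pop", "base"))

test_that("grid search returns the exhaustive argmin", {
  ev <- function(p) list(rate_observation("pop", "base", 10 + (p$w - 3)^2))
  res <- grid_search(ev, list(w = 1:5), quad_targets)
  expect_identical(res$best_params$w, 3L)
  expect_identical(res$best_error, 0)
  expect_identical(nrow(res$trace), 5L)
})

test_that("grid search agrees with independent enumeration on 3 parameters", {
  centers <- c(a = 2, b = 0.5, c = -1)
  ev <- quad_evaluator(centers)
  grid <- list(a = c(1, 2, 3), b = c(0, 0.5, 1), c = c(-2, -1, 0, 1))
  res <- grid_search(ev, grid, quad_targets)
  # independent brute-force enumeration with nested loops
  best <- NULL
  best_err <- Inf
  for (a in grid$a) for (b in grid$b) for (cc in grid$c) {
    rate <- 10 + (a - 2)^2 + (b - 0.5)^2 + (cc + 1)^2
    err <- abs(rate - 10) / 2
    if (err < best_err) {
      best_err <- err
      best <- list(a = a, b = b, c = cc)
    }
  }
  expect_identical(res$best_params[c("a", "b", "c")], best)
  expect_equal(res$best_error, best_err)
  expect_identical(nrow(res$trace), 36L)
})

test_that("ties resolve to the first point in lexicographic grid order", {
  ev <- function(p) list(rate_observation("pop", "base", 10))  # flat
  res <- grid_search(ev, list(x = c(5, 1), y = c(9, 2)), quad_targets)
  expect_identical(res$best_params$x, 5)
  expect_identical(res$best_params$y, 9)
})

test_that("frozen parameters override grid entries and never vary", {
  centers <- c(w_base = 1, w_stim = 4)
  ev <- quad_evaluator(centers)
  # stage 1: baseline grid
  s1 <- grid_search(ev, list(w_base = c(0, 1, 2)), quad_targets,
                    frozen = list(w_stim = 4))
  expect_identical(s1$best_params$w_base, 1)
  # stage 2: stimulus grid with the baseline frozen at its optimum
  s2 <- grid_search(ev, list(w_stim = c(3, 4, 5)), quad_targets,
                    frozen = list(w_base = s1$best_params$w_base))
  expect_identical(s2$best_params$w_stim, 4)
  expect_false("w_base" %in% names(s2$trace))   # never varied
  expect_identical(s2$best_params$w_base, 1)
  # a frozen name colliding with the grid wins, with a warning
  expect_warning(
    s3 <- grid_search(ev, list(w_base = c(0, 2), w_stim = c(3, 4, 5)),
                      quad_targets, frozen = list(w_base = 1)),
    "frozen")
  expect_identical(s3$best_params$w_base, 1)
  expect_identical(nrow(s3$trace), 3L)
})

test_that("evaluator failures score as infinite error without aborting", {
  ev <- function(p) {
    if (p$w == 2) stop("simulator crashed")
    list(rate_observation("pop", "base", 10 + (p$w - 3)^2))
  }
  res <- grid_search(ev, list(w = 1:5), quad_targets)
  expect_identical(res$best_params$w, 3L)
  expect_identical(res$trace$error[res$trace$w == 2], Inf)
})
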