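quadratic_objective <- function(x) (x[["r"]] - 5)^2

test_that("at T = 0 only downhill moves are accepted", {
  res <- metropolis_run(quadratic_objective, c(r = 8), step_sizes = 0.5,
                        bounds = list(c(0, 20)), steps = 300,
                        temperature = 0, seed = 4)
  expect_true(all(res$trace$delta_e[res$trace$accepted] <= 0))
  expect_true(all(diff(res$trace$best_energy) <= 0))
  expect_lt(abs(res$best_par[["r"]] - 5), 0.2)
})

test_that("uphill acceptance frequency matches the Metropolis rule", {
  temp <- 0.8
  res <- metropolis_run(quadratic_objective, c(r = 5.2), step_sizes = 0.6,
                        bounds = list(c(-20, 30)), steps = 10000,
                        temperature = temp, seed = 42)
  up <- res$trace[res$trace$delta_e > 0, ]
  expect_gt(nrow(up), 1000)
  p_expected <- mean(exp(-up$delta_e / temp))
  p_observed <- mean(up$accepted)
  # binomial 3-sigma band around the expected acceptance probability
  sigma <- sqrt(p_expected * (1 - p_expected) / nrow(up))
  expect_lt(abs(p_observed - p_expected), 3 * sigma + 0.01)
})

test_that("optimizations are reproducible and monotone in best energy", {
  spec <- canonical_dimer_spec(heptads = 2)
  cfg <- optimizer_config(steps = 40, seed = 7)
  r1 <- optimize_parameters(spec, cfg)
  r2 <- optimize_parameters(spec, cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best_parameters, r2$best_parameters)
  expect_true(all(diff(r1$trace$best_energy) <= 0))
  expect_lte(r1$best_energy, r1$initial_energy)
  expect_equal(r1$best_energy, min(r1$trace$energy))
})

test_that("the fast objective equals the public pipeline", {
  spec <- validate_spec(canonical_dimer_spec(heptads = 3))
  obj <- basic_mode_objective(spec)
  for (x in list(c(radius = 4.9, pitch = 180, interface_angle = 26),
                 c(radius = 6.5, pitch = 120, interface_angle = -10))) {
    h <- spec$helices[[1]]
    h$radius <- x[["radius"]]
    h$pitch <- -x[["pitch"]]
    h$interface_angle <- x[["interface_angle"]]
    s <- assembly_spec("basic", "coiled_coil", 2, list(h))
    public <- interaction_energy(
      place_sidechains(build_assembly(s)$model, max_passes = 0))$total
    expect_equal(obj(x), public)
  }
})

test_that("mode and size restrictions are enforced", {
  adv <- example_specs("cc-dimer-antiparallel")
  expect_error(optimize_parameters(adv), "basic")
  big <- canonical_dimer_spec(heptads = 22)     # 2 x 154 = 308 residues
  expect_error(optimize_parameters(big), "300")
  expect_error(optimize_parameters(big, optimizer_config(steps = 1)),
               "allow_large")
  small <- canonical_dimer_spec(heptads = 10)   # 140 residues: accepted
  res <- optimize_parameters(small, optimizer_config(steps = 1, seed = 1))
  expect_s3_class(res, "coilr_optimization")
  expect_error(optimizer_config(steps = 0), class = "coilr_domain_error")
  expect_error(optimizer_config(step_sizes = c(radius = -1, pitch = 1,
                                               interface_angle = 1)),
               class = "coilr_domain_error")
})

test_that("measured parameters of the optimized model match the optimizer", {
  spec <- canonical_dimer_spec(heptads = 4, radius = 6, pitch = -160)
  res <- optimize_parameters(spec, optimizer_config(steps = 150, seed = 21))
  m <- build_assembly(res$best_spec)$model
  fit <- measure_parameters(m)
  expect_equal(mean(fit$radius), res$best_parameters$radius, tolerance = 0.02)
  expect_equal(mean(fit$pitch), res$best_parameters$pitch, tolerance = 0.02)
})

test_that("oligomer-state scans are reproducible and prefer low order", {
  tab1 <- scan_oligomer_states(strrep("IAALKQE", 3), n_range = 2:3,
                               config = optimizer_config(steps = 25, seed = 5),
                               restarts = 1)
  tab2 <- scan_oligomer_states(strrep("IAALKQE", 3), n_range = 2:3,
                               config = optimizer_config(steps = 25, seed = 5),
                               restarts = 1)
  expect_identical(tibble::as_tibble(tab1), tibble::as_tibble(tab2))
  expect_equal(nrow(tab1), 2)
  expect_error(scan_oligomer_states("IAALKQE", n_range = integer(0)),
               class = "coilr_domain_error")
})

test_that("tidy, glance and autoplot work on optimizations", {
  res <- optimize_parameters(canonical_dimer_spec(heptads = 2),
                             optimizer_config(steps = 15, seed = 2))
  expect_identical(tidy(res), res$trace)
  gl <- glance(res)
  expect_true(all(c("best_energy", "acceptance_rate", "seed") %in% names(gl)))
  expect_s3_class(autoplot(res), "ggplot")
})
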