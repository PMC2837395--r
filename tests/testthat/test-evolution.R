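make_test_pop <- function(n = 20) make_fixture("toy_population", rng_seed = 3)

test_that("a population with no births, deaths or fluctuations is static", {
  pop <- make_test_pop()
  params <- fitness_params(d = 0, r = 0, G_ref = 1e9)
  pop$b <- rep(0, pop$n)
  pop$r <- rep(0, pop$n)
  acc <- mutatorsim:::new_acc()
  pop2 <- mutatorsim:::step_population(pop, params, tiny_set(), energy_model(),
                                       1L, acc, list(cap = 100,
                                                     log_divisions = FALSE,
                                                     k_form = "centered",
                                                     k_code = 0L))
  expect_equal(pop2$n, pop$n)
  expect_identical(pop2$geno, pop$geno)
  expect_identical(pop2$C, pop$C)
  expect_equal(acc$k, 0)
})

test_that("culling brings the population back to the carrying capacity exactly", {
  pop <- make_test_pop()
  params <- fitness_params(d = 0, r = 0, G_ref = 1e9)
  pop$b <- rep(1, pop$n)  # every cell divides: 20 -> 40
  pop$m <- rep(0, pop$n)
  pop$r <- rep(0, pop$n)
  acc <- mutatorsim:::new_acc()
  withr::with_seed(31, {
    pop2 <- mutatorsim:::step_population(pop, params, tiny_set(), energy_model(),
                                         1L, acc, list(cap = 25,
                                                       log_divisions = FALSE,
                                                       k_form = "centered",
                                                       k_code = 0L))
  })
  expect_equal(pop2$n, 25)
  expect_equal(attr(pop2, "counts")[["culled"]], 15)
})

test_that("with b = d the expected population change is zero", {
  pop <- make_test_pop()
  params <- fitness_params(d = 0.02, r = 0, G_ref = 1e9)
  opts <- list(cap = 10000, log_divisions = FALSE, k_form = "centered",
               k_code = 0L)
  set <- tiny_set(); em <- energy_model()
  withr::with_seed(32, {
    deltas <- replicate(400, {
      pop$b <- rep(0.02, pop$n)
      pop$m <- rep(0, pop$n)
      pop$r <- rep(0, pop$n)
      acc <- mutatorsim:::new_acc()
      mutatorsim:::step_population(pop, params, set, em, 1L, acc, opts)$n - pop$n
    })
  })
  # per step: E[delta] = n (b - d) = 0; sd approx sqrt(n (b + d))
  se <- sqrt(pop$n * 0.04) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 3 * se)
})

test_that("stress protocols change exactly one parameter and refuse re-application", {
  p <- fitness_params()
  p1 <- apply_stress(p, stress_protocol("stationary_phase"))
  expect_equal(p1$b0, 235.815, tolerance = 1e-9)
  expect_equal(p1$C0, p$C0)
  expect_equal(p1$temperature, p$temperature)
  p2 <- apply_stress(p, stress_protocol("starvation"))
  expect_equal(p2$C0, 0.04, tolerance = 1e-12)
  p3 <- apply_stress(p, stress_protocol("heat_shock"))
  expect_equal(p3$temperature, 1.00)
  expect_error(apply_stress(p3, stress_protocol("heat_shock")),
               class = "mutatorsim_config_error")
  expect_error(apply_stress(p1, stress_protocol("stationary_phase")),
               class = "mutatorsim_config_error")
  expect_error(stress_protocol("freeze"), class = "mutatorsim_config_error")
})

test_that("a zero-length run returns the seeded initial record", {
  cfg <- run_config(cap = 50, n_seed = 17, t_max = 0, n_struct = 200, seed = 2,
                    design = list(p_nat_threshold = 0.62, p_int_threshold = 0.2))
  run <- run_evolution(cfg, structure_set = tiny_set())
  expect_s3_class(run, "evolution_run")
  expect_equal(nrow(run$time_series), 1)
  expect_equal(run$time_series$n, 17)
  expect_equal(run$time_series$t, 0)
  # seed calibration: initial birth rate equals the death rate, m = m_min
  expect_equal(run$time_series$mean_b, cfg$d, tolerance = 1e-9)
  expect_equal(run$time_series$mean_m, cfg$m_min, tolerance = 1e-12)
})

test_that("runs are exactly reproducible under the same master seed", {
  cfg <- run_config(cap = 60, n_seed = 20, t_max = 150, n_struct = 200,
                    seed = 77, record_every = 10,
                    design = list(p_nat_threshold = 0.62, p_int_threshold = 0.2))
  r1 <- run_evolution(cfg, structure_set = tiny_set())
  r2 <- run_evolution(cfg, structure_set = tiny_set())
  expect_identical(r1$time_series, r2$time_series)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$population$geno, r2$population$geno)
  cfg$seed <- 78
  r3 <- run_evolution(cfg, structure_set = tiny_set())
  expect_false(identical(r1$time_series, r3$time_series))
})

test_that("replaying a fully logged event stream reproduces the final population", {
  cfg <- run_config(cap = 40, n_seed = 15, t_max = 120, n_struct = 200,
                    seed = 5, r = 0.05, log_divisions = TRUE,
                    design = list(p_nat_threshold = 0.62, p_int_threshold = 0.2))
  run <- run_evolution(cfg, structure_set = tiny_set())
  replayed <- replay_event_log(run)
  pop <- run$population
  expect_equal(nrow(replayed), pop$n)
  ord <- order(pop$id)
  expect_equal(replayed$cell, pop$id[ord])
  # genomes match exactly
  genom <- vapply(seq_len(pop$n), function(r)
    mutatorsim:::int_to_nt(pop$geno[r, 1:81]), "")
  expect_equal(replayed$gene1, genom[ord])
  genom4 <- vapply(seq_len(pop$n), function(r)
    mutatorsim:::int_to_nt(pop$geno[r, 244:324]), "")
  expect_equal(replayed$gene4, genom4[ord])
  expect_equal(replayed$C4, pop$C[ord, 4], tolerance = 1e-12)
})

test_that("culling is unbiased between neutral labels", {
  # constant fitness, no mutation pressure: a neutral label performs an
  # unbiased random walk
  pop <- make_test_pop()
  params <- fitness_params(d = 0.01, r = 0, G_ref = 1e-12)
  params$constant_b <- 0.5
  opts <- list(cap = 20, log_divisions = FALSE, k_form = "centered", k_code = 0L)
  set <- tiny_set(); em <- energy_model()
  withr::with_seed(33, {
    changes <- replicate(300, {
      pop$lineage <- rep(c(1L, 2L), each = 10)
      pop$b <- rep(0.5, pop$n)
      pop$m <- rep(0, pop$n)
      pop$r <- rep(0, pop$n)
      acc <- mutatorsim:::new_acc()
      pop2 <- mutatorsim:::step_population(pop, params, set, em, 1L, acc, opts)
      mean(pop2$lineage == 1L) - 0.5
    })
  })
  expect_lt(abs(mean(changes)), 3 * sd(changes) / sqrt(length(changes)))
})

test_that("competition between equal fluctuation rates stays near one half", {
  cfg <- run_config(cap = 60, n_seed = 20, t_max = 400, n_struct = 200,
                    seed = 9, record_every = 20,
                    design = list(p_nat_threshold = 0.62, p_int_threshold = 0.2))
  traces <- run_competition(cfg, r_high = 0.01, r_low = 0.01, replicates = 4,
                            structure_set = tiny_set())
  final <- dplyr::filter(traces, t == max(t))
  expect_lt(abs(mean(final$fraction) - 0.5), 0.35)  # drift-scale deviation
  expect_error(run_competition(cfg, replicates = 0),
               class = "mutatorsim_config_error")
})

test_that("extinction terminates a run cleanly", {
  cfg <- run_config(cap = 30, n_seed = 4, t_max = 3000, n_struct = 200,
                    seed = 3, d = 0.2, record_every = 1,
                    design = list(p_nat_threshold = 0.62, p_int_threshold = 0.2))
  run <- run_evolution(cfg, structure_set = tiny_set())
  expect_true(run$meta$extinct)
  expect_lt(run$meta$t_end, 3000)
  expect_equal(tail(run$time_series$n, 1), 0)
})
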