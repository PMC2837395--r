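test_that("mutator frequency counts cells above the rate threshold", {
  expect_equal(mutator_frequency(rep(1e-4, 10)), 0)
  expect_equal(mutator_frequency(rep(0.05, 10)), 1)
  expect_equal(mutator_frequency(c(rep(0.05, 3), rep(1e-4, 7))), 0.3)
  expect_error(mutator_frequency(numeric(0)), class = "mutatorsim_input_error")
})

test_that("constructed event logs classify to the predetermined causes", {
  fx <- make_fixture("constructed_event_log")
  tr <- classify_transitions(fx)
  expect_equal(nrow(tr), 3)
  expect_equal(tr$direction, c("M", "W", "M"))
  expect_equal(tr$cause, c("Env", "Mut", "SS"))
  # pure function: identical output on re-run
  expect_identical(tr, classify_transitions(fx))
})

test_that("single-cause logs give a single-cause classification", {
  base <- make_fixture("constructed_event_log")
  # every flip environmental at one stress step
  env <- list(
    time_series = tibble::tibble(t = 0:20,
                                 mutator_freq = c(rep(0, 10), rep(0.9, 11))),
    events = tibble::tibble(t = 9L, seq = 1:6, type = "flip", cell = 1:6,
                            direction = "to_mutator", cause = "Env"))
  tr <- classify_transitions(env)
  expect_equal(tr$cause, "Env")
  expect_equal(tr$n_flips, 6)
  # every flip tied to gene-4 replication mutations
  mutl <- env
  mutl$events$cause <- "Mut"
  expect_equal(classify_transitions(mutl)$cause, "Mut")
})

test_that("hysteresis suppresses chatter around one half", {
  wob <- list(
    time_series = tibble::tibble(
      t = 0:9, mutator_freq = c(0.1, 0.45, 0.55, 0.45, 0.55, 0.45,
                                0.55, 0.45, 0.55, 0.45)),
    events = tibble::tibble(t = integer(), seq = integer(), type = character(),
                            cell = integer(), direction = character(),
                            cause = character()))
  tr <- classify_transitions(wob)
  expect_equal(nrow(tr), 1)  # only the first crossing counts
})

test_that("fitness classes snap to the nearest adapted level", {
  expect_equal(fitness_class(0.30), 0.33)
  expect_equal(fitness_class(0.62), 0.62)
  expect_equal(fitness_class(0.80), 0.62)  # 0.18 below vs 0.20 above
  expect_equal(fitness_class(0.82), 1.0)
  expect_equal(fitness_class(c(1, 0.05)), c(1, 0.33))
  expect_error(fitness_class(1.2))
})

test_that("local fitness landscapes count every mutant once, lethal at x = -1", {
  set <- tiny_set()
  em <- energy_model()
  cell <- make_fixture("toy_cell", rng_seed = 3)
  params <- fitness_params(G_ref = cell$G44)
  withr::with_seed(71, {
    ls <- local_fitness_landscape(cell, set, em, params, n_mutants = 300)
  })
  expect_equal(sum(ls$bins$count), 300)
  expect_equal(length(ls$x), 300)
  expect_equal(ls$n_lethal, sum(ls$x == -1))
  # lethal mutants occupy the terminal bin
  if (ls$n_lethal > 0) {
    expect_equal(ls$bins$bin_left[1], -1)
    expect_gte(ls$bins$count[1], ls$n_lethal)
  }
})

test_that("a synonymous genome edit leaves the recomputed birth rate unchanged", {
  # phenotype identity: a different codon for the same protein gives x = 0
  set <- tiny_set()
  em <- energy_model()
  cell <- make_fixture("toy_cell", rng_seed = 3)
  params <- fitness_params(G_ref = cell$G44)
  gi <- mutatorsim:::nt_to_int(cell$genome[1])
  aa0 <- mutatorsim:::translate_int(gi)
  pos <- which(vapply(seq_len(27), function(p) {
    a <- mutatorsim:::RES_ORDER[aa0[p] + 1]
    length(mutatorsim:::the$syn_codons[[a]]) > 1
  }, TRUE))[1]
  a <- mutatorsim:::RES_ORDER[aa0[pos] + 1]
  cur <- 16 * gi[3 * pos - 2] + 4 * gi[3 * pos - 1] + gi[3 * pos]
  alt <- setdiff(mutatorsim:::the$syn_codons[[a]], cur)[1]
  gi2 <- gi
  gi2[(3 * pos - 2):(3 * pos)] <- c(alt %/% 16, (alt %/% 4) %% 4, alt %% 4)
  genome2 <- cell$genome
  genome2[1] <- mutatorsim:::int_to_nt(gi2)
  cell2 <- make_cell(genome2, cell$C, set, em, params)
  x <- (cell2$b - cell$b) / cell$b
  expect_equal(x, 0, tolerance = 1e-12)
})
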