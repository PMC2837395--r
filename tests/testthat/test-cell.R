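test_that("translation follows the standard genetic code", {
  expect_equal(translate_gene(strrep("ATG", 27)), strrep("M", 27))
  g <- paste0(strrep("ATG", 10), "TAA", strrep("ATG", 16))
  expect_true(is.na(translate_gene(g)))
  expect_true(attr(translate_gene(g), "stop"))
  expect_error(translate_gene(strrep("X", 81)), class = "mutatorsim_sequence_error")
  expect_error(translate_gene("ATG"), class = "mutatorsim_sequence_error")
  # random genes round-trip against seqinr's codon translation
  withr::with_seed(8, {
    for (i in 1:5) {
      gene <- paste(sample(c("A", "C", "G", "T"), 81, TRUE), collapse = "")
      aa_pkg <- translate_gene(gene)
      aa_ref <- paste(seqinr::translate(strsplit(tolower(gene), "")[[1]]),
                      collapse = "")
      if (grepl("\\*", aa_ref)) expect_true(is.na(aa_pkg))
      else expect_equal(aa_pkg, aa_ref)
    }
  })
})

test_that("birth rate follows the overproduction-penalized growth law", {
  p <- fitness_params(b0 = 707.445, C0 = 0.4, sigma = 100)
  cell <- list(G1 = 1e-3, G23 = 2e-3, C = c(0.19, 0.19, 0.19, 0.19))
  # penalty at sum(C) = 0.76: 1 + 100 * 0.36^2 = 13.96
  expect_equal(birth_rate(cell, p),
               min(707.445 * 1e-3 * 2e-3 / 13.96, 1))
  cell$C <- c(0.1, 0.1, 0.1, 0.1)  # at the optimum the penalty vanishes
  expect_equal(birth_rate(cell, p), min(707.445 * 2e-6 / 1, 1))
  cell$G23 <- 0
  expect_equal(birth_rate(cell, p), 0)
  # with sigma = 0 the rate is independent of total production
  p0 <- fitness_params(sigma = 0)
  cell$G23 <- 2e-3
  b1 <- birth_rate(cell, p0)
  cell$C <- c(1, 1, 1, 1)
  expect_equal(birth_rate(cell, p0), b1)
})

test_that("mutation rate interpolates linearly in the functional MMR concentration", {
  p <- fitness_params(G_ref = 0.02, m_min = 1e-4, m_max = 0.1)
  expect_equal(mutation_rate(0.02, p), 1e-4)
  expect_equal(mutation_rate(0.05, p), 1e-4)  # saturates above G_ref
  expect_equal(mutation_rate(0, p), 0.1)
  expect_equal(mutation_rate(0.01, p), (1e-4 + 0.1) / 2)
})

test_that("the mutator threshold is strict at m = 0.01", {
  expect_false(is_mutator(1e-4))
  expect_true(is_mutator(0.02))
  expect_false(is_mutator(0.01))
})

test_that("concentration fluctuations are mean-preserving multiplicative noise", {
  cell <- make_fixture("toy_cell", rng_seed = 3)
  p0 <- fitness_params(r = 0)
  out <- fluctuate_concentrations(cell, p0)
  expect_identical(out$cell$C, cell$C)
  expect_equal(nrow(out$events), 0)
  # moment check on the raw multiplier at r = 1
  p1 <- fitness_params(r = 1)
  withr::with_seed(9, {
    mult <- replicate(4000, {
      out <- fluctuate_concentrations(cell, p1)
      out$cell$C / cell$C
    })
  })
  dev <- as.vector(mult) - 1
  n <- length(dev)
  expect_lt(abs(mean(dev)), 3 * 0.1 / sqrt(n))
  se_sd <- 0.1 / sqrt(2 * n)
  expect_lt(abs(sd(dev) - 0.1), 3 * se_sd)
})

test_that("replication without mutation copies the mother exactly", {
  cell <- make_fixture("toy_cell", rng_seed = 3)
  cell$m <- 0
  out <- replicate_cell(cell, tiny_set(), energy_model(), fitness_params())
  expect_length(out$daughters, 2)
  for (d in out$daughters) expect_identical(d$genome, cell$genome)
  expect_equal(out$lethal, 0)
  expect_equal(nrow(out$events), 0)
})

test_that("substitution counts are Poisson with mean 4m per daughter", {
  cell <- make_fixture("toy_cell", rng_seed = 3)
  cell$m <- 0.25
  params <- fitness_params(theta_nat = 0.01)  # keep nearly all daughters
  withr::with_seed(10, {
    nsub <- replicate(300, {
      out <- replicate_cell(cell, tiny_set(), energy_model(), params)
      nrow(out$events) / 2
    })
  })
  lam <- 4 * 0.25
  expect_lt(abs(mean(nsub) - lam), 3 * sqrt(lam / 2) / sqrt(300))
})

test_that("daughters below the stability threshold or with stop codons are lethal", {
  cell <- make_fixture("toy_cell", rng_seed = 3)
  cell$m <- 2  # hypermutate to provoke lethality
  params <- fitness_params(theta_nat = 0.999)  # any destabilization is lethal
  withr::with_seed(11, {
    out <- replicate_cell(cell, tiny_set(), energy_model(), params)
  })
  expect_equal(length(out$daughters) + out$lethal, 2)
  expect_gt(out$lethal, 0)
})

test_that("synonymous substitutions never change the phenotype", {
  set <- tiny_set()
  em <- energy_model()
  cell <- make_fixture("toy_cell", rng_seed = 3)
  params <- fitness_params(G_ref = cell$G44)
  cell <- mutatorsim:::refresh_cell(cell, params)
  withr::with_seed(12, {
    for (i in 1:10) {
      g <- sample.int(4, 1)
      gi <- mutatorsim:::nt_to_int(cell$genome[g])
      aa0 <- mutatorsim:::translate_int(gi)
      # resample a synonymous codon at a random position
      pos <- sample.int(27, 1)
      opts <- mutatorsim:::the$syn_codons[[mutatorsim:::RES_ORDER[aa0[pos] + 1]]]
      cid <- opts[sample.int(length(opts), 1)]
      gi2 <- gi
      gi2[(3 * pos - 2):(3 * pos)] <- c(cid %/% 16, (cid %/% 4) %% 4, cid %% 4)
      genome2 <- cell$genome
      genome2[g] <- mutatorsim:::int_to_nt(gi2)
      cell2 <- make_cell(genome2, cell$C, set, em, params)
      expect_equal(cell2$b, cell$b, tolerance = 1e-12)
      expect_equal(cell2$m, cell$m, tolerance = 1e-12)
    }
  })
})

test_that("cached rates equal recomputation from scratch", {
  set <- tiny_set()
  em <- energy_model()
  cell <- make_fixture("toy_cell", rng_seed = 3)
  params <- fitness_params(G_ref = cell$G44, r = 1)
  withr::with_seed(13, out <- fluctuate_concentrations(cell, params))
  fresh <- make_cell(out$cell$genome, out$cell$C, set, em, params)
  expect_equal(out$cell$b, fresh$b, tolerance = 1e-9)
  expect_equal(out$cell$m, fresh$m, tolerance = 1e-9)
})

test_that("the fast mutant-phenotype path agrees with the full genotype map", {
  set <- tiny_set()
  em <- energy_model()
  cell <- make_fixture("toy_cell", rng_seed = 3)
  withr::with_seed(14, {
    for (i in 1:5) {
      g <- sample.int(4, 1)
      gi <- mutatorsim:::nt_to_int(cell$genome[g])
      mut <- mutatorsim:::mutate_gene_int(gi, 2L)
      aa <- mutatorsim:::translate_int(mut$gene)
      if (anyNA(aa)) next
      aa108 <- cell$aa
      aa108[(27 * (g - 1) + 1):(27 * g)] <- aa
      full <- mutatorsim:::genome_phenotype(aa108, set, em)
      fast <- mutatorsim:::.mutant_phenotype_cpp(
        aa108, g, cell$phenotype$native, cell$phenotype$pnat,
        cell$phenotype$K10, cell$phenotype$pint10, set$contacts, set$faces,
        em$contact_energy, em$temperature, 0L)
      expect_equal(fast$pnat, full$pnat, tolerance = 1e-10)
      expect_equal(fast$native, full$native)
      expect_equal(fast$K10, full$K10, tolerance = 1e-8)
      expect_equal(fast$pint10, full$pint10, tolerance = 1e-10)
    }
  })
})
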