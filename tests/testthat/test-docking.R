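test_that("there are exactly 144 rigid docking modes with 9 interface pairs each", {
  modes <- enumerate_docking_modes()
  expect_equal(nrow(modes), 144)
  expect_equal(length(unique(paste(modes$face_i, modes$face_j, modes$rotation))), 144)
  expect_true(all(vapply(modes$interface_pairs, nrow, 0L) == 9))
  # every interface site really lies on the declared cube face
  axes <- c(1, 1, 2, 2, 3, 3); lvls <- c(0, 2, 0, 2, 0, 2)
  for (k in c(1, 40, 144)) {
    m <- modes$interface_pairs[[k]]
    s <- m[, 1] - 1
    xyz <- cbind(s %% 3, (s %/% 3) %% 3, s %/% 9)
    f <- modes$face_i[k]
    expect_true(all(xyz[, axes[f]] == lvls[f]))
  }
  expect_identical(modes, enumerate_docking_modes())  # deterministic
})

test_that("identical homopolymers bind with full mode degeneracy", {
  set <- tiny_set()
  em <- energy_model()
  ps <- fold(strrep("G", 27), set, em)
  b <- bind_pair(ps, ps, set, em)
  expect_equal(b$p_int, 1 / 144)
})

test_that("binding is symmetric under partner exchange", {
  set <- tiny_set()
  em <- energy_model()
  withr::with_seed(21, {
    for (k in 1:5) {
      si <- fold(random_aa(), set, em)
      sj <- fold(random_aa(), set, em)
      bij <- bind_pair(si, sj, set, em)
      bji <- bind_pair(sj, si, set, em)
      expect_equal(bij$E_int, bji$E_int, tolerance = 1e-12)
      expect_equal(bij$p_int, bji$p_int, tolerance = 1e-12)
      expect_equal(bij$K, bji$K, tolerance = 1e-12)
    }
  })
})

test_that("mode energies match an exhaustive geometric enumeration", {
  # independent oracle: score every mode from enumerate_docking_modes()
  # geometry directly in R, reading residues off the native coordinates
  set <- tiny_set()
  em <- energy_model()
  withr::with_seed(31, {
    seq_i <- paste(sample(c("A", "W"), 27, TRUE), collapse = "")
    seq_j <- paste(sample(c("A", "W"), 27, TRUE), collapse = "")
  })
  si <- fold(seq_i, set, em)
  sj <- fold(seq_j, set, em)
  modes <- enumerate_docking_modes()
  mj <- em$contact_energy
  res_at <- function(state) {
    # residue letter occupying each cube site in the native conformation
    path <- set$paths[state$native_index, ] + 1
    out <- character(27)
    out[path] <- strsplit(state$aa_seq, "")[[1]]
    out
  }
  ri <- res_at(si); rj <- res_at(sj)
  e_oracle <- vapply(modes$interface_pairs, function(m)
    sum(mj[cbind(ri[m[, 1]], rj[m[, 2]])]), 0)
  b <- bind_pair(si, sj, set, em, keep_energies = TRUE)
  expect_equal(sort(b$energies), sort(e_oracle), tolerance = 1e-12)
  expect_equal(b$E_int, min(e_oracle), tolerance = 1e-12)
  w <- exp(-(e_oracle - min(e_oracle)) / 0.85)
  expect_equal(b$p_int, 1 / sum(w), tolerance = 1e-10)
})

test_that("the three binding-constant conventions are consistent", {
  set <- tiny_set()
  em <- energy_model()
  withr::with_seed(41, s1 <- fold(random_aa(), set, em))
  withr::with_seed(42, s2 <- fold(random_aa(), set, em))
  bc <- bind_pair(s1, s2, set, em, "centered", keep_energies = TRUE)
  bm <- bind_pair(s1, s2, set, em, "min_energy")
  bs <- bind_pair(s1, s2, set, em, "mode_sum")
  expect_equal(bc$K, exp((mean(bc$energies) - bc$E_int) / 0.85), tolerance = 1e-10)
  expect_equal(bm$K, exp(-bc$E_int / 0.85), tolerance = 1e-8)
  expect_equal(bs$K, sum(exp(-bc$energies / 0.85)), tolerance = 1e-8)
  expect_equal(bc$p_int, bm$p_int)  # P_int independent of the K convention
})

test_that("interaction tables are symmetric with valid probabilities", {
  set <- tiny_set()
  em <- energy_model()
  withr::with_seed(51, states <- lapply(1:4, function(i) fold(random_aa(), set, em)))
  tab <- interaction_table(states, set, em)
  expect_true(isSymmetric(tab$E_int))
  expect_true(isSymmetric(tab$K))
  expect_true(all(tab$p_int > 0 & tab$p_int <= 1))
  expect_true(all(tab$K > 0))
})
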