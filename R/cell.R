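#' Fitness and mutation-rate parameters
#'
#' Bundles every parameter of the genotype-phenotype map. Defaults reproduce
#' the reference simulation conditions: base growth rate b0 = 707.445 (the
#' published instance; normally recalibrated per seed genome so that the seed
#' birth rate equals the death rate), optimal total protein concentration
#' C0 = 0.4, overproduction penalty coefficient sigma = 100, death rate
#' d = 0.005 per step, concentration-fluctuation probability r = 0.01 per gene
#' per step, base (wild-type) mutation rate 1e-4 and maximal rate 0.1 per gene
#' per replication, lethality stability threshold theta_nat = 0.6, and
#' temperature T = 0.85 (heat shock raises it to `T_high` = 1.00).
#'
#' `G_ref` is the functional MMR dimer concentration at which the mutation
#' rate attains its base value; it is calibrated to the designed seed cell so
#' the seed is exactly wild-type.
#'
#' @param b0 Base growth rate.
#' @param C0 Optimal total protein concentration.
#' @param sigma Overproduction penalty coefficient.
#' @param d Death probability per cell per step.
#' @param r Concentration-fluctuation probability per gene per step.
#' @param m_min,m_max Bounds of the mutation rate (per gene per replication).
#' @param G_ref Reference functional-MMR concentration (NA until calibrated).
#' @param theta_nat Stability threshold below which a mutated protein is
#'   lethal.
#' @param temperature Environmental temperature.
#' @param T_high Heat-shock temperature.
#' @param conc_floor Positivity floor applied to concentrations after
#'   fluctuation.
#' @return A `fitness_params` object.
#' @export
fitness_params <- function(b0 = 707.445, C0 = 0.4, sigma = 100, d = 0.005,
                           r = 0.01, m_min = 1e-4, m_max = 0.1, G_ref = NA_real_,
                           theta_nat = 0.6, temperature = 0.85, T_high = 1.00,
                           conc_floor = 1e-6) {
  p <- list(b0 = b0, C0 = C0, sigma = sigma, d = d, r = r, m_min = m_min,
            m_max = m_max, G_ref = G_ref, theta_nat = theta_nat,
            temperature = temperature, T_high = T_high, conc_floor = conc_floor)
  stopifnot(b0 > 0, C0 > 0, sigma >= 0, d >= 0, d <= 1, r >= 0, r <= 1,
            m_min > 0, m_max > m_min, m_min < 0.01, m_max > 0.01,
            theta_nat > 0, theta_nat < 1, temperature > 0, T_high > 0)
  structure(p, class = "fitness_params")
}

# full genotype -> phenotype map for one genome given as 108 residue ints
# (4 x 27, 0-based). Returns NULL phenotype pieces on a stop codon upstream.
genome_phenotype <- function(aa108, set, em, k_form = "centered") {
  pnat <- numeric(4); e0 <- numeric(4); native <- integer(4)
  for (g in 1:4) {
    aa <- aa108[(27 * (g - 1) + 1):(27 * g)]
    e <- .fold_energies_cpp(aa, set$contacts, em$contact_energy)
    native[g] <- which.min(e)
    e0[g] <- e[native[g]]
    pnat[g] <- 1 / sum(exp(-(e - e0[g]) / em$temperature))
  }
  K10 <- numeric(10); pint10 <- numeric(10); eint10 <- numeric(10)
  for (p in 1:10) {
    i <- PAIR_IDX[p, 1]; j <- PAIR_IDX[p, 2]
    e <- .dock_energies_cpp(
      aa108[(27 * (i - 1) + 1):(27 * i)], aa108[(27 * (j - 1) + 1):(27 * j)],
      set$faces[native[i], ], set$faces[native[j], ], em$contact_energy)
    bnd <- summarise_binding(e, em$temperature, k_form)
    K10[p] <- bnd$K; pint10[p] <- bnd$p_int; eint10[p] <- bnd$E_int
  }
  list(pnat = pnat, E0 = e0, native = native, K10 = K10,
       pint10 = pint10, Eint10 = eint10)
}

# re-fold/re-bind only the genes in `changed` (integer vector), reusing `prev`
genome_phenotype_update <- function(prev, aa108, changed, set, em,
                                    k_form = "centered") {
  ph <- prev
  for (g in changed) {
    aa <- aa108[(27 * (g - 1) + 1):(27 * g)]
    e <- .fold_energies_cpp(aa, set$contacts, em$contact_energy)
    ph$native[g] <- which.min(e)
    ph$E0[g] <- e[ph$native[g]]
    ph$pnat[g] <- 1 / sum(exp(-(e - ph$E0[g]) / em$temperature))
  }
  touched <- which(PAIR_IDX[, 1] %in% changed | PAIR_IDX[, 2] %in% changed)
  for (p in touched) {
    i <- PAIR_IDX[p, 1]; j <- PAIR_IDX[p, 2]
    e <- .dock_energies_cpp(
      aa108[(27 * (i - 1) + 1):(27 * i)], aa108[(27 * (j - 1) + 1):(27 * j)],
      set$faces[ph$native[i], ], set$faces[ph$native[j], ], em$contact_energy)
    bnd <- summarise_binding(e, em$temperature, k_form)
    ph$K10[p] <- bnd$K; ph$pint10[p] <- bnd$p_int; ph$Eint10[p] <- bnd$E_int
  }
  ph
}

# columns of the pair store (PAIR_IDX order) holding the 2-3 heterodimer and
# the MMR homodimer
P23 <- 6L
P44 <- 10L

#' Build a model cell from its genome
#'
#' Translates the four genes, folds the products over the conformation set,
#' computes the pairwise interaction table, solves the law-of-mass-action
#' equilibrium at the given total concentrations, and evaluates the birth
#' rate and mutation rate.
#'
#' @param genome Character vector of 4 genes (81 nt each).
#' @param C Numeric vector of 4 total protein concentrations.
#' @param set A `conformation_set`.
#' @param em An `energy_model`.
#' @param params A `fitness_params` (needs `G_ref` set for a meaningful
#'   mutation rate; `NA` G_ref yields `m = m_min`).
#' @return A `cell` object with the genome, concentrations, per-protein
#'   stabilities, interaction constants, equilibrium state, birth rate `b`,
#'   mutation rate `m`, and `mutator` flag.
#' @export
make_cell <- function(genome, C, set, em, params = fitness_params()) {
  stopifnot(length(genome) == 4, length(C) == 4, all(C > 0))
  aa108 <- unlist(lapply(genome, function(g) translate_int(nt_to_int(g))))
  if (anyNA(aa108))
    abort("genome contains an in-frame stop codon (lethal phenotype)",
          class = "mutatorsim_lethal_error")
  ph <- genome_phenotype(aa108, set, em)
  cell <- list(genome = genome, aa = aa108, C = C, phenotype = ph,
               lineage_id = 1L, parent_id = NA_integer_)
  refresh_cell(cell, params)
}

# recompute equilibrium, b, m from the cell's genome phenotype and C
refresh_cell <- function(cell, params) {
  ph <- cell$phenotype
  Km <- matrix(0, 4, 4)
  Km[cbind(PAIR_IDX[, 1], PAIR_IDX[, 2])] <- ph$K10
  Km[cbind(PAIR_IDX[, 2], PAIR_IDX[, 1])] <- ph$K10
  eq <- solve_lma(cell$C, Km)
  G <- functional_rcg_concentrations(eq, ph$pnat[1], ph$pnat[2], ph$pnat[3],
                                     ph$pint10[P23])
  G44 <- functional_mmr_concentration(eq, ph$pint10[P44], ph$pnat[4])
  cell$eq <- eq
  cell$G1 <- G$G1; cell$G23 <- G$G23; cell$G44 <- G44
  cell$b <- birth_rate_value(G$G1, G$G23, sum(cell$C), params)
  cell$m <- mutation_rate(G44, params)
  cell$mutator <- cell$m > 0.01
  class(cell) <- "cell"
  cell
}

#' @export
print.cell <- function(x, ...) {
  cat("<cell> b =", format(x$b), " m =", format(x$m),
      if (x$mutator) "(mutator)" else "", "\n")
  cat(" C:", format(x$C, digits = 3), "\n")
  cat(" P_nat:", format(x$phenotype$pnat, digits = 3), "\n")
  invisible(x)
}

birth_rate_value <- function(G1, G23, Csum, params) {
  b <- params$b0 * G1 * G23 / (1 + params$sigma * (Csum - params$C0)^2)
  min(max(b, 0), 1)
}

#' Birth rate of a cell
#'
#' b = b0 * G1 * G23 / (1 + sigma * (sum C_i - C0)^2), clamped to the unit interval:
#' growth requires functional protein-1 monomers and functional 2-3
#' heterodimers, and deviation of the total protein production from its
#' optimum C0 incurs a metabolic penalty.
#'
#' @param cell A `cell`.
#' @param params A `fitness_params`.
#' @return Division probability per time step.
#' @export
birth_rate <- function(cell, params = fitness_params()) {
  birth_rate_value(cell$G1, cell$G23, sum(cell$C), params)
}

#' Mutation rate from the functional MMR dimer concentration
#'
#' The replication fidelity is proportional to the concentration G44 of
#' functional mismatch-repair homodimers:
#' m = m_min + (m_max - m_min) * max(0, 1 - G44 / G_ref), so a cell with the
#' reference MMR capacity replicates at the wild-type rate m_min and a cell
#' with no functional MMR dimers at m_max.
#'
#' @param G44 Functional MMR dimer concentration (>= 0).
#' @param params A `fitness_params`; with `G_ref = NA` the rate is `m_min`.
#' @return Mutation rate per gene per replication.
#' @export
mutation_rate <- function(G44, params = fitness_params()) {
  stopifnot(all(G44 >= 0))
  if (is.na(params$G_ref)) return(rep(params$m_min, length(G44)))
  params$m_min + (params$m_max - params$m_min) * pmax(0, 1 - G44 / params$G_ref)
}

#' Is a cell a mutator?
#'
#' A mutator is a clone whose mutation rate exceeds 0.01 per gene per
#' replication, i.e. at least two orders of magnitude above the wild-type
#' rate of 1e-4. The threshold is strict: m = 0.01 exactly is not a mutator.
#'
#' @param cell A `cell`, or a numeric vector of mutation rates.
#' @return Logical.
#' @export
is_mutator <- function(cell) {
  m <- if (inherits(cell, "cell")) cell$m else cell
  m > 0.01
}

#' Epigenetic fluctuation of protein production levels
#'
#' Independently for each gene, with probability `r` the total concentration
#' is multiplied by (1 + eta), eta ~ Normal(0, 0.1); otherwise it is left
#' unchanged. Concentrations are floored at a small positive value. Each
#' change is a stochastic-switching (SS) event: heritable, mutation-free
#' variation in expression level.
#'
#' @param cell A `cell`.
#' @param params A `fitness_params` (supplies `r` and the floor).
#' @return List with the updated `cell` (equilibrium and rates refreshed) and
#'   an `events` tibble (one row per changed gene: gene, old, new).
#' @export
fluctuate_concentrations <- function(cell, params = fitness_params()) {
  hit <- runif(4) < params$r
  if (!any(hit)) return(list(cell = cell, events = fluct_events_tbl()))
  old <- cell$C[hit]
  eta <- rnorm(sum(hit), 0, 0.1)
  cell$C[hit] <- pmax(old * (1 + eta), params$conc_floor)
  cell <- refresh_cell(cell, params)
  list(cell = cell,
       events = tibble(gene = which(hit), old = old, new = cell$C[hit]))
}

fluct_events_tbl <- function() tibble(gene = integer(), old = numeric(), new = numeric())

#' Replicate a cell
#'
#' Division produces two daughters. Each daughter inherits the mother's
#' protein concentrations (epigenetic inheritance) and a genome carrying,
#' independently per gene, Poisson(m) single-nucleotide substitutions at
#' uniform positions. Mutated genes are re-translated and re-folded and the
#' equilibrium re-solved. A daughter whose mutated gene carries an in-frame
#' stop codon or folds with stability below `theta_nat` is lethal and
#' discarded.
#'
#' @param cell The mother `cell`.
#' @param set,em Conformation set and energy model.
#' @param params A `fitness_params`.
#' @return List with `daughters` (list of 0, 1 or 2 viable cells), `lethal`
#'   (number discarded), and `events` (tibble of substitutions: daughter,
#'   gene, pos, from, to, synonymous).
#' @export
replicate_cell <- function(cell, set, em, params = fitness_params()) {
  daughters <- list()
  lethal <- 0L
  ev <- list()
  for (d in 1:2) {
    n_mut <- rpois(4, cell$m)
    if (all(n_mut == 0)) { daughters[[length(daughters) + 1]] <- cell; next }
    dau <- cell
    ok <- TRUE
    changed <- which(n_mut > 0)
    for (g in changed) {
      gi <- nt_to_int(dau$genome[g])
      mut <- mutate_gene_int(gi, n_mut[g])
      dau$genome[g] <- int_to_nt(mut$gene)
      aa <- translate_int(mut$gene)
      syn <- !anyNA(aa) &&
        identical(aa, dau$aa[(27 * (g - 1) + 1):(27 * g)])
      ev[[length(ev) + 1]] <- tibble(
        daughter = d, gene = g, pos = mut$pos,
        from = NT_ORDER[mut$from + 1L], to = NT_ORDER[mut$to + 1L],
        synonymous = syn)
      if (anyNA(aa)) { ok <- FALSE; break }
      dau$aa[(27 * (g - 1) + 1):(27 * g)] <- aa
    }
    if (ok) {
      dau$phenotype <- genome_phenotype_update(cell$phenotype, dau$aa, changed,
                                               set, em)
      if (any(dau$phenotype$pnat[changed] < params$theta_nat)) ok <- FALSE
    }
    if (!ok) { lethal <- lethal + 1L; next }
    daughters[[length(daughters) + 1]] <- refresh_cell(dau, params)
  }
  list(daughters = daughters, lethal = lethal,
       events = if (length(ev)) dplyr::bind_rows(ev) else
         tibble(daughter = integer(), gene = integer(), pos = integer(),
                from = character(), to = character(), synonymous = logical()))
}
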