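#' Sequence-design settings
#'
#' Controls the Monte-Carlo search in sequence space used to build seed
#' genomes. The default thresholds place seed proteins near the stability and
#' binding levels that adapted populations settle at (P_nat around 0.85,
#' homodimer P_int around 0.6-0.8), well above the lethality cut, so the
#' mutation-rate response to stress is anchored at a realistic reference
#' MMR capacity. Acceptance is Metropolis on the design objective with a
#' geometrically annealed selection temperature.
#'
#' @param p_nat_threshold Required native-state probability of the designed
#'   protein (in (0,1)).
#' @param p_int_threshold Required native-mode homodimer binding probability
#'   (gene-4 design only).
#' @param max_steps Monte-Carlo step budget per attempt.
#' @param t_sel_start,t_sel_end Selection-temperature annealing endpoints.
#' @param max_restarts Fresh random target structures tried before giving up.
#' @return A `design_config` object.
#' @export
design_config <- function(p_nat_threshold = 0.85, p_int_threshold = 0.8,
                          max_steps = 30000, t_sel_start = 0.05,
                          t_sel_end = 0.005, max_restarts = 3) {
  stopifnot(p_nat_threshold > 0, p_nat_threshold < 1,
            p_int_threshold > 0, p_int_threshold < 1, max_steps >= 1)
  structure(list(p_nat_threshold = p_nat_threshold,
                 p_int_threshold = p_int_threshold,
                 max_steps = max_steps, t_sel_start = t_sel_start,
                 t_sel_end = t_sel_end, max_restarts = max_restarts),
            class = "design_config")
}

# Boltzmann probability of the designated conformation given the energy
# spectrum
p_target <- function(e, target, temperature) {
  1 / sum(exp(-(e - e[target]) / temperature))
}

# Metropolis Monte Carlo in sequence space maximizing `objective(aa)`, a
# function returning a scalar in [0, 1]-ish scale; proposals are single
# residue substitutions. Stops when `done(aa, obj)` is TRUE.
design_mc <- function(aa0, objective, done, cfg) {
  aa <- aa0
  obj <- objective(aa)
  cool <- (cfg$t_sel_end / cfg$t_sel_start)^(1 / cfg$max_steps)
  t_sel <- cfg$t_sel_start
  for (s in seq_len(cfg$max_steps)) {
    if (done(aa, obj)) return(list(aa = aa, objective = obj, steps = s - 1L))
    pos <- sample.int(27, 1)
    new_res <- sample.int(20, 1) - 1L
    if (new_res == aa[pos]) next
    aa2 <- aa
    aa2[pos] <- new_res
    obj2 <- objective(aa2)
    if (obj2 >= obj || runif(1) < exp((obj2 - obj) / t_sel)) {
      aa <- aa2; obj <- obj2
    }
    t_sel <- t_sel * cool
  }
  if (done(aa, obj)) return(list(aa = aa, objective = obj, steps = cfg$max_steps))
  NULL
}

#' Design a gene encoding a protein stable in a chosen native structure
#'
#' Monte-Carlo search in sequence space (random residue substitutions with
#' Metropolis acceptance on the stability objective) until the designated
#' structure is the unique energy minimum and its Boltzmann probability
#' reaches the configured threshold. The sequence is back-translated into an
#' 81-nt gene using uniformly random synonymous codons.
#'
#' @param structure_index Index of the designated native structure in `set`.
#' @param set A `conformation_set`.
#' @param em An `energy_model`.
#' @param cfg A `design_config`.
#' @return The 81-nt gene (character), with attributes `p_nat` and
#'   `structure_index`.
#' @export
design_stable_gene <- function(structure_index, set, em, cfg = design_config()) {
  stopifnot(structure_index >= 1, structure_index <= set$count)
  fold_e <- function(aa) .fold_energies_cpp(aa, set$contacts, em$contact_energy)
  objective <- function(aa) p_target(fold_e(aa), structure_index, em$temperature)
  done <- function(aa, obj) {
    if (obj < cfg$p_nat_threshold) return(FALSE)
    e <- fold_e(aa)
    e[structure_index] < min(e[-structure_index])  # unique native minimum
  }
  res <- design_mc(sample.int(20, 27, replace = TRUE) - 1L, objective, done, cfg)
  if (is.null(res))
    abort("stable-gene design failed within the step budget",
          class = "mutatorsim_design_error")
  structure(int_to_nt(back_translate_int(res$aa)),
            p_nat = res$objective, structure_index = structure_index)
}

#' Design the MMR gene: stable and strongly homodimerizing
#'
#' Joint Monte-Carlo objective: the designated structure must be the unique
#' native minimum with stability above the threshold, and the protein's
#' homodimer must occupy its lowest-energy docking mode with probability
#' above the binding threshold. Interactions with the other gene products are
#' left undesigned.
#'
#' @inheritParams design_stable_gene
#' @return The 81-nt gene (character), with attributes `p_nat`, `p_int` and
#'   `structure_index`.
#' @export
design_homodimer_gene <- function(structure_index, set, em, cfg = design_config()) {
  stopifnot(structure_index >= 1, structure_index <= set$count)
  fold_e <- function(aa) .fold_energies_cpp(aa, set$contacts, em$contact_energy)
  pint_self <- function(aa) {
    e <- .dock_energies_cpp(aa, aa, set$faces[structure_index, ],
                            set$faces[structure_index, ], em$contact_energy)
    1 / sum(exp(-(e - min(e)) / em$temperature))
  }
  # progress on stability and binding jointly: the lagging objective drives
  objective <- function(aa) {
    pn <- p_target(fold_e(aa), structure_index, em$temperature)
    pi <- pint_self(aa)
    min(pn / cfg$p_nat_threshold, pi / cfg$p_int_threshold)
  }
  done <- function(aa, obj) {
    if (obj < 1) return(FALSE)
    e <- fold_e(aa)
    e[structure_index] < min(e[-structure_index])
  }
  res <- design_mc(sample.int(20, 27, replace = TRUE) - 1L, objective, done, cfg)
  if (is.null(res))
    abort("homodimer-gene design failed within the step budget",
          class = "mutatorsim_design_error")
  aa <- res$aa
  structure(int_to_nt(back_translate_int(aa)),
            p_nat = p_target(fold_e(aa), structure_index, em$temperature),
            p_int = pint_self(aa), structure_index = structure_index)
}

#' Design a complete seed genome
#'
#' Draws four native structures uniformly at random from the set, designs
#' genes 1-3 for stability and gene 4 for stability plus strong
#' homodimerization. Interactions among the replication-controlling gene
#' products are left undesigned, so seed populations start from unadapted
#' growth conditions. Failed attempts are retried with a fresh random
#' structure up to `cfg$max_restarts` times per gene.
#'
#' @param set A `conformation_set`.
#' @param em An `energy_model`.
#' @param cfg A `design_config`.
#' @return List with `genome` (4 genes), `structures` (native structure
#'   indices), `p_nat` (achieved stabilities) and `p_int44` (achieved
#'   homodimer binding probability).
#' @export
design_seed_genome <- function(set, em, cfg = design_config()) {
  genome <- character(4)
  structures <- integer(4)
  p_nat <- numeric(4)
  p_int44 <- NA_real_
  for (g in 1:4) {
    gene <- NULL
    for (try in seq_len(cfg$max_restarts)) {
      target <- sample.int(set$count, 1)
      gene <- tryCatch(
        if (g < 4) design_stable_gene(target, set, em, cfg)
        else design_homodimer_gene(target, set, em, cfg),
        mutatorsim_design_error = function(e) NULL)
      if (!is.null(gene)) break
    }
    if (is.null(gene))
      abort(sprintf("seed design failed for gene %d", g),
            class = "mutatorsim_design_error")
    genome[g] <- gene
    structures[g] <- attr(gene, "structure_index")
    p_nat[g] <- attr(gene, "p_nat")
    if (g == 4) p_int44 <- attr(gene, "p_int")
  }
  list(genome = genome, structures = structures, p_nat = p_nat,
       p_int44 = p_int44)
}
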