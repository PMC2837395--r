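# ---- population state --------------------------------------------------
# The population is stored as parallel arrays (one row per cell): genomes as
# 0..3 integers, translated products as 0..19 integers, per-gene stabilities,
# the 10 pairwise binding constants / native-mode probabilities, total
# concentrations, rates, and identifiers. This matrix layout keeps the per
# step cost dominated by a handful of vectorized operations.

new_population <- function(geno324, aa108, ph, C4, params, n, r_cell = NULL,
                           lineage = NULL) {
  pop <- list(
    n = n,
    geno = matrix(rep(geno324, each = n), n, 324),
    aa = matrix(rep(aa108, each = n), n, 108),
    pnat = matrix(rep(ph$pnat, each = n), n, 4),
    native = matrix(rep(ph$native, each = n), n, 4),
    K10 = matrix(rep(ph$K10, each = n), n, 10),
    pint23 = rep(ph$pint10[P23], n),
    pint44 = rep(ph$pint10[P44], n),
    C = matrix(rep(C4, each = n), n, 4),
    b = numeric(n), m = numeric(n), mut = logical(n),
    id = seq_len(n),
    lineage = lineage %||% seq_len(n),
    r = r_cell %||% rep(params$r, n),
    next_id = n + 1L
  )
  rates <- pop_rates(pop, params, seq_len(n))
  pop$b <- rates$b; pop$m <- rates$m; pop$mut <- rates$m > 0.01
  pop
}

# equilibrium + rates for the rows in `idx`
pop_rates <- function(pop, params, idx) {
  eq <- solve_lma_matrix(pop$C[idx, , drop = FALSE], pop$K10[idx, , drop = FALSE])
  G1 <- eq$F[, 1] * pop$pnat[idx, 1]
  G23 <- eq$F_pair[, P23] * pop$pint23[idx] * pop$pnat[idx, 2] * pop$pnat[idx, 3]
  G44 <- eq$F_pair[, P44] * pop$pint44[idx] * pop$pnat[idx, 4]^2
  b <- if (!is.null(params$constant_b)) rep(params$constant_b, length(idx)) else {
    raw <- params$b0 * G1 * G23 /
      (1 + params$sigma * (rowSums(pop$C[idx, , drop = FALSE]) - params$C0)^2)
    pmin(pmax(raw, 0), 1)
  }
  list(b = b, m = mutation_rate(G44, params), G1 = G1, G23 = G23, G44 = G44)
}

pop_subset <- function(pop, keep) {
  pop$geno <- pop$geno[keep, , drop = FALSE]
  pop$aa <- pop$aa[keep, , drop = FALSE]
  pop$pnat <- pop$pnat[keep, , drop = FALSE]
  pop$native <- pop$native[keep, , drop = FALSE]
  pop$K10 <- pop$K10[keep, , drop = FALSE]
  pop$pint23 <- pop$pint23[keep]
  pop$pint44 <- pop$pint44[keep]
  pop$C <- pop$C[keep, , drop = FALSE]
  pop$b <- pop$b[keep]; pop$m <- pop$m[keep]; pop$mut <- pop$mut[keep]
  pop$id <- pop$id[keep]; pop$lineage <- pop$lineage[keep]; pop$r <- pop$r[keep]
  pop$n <- length(pop$id)
  pop
}

# ---- event accumulator -------------------------------------------------

new_acc <- function() {
  acc <- new.env(parent = emptyenv())
  acc$chunks <- vector("list", 256)
  acc$k <- 0L
  acc
}

acc_add <- function(acc, .type, ...) {
  acc$k <- acc$k + 1L
  if (acc$k > length(acc$chunks)) length(acc$chunks) <- 2L * length(acc$chunks)
  acc$chunks[[acc$k]] <- c(list(.type = .type), list(...))
  invisible(acc)
}

acc_events <- function(acc) {
  chunks <- acc$chunks[seq_len(acc$k)]
  if (!length(chunks)) return(empty_event_log())
  tbl <- dplyr::bind_rows(lapply(seq_along(chunks), function(i) {
    ch <- chunks[[i]]
    df <- tibble::as_tibble(ch[setdiff(names(ch), ".type")])
    df$type <- ch$.type
    df$seq <- i
    df
  }))
  cols <- names(empty_event_log())
  for (cl in setdiff(cols, names(tbl))) tbl[[cl]] <- empty_event_log()[[cl]][0][1]
  dplyr::arrange(tbl[cols], t, seq)
}

empty_event_log <- function() {
  tibble(t = integer(), seq = integer(), type = character(),
         cell = integer(), lineage = integer(), mother = integer(),
         gene = integer(), pos = integer(), from = character(),
         to = character(), synonymous = logical(), old = numeric(),
         new = numeric(), direction = character(), cause = character(),
         param = character())
}

# ---- one time step -----------------------------------------------------
# Per-cell order of play: (1) concentration fluctuation, (2) equilibrium and
# rate refresh for affected cells (mutator flips logged with their proximal
# cause), (3) death, (4) division with mutation, lethality screening of
# daughters, (5) random culling back to the carrying capacity.

step_population <- function(pop, params, set, em, t, acc, opts) {
  n <- pop$n
  # (1) epigenetic fluctuation of production levels
  hit <- matrix(runif(4L * n) < pop$r, n, 4)
  dirty <- integer(0)
  if (any(hit)) {
    ih <- which(hit, arr.ind = TRUE)
    old <- pop$C[ih]
    eta <- rnorm(nrow(ih), 0, 0.1)
    pop$C[ih] <- pmax(old * (1 + eta), params$conc_floor)
    acc_add(acc, "fluctuation", t = t, cell = pop$id[ih[, 1]],
            lineage = pop$lineage[ih[, 1]], gene = as.integer(ih[, 2]),
            old = old, new = pop$C[ih])
    dirty <- unique(ih[, 1])
  }
  # (2) refresh rates, log mutator flips due to stochastic switching
  if (length(dirty)) {
    rates <- pop_rates(pop, params, dirty)
    newmut <- rates$m > 0.01
    flipped <- which(newmut != pop$mut[dirty])
    if (length(flipped)) {
      rows <- dirty[flipped]
      cause <- ifelse(hit[rows, 4], "SS", "unattributed")
      acc_add(acc, "flip", t = t, cell = pop$id[rows], lineage = pop$lineage[rows],
              direction = ifelse(newmut[flipped], "to_mutator", "to_nonmutator"),
              cause = cause)
    }
    pop$b[dirty] <- rates$b; pop$m[dirty] <- rates$m; pop$mut[dirty] <- newmut
  }
  # (3) death
  dead <- runif(n) < params$d
  # (4) division
  divide <- !dead & (runif(n) < pop$b)
  keep <- which(!dead & !divide)
  div <- which(divide)
  n_deaths <- sum(dead)
  if (n_deaths && opts$log_divisions)
    acc_add(acc, "death", t = t, cell = pop$id[dead])
  n_births <- 0L; n_lethal <- 0L
  if (length(div)) {
    ndau <- 2L * length(div)
    mother_of <- rep(div, each = 2)
    src <- c(keep, mother_of)
    first_dau <- length(keep) + 1L
    pop2 <- pop_subset(pop, src)
    dau_rows <- first_dau:(first_dau + ndau - 1L)
    pop2$id[dau_rows] <- pop$next_id + seq_len(ndau) - 1L
    pop2$next_id <- pop$next_id + ndau
    if (opts$log_divisions)
      acc_add(acc, "division", t = t, cell = pop2$id[dau_rows],
              mother = pop$id[mother_of], lineage = pop2$lineage[dau_rows])
    # substitutions: Poisson(m) per gene per daughter
    lam <- pop$m[mother_of]
    nm <- matrix(rpois(4L * ndau, rep(lam, times = 4)), ndau, 4)
    lethal_dau <- logical(ndau)
    mut_rows <- which(rowSums(nm) > 0)
    mut_dirty <- integer(length(mut_rows))
    nd <- 0L
    # batched per-step logging buffers (one event row per substitution)
    ev <- list(cell = integer(0), lineage = integer(0), mother = integer(0),
               gene = integer(0), pos = integer(0), from = integer(0),
               to = integer(0), syn = logical(0))
    for (k in mut_rows) {
      row <- first_dau + k - 1L
      changed <- which(nm[k, ] > 0)
      ok <- TRUE
      for (g in changed) {
        cols <- (81L * (g - 1L) + 1L):(81L * g)
        mut <- mutate_gene_int(pop2$geno[row, cols], nm[k, g])
        pop2$geno[row, cols] <- mut$gene
        aa <- translate_int(mut$gene)
        acols <- (27L * (g - 1L) + 1L):(27L * g)
        syn <- !anyNA(aa) && identical(aa, pop2$aa[row, acols])
        np <- length(mut$pos)
        ev$cell <- c(ev$cell, rep(pop2$id[row], np))
        ev$lineage <- c(ev$lineage, rep(pop2$lineage[row], np))
        ev$mother <- c(ev$mother, rep(pop$id[mother_of[k]], np))
        ev$gene <- c(ev$gene, rep(g, np))
        ev$pos <- c(ev$pos, mut$pos)
        ev$from <- c(ev$from, mut$from)
        ev$to <- c(ev$to, mut$to)
        ev$syn <- c(ev$syn, rep(syn, np))
        if (anyNA(aa)) { ok <- FALSE; break }
        pop2$aa[row, acols] <- aa
      }
      if (ok) {
        ph <- .mutant_phenotype_cpp(
          pop2$aa[row, ], changed, pop2$native[row, ], pop2$pnat[row, ],
          pop2$K10[row, ],
          replace(replace(numeric(10), P23, pop2$pint23[row]),
                  P44, pop2$pint44[row]),
          set$contacts, set$faces, em$contact_energy, em$temperature,
          opts$k_code)
        if (any(ph$pnat[changed] < params$theta_nat)) ok <- FALSE else {
          pop2$pnat[row, ] <- ph$pnat; pop2$native[row, ] <- ph$native
          pop2$K10[row, ] <- ph$K10
          pop2$pint23[row] <- ph$pint10[P23]; pop2$pint44[row] <- ph$pint10[P44]
          nd <- nd + 1L
          mut_dirty[nd] <- row
        }
      }
      if (!ok) lethal_dau[k] <- TRUE
    }
    mut_dirty <- mut_dirty[seq_len(nd)]
    if (length(ev$cell))
      acc_add(acc, "mutation", t = t, cell = ev$cell, lineage = ev$lineage,
              mother = ev$mother, gene = ev$gene, pos = ev$pos,
              from = NT_ORDER[ev$from + 1L], to = NT_ORDER[ev$to + 1L],
              synonymous = ev$syn)
    # rates for viable mutated daughters; flips are relative to the mother
    if (length(mut_dirty)) {
      rates <- pop_rates(pop2, params, mut_dirty)
      newmut <- rates$m > 0.01
      flipped <- which(newmut != pop2$mut[mut_dirty])
      if (length(flipped)) {
        rows <- mut_dirty[flipped]
        # proximal cause: a gene-4 substitution at this replication,
        # otherwise unattributed
        g4 <- nm[rows - first_dau + 1L, 4] > 0
        acc_add(acc, "flip", t = t, cell = pop2$id[rows],
                lineage = pop2$lineage[rows],
                direction = ifelse(newmut[flipped], "to_mutator", "to_nonmutator"),
                cause = ifelse(g4, "Mut", "unattributed"))
      }
      pop2$b[mut_dirty] <- rates$b; pop2$m[mut_dirty] <- rates$m
      pop2$mut[mut_dirty] <- newmut
    }
    n_lethal <- sum(lethal_dau)
    if (n_lethal) {
      drop_rows <- first_dau + which(lethal_dau) - 1L
      acc_add(acc, "lethal", t = t, cell = pop2$id[drop_rows],
              mother = pop$id[mother_of[lethal_dau]])
      pop2 <- pop_subset(pop2, setdiff(seq_len(pop2$n), drop_rows))
    }
    n_births <- pop2$n - length(keep)
    pop <- pop2
  } else {
    pop <- pop_subset(pop, keep)
  }
  # (5) chemostat culling
  n_culled <- 0L
  if (pop$n > opts$cap) {
    n_culled <- pop$n - opts$cap
    keep2 <- sort(sample.int(pop$n, opts$cap))
    if (opts$log_divisions)
      acc_add(acc, "cull", t = t, cell = pop$id[-keep2])
    pop <- pop_subset(pop, keep2)
  }
  attr(pop, "counts") <- c(births = n_births, deaths = n_deaths,
                           lethal = n_lethal, culled = n_culled)
  pop
}

# ---- stress protocols --------------------------------------------------

#' Define a stress protocol
#'
#' Exactly one environmental parameter changes at `t_apply`: heat shock raises
#' the temperature to `T_high` (0.85 -> 1.00), stationary phase drops the base
#' growth rate threefold (707.445 -> 235.815 at the reference calibration),
#' and starvation drops the optimal production level tenfold (0.4 -> 0.04).
#'
#' @param kind One of `"heat_shock"`, `"stationary_phase"`, `"starvation"`.
#' @param t_apply Time step at which the stress is applied.
#' @param new_value Optional explicit override for the changed parameter;
#'   defaults to the protocol's standard change.
#' @return A `stress_protocol` object.
#' @export
stress_protocol <- function(kind = c("heat_shock", "stationary_phase", "starvation"),
                            t_apply = 20000, new_value = NULL) {
  if (length(kind) != 1 || !kind %in% c("heat_shock", "stationary_phase", "starvation"))
    abort(paste0("unknown stress kind: ", paste(kind, collapse = "/")),
          class = "mutatorsim_config_error")
  structure(list(kind = kind, t_apply = as.integer(t_apply), new_value = new_value),
            class = "stress_protocol")
}

#' Apply a stress protocol to the simulation parameters
#'
#' Pure parameter transform: returns a `fitness_params` in which exactly the
#' protocol's one parameter has changed. Applying a second stress to
#' already-stressed parameters is an error (single-change contract).
#'
#' @param params A `fitness_params`.
#' @param protocol A `stress_protocol`.
#' @return The modified `fitness_params`.
#' @export
apply_stress <- function(params, protocol) {
  if (!inherits(protocol, "stress_protocol"))
    abort("`protocol` must be a stress_protocol", class = "mutatorsim_config_error")
  if (!is.null(params$stress_applied))
    abort("a stress has already been applied to these parameters",
          class = "mutatorsim_config_error")
  kind <- protocol$kind
  if (kind == "heat_shock") {
    new <- protocol$new_value %||% params$T_high
    if (new == params$temperature)
      abort("temperature already at the stressed value",
            class = "mutatorsim_config_error")
    params$temperature <- new
  } else if (kind == "stationary_phase") {
    params$b0 <- protocol$new_value %||% (params$b0 / 3)
  } else if (kind == "starvation") {
    params$C0 <- protocol$new_value %||% (params$C0 / 10)
  }
  params$stress_applied <- kind
  params
}

# refold every cell after a temperature change (stabilities, native states
# and binding constants all shift); phenotypes are recomputed per distinct
# genome
refold_population <- function(pop, set, em, k_form) {
  key <- apply(pop$aa, 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  phs <- lapply(which(uniq), function(rw) genome_phenotype(pop$aa[rw, ], set, em, k_form))
  names(phs) <- key[uniq]
  for (rw in seq_len(pop$n)) {
    ph <- phs[[key[rw]]]
    pop$pnat[rw, ] <- ph$pnat; pop$native[rw, ] <- ph$native
    pop$K10[rw, ] <- ph$K10
    pop$pint23[rw] <- ph$pint10[P23]; pop$pint44[rw] <- ph$pint10[P44]
  }
  pop
}

# ---- full evolutionary run --------------------------------------------

#' Run an evolutionary simulation
#'
#' Initializes a clonal population of `n_seed` cells carrying the seed genome
#' (designed on the fly unless supplied), calibrates `G_ref` so the seed is
#' exactly wild-type (m = m_min) and `b0` so the seed birth rate equals the
#' death rate, then iterates the population dynamics to `t_max`, applying the
#' configured stress protocol at `t_apply`. All randomness derives from
#' `config$seed`.
#'
#' @param config A `run_config`.
#' @param structure_set Optional pre-built `conformation_set`; when `NULL` the
#'   full enumeration is computed and subsampled to `config$n_struct`
#'   structures.
#' @param seed_genome Optional character vector of 4 genes (81 nt); when
#'   `NULL` a seed genome is designed (genes 1-3 stable, gene 4 stable and
#'   strongly homodimerizing).
#' @return An `evolution_run` object: `time_series` (tibble of population
#'   summaries), `events` (tibble event log), `config`, `params` (post-run),
#'   `population` (final state), `meta` (calibrated b0 and G_ref, extinction
#'   flag, seed genome, designed structures).
#' @export
run_evolution <- function(config = run_config(), structure_set = NULL,
                          seed_genome = NULL) {
  config <- validate_config(config)
  set.seed(config$seed)
  seeds <- sample.int(2^31 - 1, 4)
  if (is.null(structure_set)) {
    full <- enumerate_compact_conformations()
    structure_set <- if (config$n_struct < full$count)
      sample_structure_set(full, config$n_struct, seeds[1]) else full
  }
  em <- energy_model(config$T)
  params <- fitness_params(
    b0 = config$b0, C0 = config$C0,
    sigma = config$sigma, d = config$d, r = config$r, m_min = config$m_min,
    m_max = config$m_max, G_ref = config$G_ref, theta_nat = config$theta_nat,
    temperature = config$T, T_high = config$T_high)
  design_meta <- NULL
  if (is.null(seed_genome)) {
    set.seed(seeds[2])
    des <- design_seed_genome(structure_set, em,
                              design_config(p_nat_threshold = config$design$p_nat_threshold,
                                            p_int_threshold = config$design$p_int_threshold,
                                            max_steps = config$design$max_steps))
    seed_genome <- des$genome
    design_meta <- des[c("structures", "p_nat", "p_int44")]
  }
  C_init <- config$C_init %||% rep(config$C0 / 4, 4)
  aa108 <- unlist(lapply(seed_genome, function(g) translate_int(nt_to_int(g))))
  if (anyNA(aa108))
    abort("seed genome contains an in-frame stop codon",
          class = "mutatorsim_sequence_error")
  geno324 <- unlist(lapply(seed_genome, nt_to_int))
  ph <- genome_phenotype(aa108, structure_set, em, config$k_form)
  eq0 <- solve_lma_matrix(matrix(C_init, 1), matrix(ph$K10, 1))
  G1 <- eq0$F[1, 1] * ph$pnat[1]
  G23 <- eq0$F_pair[1, P23] * ph$pint10[P23] * ph$pnat[2] * ph$pnat[3]
  G44 <- eq0$F_pair[1, P44] * ph$pint10[P44] * ph$pnat[4]^2
  if (is.na(params$G_ref)) params$G_ref <- G44
  if (config$protocol == "constant_fitness") params$constant_b <- config$constant_b
  if (config$calibrate_b0 && is.null(params$constant_b))
    params$b0 <- params$d *
      (1 + params$sigma * (sum(C_init) - params$C0)^2) / (G1 * G23)
  pop <- new_population(geno324, aa108, ph, C_init, params, config$n_seed)
  run_dynamics(pop, params, structure_set, em, config,
               list(seed_genome = seed_genome, design = design_meta,
                    b0 = params$b0, G_ref = params$G_ref))
}

# shared driver for run_evolution / run_competition
run_dynamics <- function(pop, params, set, em, config, meta) {
  opts <- list(cap = config$cap, log_divisions = config$log_divisions,
               k_form = config$k_form,
               k_code = match(config$k_form,
                              c("centered", "min_energy", "mode_sum")) - 1L)
  acc <- new_acc()
  nrec <- length(seq(0, config$t_max, by = config$record_every)) + 1L
  ts <- matrix(NA_real_, nrec, 20)
  colnames(ts) <- c("t", "n", "mean_b", "mean_m", "mutator_freq",
                    "mean_C1", "mean_C2", "mean_C3", "mean_C4",
                    "mean_pnat1", "mean_pnat2", "mean_pnat3", "mean_pnat4",
                    "mean_pint23", "mean_pint44", "frac_lineage1",
                    "births", "deaths", "lethal", "culled")
  rec <- function(row, t, pop, counts) {
    ts[row, ] <<- c(t, pop$n, mean(pop$b), mean(pop$m), mean(pop$mut),
                    colMeans(pop$C), colMeans(pop$pnat), mean(pop$pint23),
                    mean(pop$pint44), mean(pop$lineage == 1L), counts)
  }
  rec(1, 0L, pop, c(0, 0, 0, 0))
  row <- 1L
  extinct <- FALSE
  protocol <- if (config$protocol %in% c("heat_shock", "stationary_phase", "starvation"))
    stress_protocol(config$protocol, config$t_apply, config$stress_new_value)
  for (t in seq_len(config$t_max)) {
    if (!is.null(protocol) && t == protocol$t_apply) {
      old_T <- params$temperature
      params <- apply_stress(params, protocol)
      acc_add(acc, "stress", t = t, param = protocol$kind)
      if (params$temperature != old_T) {
        em <- energy_model(params$temperature, em$contact_energy)
        pop <- refold_population(pop, set, em, opts$k_form)
      }
      rates <- pop_rates(pop, params, seq_len(pop$n))
      newmut <- rates$m > 0.01
      flipped <- which(newmut != pop$mut)
      if (length(flipped))
        acc_add(acc, "flip", t = t, cell = pop$id[flipped],
                lineage = pop$lineage[flipped],
                direction = ifelse(newmut[flipped], "to_mutator", "to_nonmutator"),
                cause = "Env")
      pop$b <- rates$b; pop$m <- rates$m; pop$mut <- newmut
    }
    pop <- step_population(pop, params, set, em, t, acc, opts)
    counts <- attr(pop, "counts")
    if (pop$n == 0L) {
      extinct <- TRUE
      row <- row + 1L
      ts[row, ] <- c(t, 0, rep(NA_real_, 14), counts)
      break
    }
    if (t %% config$record_every == 0L) {
      row <- row + 1L
      rec(row, t, pop, counts)
    }
  }
  meta$extinct <- extinct
  meta$t_end <- if (extinct) t else config$t_max
  structure(list(
    time_series = tibble::as_tibble(ts[seq_len(row), , drop = FALSE]),
    events = acc_events(acc),
    config = config, params = params, population = pop, meta = meta
  ), class = "evolution_run")
}

#' @export
print.evolution_run <- function(x, ...) {
  last <- x$time_series[nrow(x$time_series), ]
  cat("<evolution_run>", x$meta$t_end, "steps,",
      if (x$meta$extinct) "EXTINCT," else paste(last$n, "cells,"),
      "final mean b =", format(last$mean_b, digits = 3),
      " mutator freq =", format(last$mutator_freq, digits = 3), "\n")
  invisible(x)
}

# ---- competition and constant-fitness controls ------------------------

#' Competition between fluctuating and non-fluctuating phenotypes
#'
#' Seeds `n_seed` organisms at fluctuation rate `r_high` (lineage 1) and
#' `n_seed` at `r_low` (lineage 2), both carrying the same seed genome, and
#' tracks the fractional population of the high-fluctuation lineage.
#'
#' @param config A `run_config` (the `r` field is overridden per lineage).
#' @param r_high,r_low Fluctuation rates of the two competing lineages.
#' @param replicates Number of independent runs (>= 1).
#' @param structure_set,seed_genome As in [run_evolution()].
#' @return A tibble with columns `replicate`, `t`, `fraction` (share of the
#'   `r_high` lineage), `n`, `mean_b`; one row per recorded step.
#' @export
run_competition <- function(config = run_config(), r_high = 0.01, r_low = 0,
                            replicates = 1, structure_set = NULL,
                            seed_genome = NULL) {
  config <- validate_config(config)
  if (replicates < 1) abort("`replicates` must be >= 1",
                            class = "mutatorsim_config_error")
  set.seed(config$seed)
  rep_seeds <- sample.int(2^31 - 1, replicates)
  if (is.null(structure_set)) {
    full <- enumerate_compact_conformations()
    structure_set <- if (config$n_struct < full$count)
      sample_structure_set(full, config$n_struct, config$seed) else full
  }
  purrr::map_dfr(seq_len(replicates), function(rr) {
    cfg <- config
    cfg$seed <- rep_seeds[rr]
    set.seed(cfg$seed)
    seeds <- sample.int(2^31 - 1, 4)
    em <- energy_model(cfg$T)
    params <- fitness_params(C0 = cfg$C0, sigma = cfg$sigma, d = cfg$d,
                             r = r_high, m_min = cfg$m_min, m_max = cfg$m_max,
                             theta_nat = cfg$theta_nat, temperature = cfg$T,
                             T_high = cfg$T_high)
    genome <- seed_genome
    if (is.null(genome)) {
      set.seed(seeds[2])
      des <- design_seed_genome(structure_set, em,
                                design_config(p_nat_threshold = cfg$design$p_nat_threshold,
                                              p_int_threshold = cfg$design$p_int_threshold,
                                              max_steps = cfg$design$max_steps))
      genome <- des$genome
    }
    C_init <- cfg$C_init %||% rep(cfg$C0 / 4, 4)
    aa108 <- unlist(lapply(genome, function(g) translate_int(nt_to_int(g))))
    geno324 <- unlist(lapply(genome, nt_to_int))
    ph <- genome_phenotype(aa108, structure_set, em, cfg$k_form)
    eq0 <- solve_lma_matrix(matrix(C_init, 1), matrix(ph$K10, 1))
    G1 <- eq0$F[1, 1] * ph$pnat[1]
    G23 <- eq0$F_pair[1, P23] * ph$pint10[P23] * ph$pnat[2] * ph$pnat[3]
    G44 <- eq0$F_pair[1, P44] * ph$pint10[P44] * ph$pnat[4]^2
    params$G_ref <- G44
    params$b0 <- params$d *
      (1 + params$sigma * (sum(C_init) - params$C0)^2) / (G1 * G23)
    n2 <- 2L * cfg$n_seed
    pop <- new_population(geno324, aa108, ph, C_init, params, n2,
                          r_cell = rep(c(r_high, r_low), each = cfg$n_seed),
                          lineage = rep(c(1L, 2L), each = cfg$n_seed))
    set.seed(seeds[3])
    run <- run_dynamics(pop, params, structure_set, em, cfg,
                        list(seed_genome = genome, b0 = params$b0,
                             G_ref = params$G_ref))
    dplyr::transmute(run$time_series, replicate = rr, t = .data$t,
                     fraction = .data$frac_lineage1, n = .data$n,
                     mean_b = .data$mean_b)
  })
}

#' Constant-fitness drift control
#'
#' Runs simulations in which the birth rate is a fixed constant (decoupled
#' from the genome) while the protein structural constraint is retained:
#' daughters whose mutated proteins drop below the stability threshold are
#' still discarded, and the MMR system still sets the mutation rate. The
#' mutator frequency is sampled on a regular grid and ensemble-averaged,
#' isolating the supply/drift balance of mutators from hitchhiking.
#'
#' @param b_values Constant birth rates to test (each in (0, 1]).
#' @param config A `run_config`; `t_max` must cover the sampling window.
#' @param replicates Runs per birth rate.
#' @param sample_every Sampling period in steps.
#' @param window Two-element vector: sampling window (half-open, samples at
#'   `window[1] + k * sample_every <= window[2]`).
#' @param structure_set,seed_genome As in [run_evolution()].
#' @return A tibble `(b, mean_freq, n_samples)`, one row per tested birth
#'   rate, with the per-sample records in the `samples` attribute.
#' @export
run_constant_fitness <- function(b_values, config = run_config(),
                                 replicates = 3, sample_every = 25,
                                 window = c(8000, 10000),
                                 structure_set = NULL, seed_genome = NULL) {
  if (!length(b_values) || any(b_values <= 0) || any(b_values > 1))
    abort("`b_values` must be in (0, 1]", class = "mutatorsim_config_error")
  config <- validate_config(config)
  if (config$t_max < window[2])
    abort("`t_max` must cover the sampling window", class = "mutatorsim_config_error")
  set.seed(config$seed)
  seeds <- matrix(sample.int(2^31 - 1, length(b_values) * replicates),
                  length(b_values), replicates)
  if (is.null(structure_set)) {
    full <- enumerate_compact_conformations()
    structure_set <- if (config$n_struct < full$count)
      sample_structure_set(full, config$n_struct, config$seed) else full
  }
  sample_t <- seq(window[1] + sample_every, window[2], by = sample_every)
  samples <- purrr::map_dfr(seq_along(b_values), function(bi) {
    purrr::map_dfr(seq_len(replicates), function(rr) {
      cfg <- config
      cfg$seed <- seeds[bi, rr]
      cfg$protocol <- "constant_fitness"
      cfg$constant_b <- b_values[bi]
      cfg$record_every <- 1L
      run <- run_evolution(cfg, structure_set = structure_set,
                           seed_genome = seed_genome)
      dplyr::transmute(
        dplyr::filter(run$time_series, .data$t %in% sample_t),
        b = b_values[bi], replicate = rr, t = .data$t,
        freq = .data$mutator_freq)
    })
  })
  out <- dplyr::summarise(dplyr::group_by(samples, .data$b),
                          mean_freq = mean(.data$freq, na.rm = TRUE),
                          n_samples = sum(!is.na(.data$freq)), .groups = "drop")
  attr(out, "samples") <- samples
  out
}
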