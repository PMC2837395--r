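#' Fold a 27-mer sequence over a conformation set
#'
#' Computes the conformational energy of the sequence in every conformation of
#' the set (the sum of contact energies over the 28 non-bonded contacts),
#' identifies the native conformation as the energy minimum (ties broken to
#' the lowest conformation index), and evaluates the thermal stability
#' P_nat = exp(-E0/T) / sum_c exp(-E_c/T), the Boltzmann probability of
#' occupying the native conformation within the set.
#'
#' @param aa_seq 27-letter amino-acid string (standard one-letter codes).
#' @param set A `conformation_set`.
#' @param em An `energy_model`.
#' @param keep_energies Keep the full energy spectrum in the result (used by
#'   diagnostics; off by default to save memory).
#' @return A `protein_state` object with fields `aa_seq`, `native_index`
#'   (index into `set`), `E0` (native energy) and `p_nat`.
#' @export
fold <- function(aa_seq, set, em, keep_energies = FALSE) {
  stopifnot(inherits(set, "conformation_set"), inherits(em, "energy_model"))
  if (!is.character(aa_seq) || length(aa_seq) != 1 || nchar(aa_seq) != 27)
    abort("`aa_seq` must be a single 27-letter string", class = "mutatorsim_alphabet_error")
  aa <- aa_to_int(aa_seq)
  e <- .fold_energies_cpp(aa, set$contacts, em$contact_energy)
  native <- which.min(e)  # ties -> lowest index
  e0 <- e[native]
  p_nat <- 1 / sum(exp(-(e - e0) / em$temperature))
  out <- list(aa_seq = aa_seq, native_index = native, E0 = e0, p_nat = p_nat)
  if (keep_energies) out$energies <- e
  structure(out, class = "protein_state")
}

#' @export
print.protein_state <- function(x, ...) {
  cat("<protein_state> native", x$native_index,
      " E0 =", format(x$E0), " P_nat =", format(x$p_nat), "\n")
  invisible(x)
}

#' Enumerate the 144 rigid docking modes
#'
#' Two cube-shaped lattice proteins can dock rigidly by facing any of the 6
#' faces of one against any of the 6 faces of the other under one of 4
#' in-plane rotations (6 x 6 x 4 = 144 modes; reflections are not separate
#' modes). Each mode brings the two 3x3 face grids into registry, giving 9
#' interface contacts.
#'
#' @return A tibble with one row per mode: `mode` (1..144), `face_i`,
#'   `face_j` (1..6, in the face order x-, x+, y-, y+, z-, z+), `rotation`
#'   (0..3 quarter turns) and `interface_pairs`, a list column of 9x2 integer
#'   matrices pairing cube sites (1..27) of the two partners.
#' @export
enumerate_docking_modes <- function() {
  pairs <- .docking_site_pairs_cpp()
  grid <- expand.grid(rotation = 0:3, face_j = 1:6, face_i = 1:6)[, 3:1]
  tibble(
    mode = 1:144,
    face_i = grid$face_i,
    face_j = grid$face_j,
    rotation = grid$rotation,
    interface_pairs = lapply(1:144, function(i) {
      m <- matrix(pairs[i, ] + 1L, ncol = 2, byrow = TRUE)
      colnames(m) <- c("site_i", "site_j")
      m
    })
  )
}

#' Binding thermodynamics of a protein pair
#'
#' Scores all 144 rigid docking modes between the native conformations of two
#' folded proteins: the energy of a mode is the sum of contact energies over
#' its 9 interface residue pairs. Returns the minimum binding energy, the
#' probability P_int that the pair occupies its lowest-energy (functional)
#' mode, and the binding constant K used by the law-of-mass-action equations.
#'
#' Three conventions for K are provided. The default, `"centered"`, measures
#' the native-mode binding constant relative to the pair's nonspecific
#' docking baseline, K = exp(-(E_int_min - mean_modes(E)) / T), which yields
#' moderate binding constants (partial dimerization) and a seed-cell base
#' growth rate of the observed order of magnitude. `"min_energy"` ties K to
#' the absolute lowest binding energy, K = exp(-E_int_min / T) (unit
#' reference concentration), and `"mode_sum"` sums the Boltzmann weights of
#' all modes, K = sum_modes exp(-E_mode / T).
#'
#' @param state_i,state_j `protein_state` objects folded against the same
#'   conformation set.
#' @param set The `conformation_set` both proteins were folded against.
#' @param em An `energy_model`.
#' @param k_form `"centered"` (default), `"min_energy"` or `"mode_sum"`.
#' @param keep_energies Keep the 144-mode energy spectrum in the result.
#' @return A `binding` object with fields `E_int` (minimum binding energy),
#'   `p_int` and `K`.
#' @export
bind_pair <- function(state_i, state_j, set, em,
                      k_form = c("centered", "min_energy", "mode_sum"),
                      keep_energies = FALSE) {
  k_form <- match.arg(k_form)
  stopifnot(inherits(state_i, "protein_state"), inherits(state_j, "protein_state"),
            inherits(set, "conformation_set"), inherits(em, "energy_model"))
  e <- .dock_energies_cpp(
    aa_to_int(state_i$aa_seq), aa_to_int(state_j$aa_seq),
    set$faces[state_i$native_index, ], set$faces[state_j$native_index, ],
    em$contact_energy
  )
  summarise_binding(e, em$temperature, k_form, keep_energies)
}

summarise_binding <- function(e, temperature, k_form, keep_energies = FALSE) {
  emin <- min(e)
  w <- exp(-(e - emin) / temperature)
  p_int <- 1 / sum(w)
  K <- switch(k_form,
    centered = exp((mean(e) - emin) / temperature),
    min_energy = exp(-emin / temperature),
    mode_sum = exp(-emin / temperature) * sum(w))
  out <- list(E_int = emin, p_int = p_int, K = K, k_form = k_form)
  if (keep_energies) out$energies <- e
  structure(out, class = "binding")
}

#' @export
print.binding <- function(x, ...) {
  cat("<binding> E_int =", format(x$E_int), " P_int =", format(x$p_int),
      " K =", format(x$K), paste0("(", x$k_form, ")"), "\n")
  invisible(x)
}

#' Pairwise interaction table for a set of proteins
#'
#' Computes minimum binding energies, native-mode binding probabilities and
#' binding constants for every (unordered) pair of the supplied proteins,
#' including homodimers.
#'
#' @param states List of `protein_state` objects (typically the 4 gene
#'   products of one cell) folded against `set`.
#' @inheritParams bind_pair
#' @return An `interaction_table`: list of symmetric matrices `E_int`,
#'   `p_int`, `K` of dimension `length(states)` squared.
#' @export
interaction_table <- function(states, set, em,
                              k_form = c("centered", "min_energy", "mode_sum")) {
  k_form <- match.arg(k_form)
  n <- length(states)
  E <- P <- K <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    b <- bind_pair(states[[i]], states[[j]], set, em, k_form)
    E[i, j] <- E[j, i] <- b$E_int
    P[i, j] <- P[j, i] <- b$p_int
    K[i, j] <- K[j, i] <- b$K
  }
  structure(list(E_int = E, p_int = P, K = K, k_form = k_form),
            class = "interaction_table")
}
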