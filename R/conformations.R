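#' Enumerate all maximally compact 27-mer lattice conformations
#'
#' Exhaustively enumerates, by backtracking, every self-avoiding chain of 27
#' residues that fills the 3x3x3 cube (a Hamiltonian path of the cube grid
#' graph), reduced to one representative per symmetry class. Two conformations
#' are considered equivalent when one is carried onto the other by a proper
#' rotation of the cube and/or reversal of the chain; mirror images are
#' distinct. Under this convention the complete set contains exactly 103,346
#' conformations.
#'
#' The returned set stores, for every conformation, the site path, the contact
#' map (the 28 non-bonded nearest-neighbour residue pairs), and the face table
#' used by the rigid-docking energy calculation. Enumeration order is
#' canonical-lexicographic on the site path, so repeated calls return the
#' identical set.
#'
#' @return A `conformation_set` object with fields `paths` (integer matrix,
#'   one row per conformation, 27 cube-site indices in 0..26), `contacts`
#'   (integer matrix, 28 chain-position pairs per row, 0-based), `faces`
#'   (integer matrix, chain positions on each of the 6 cube faces), `count`,
#'   and `indices` (position of each conformation in the full enumeration).
#' @seealso [sample_structure_set()] for the reduced representative subsets
#'   used in production runs, [fold()] for folding a sequence over a set.
#' @export
#' @examples
#' \donttest{
#' full <- enumerate_compact_conformations()
#' full$count  # 103346
#' }
enumerate_compact_conformations <- function() {
  paths <- .enumerate_conformations_cpp()
  new_conformation_set(paths, indices = seq_len(nrow(paths)))
}

new_conformation_set <- function(paths, indices) {
  structure(
    list(
      paths = paths,
      contacts = .contact_maps_cpp(paths),
      faces = .face_tables_cpp(paths),
      count = nrow(paths),
      indices = as.integer(indices)
    ),
    class = "conformation_set"
  )
}

#' @export
print.conformation_set <- function(x, ...) {
  cat("<conformation_set>", x$count, "compact 3x3x3 lattice conformations\n")
  invisible(x)
}

#' Draw a representative subset of conformations
#'
#' Production runs use a reduced, uniformly sampled structure set in place of
#' the full enumeration to make folding thermodynamics cheap; the full model
#' uses 10,000 structures. Sampling is uniform without replacement and fully
#' determined by `rng_seed`.
#'
#' @param full A `conformation_set`, normally the full enumeration.
#' @param n Number of conformations to keep, `1 <= n <= full$count`.
#' @param rng_seed Integer seed; the same seed always yields the same subset.
#' @return A `conformation_set` of `n` conformations. `indices` records each
#'   kept conformation's position in `full`.
#' @export
sample_structure_set <- function(full, n, rng_seed) {
  stopifnot(inherits(full, "conformation_set"))
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n > full$count)
    abort(sprintf("`n` must be in 1..%d", full$count), class = "mutatorsim_size_error")
  n <- as.integer(n)
  idx <- withr_seed(rng_seed, sort(sample.int(full$count, n)))
  structure(
    list(
      paths = full$paths[idx, , drop = FALSE],
      contacts = full$contacts[idx, , drop = FALSE],
      faces = full$faces[idx, , drop = FALSE],
      count = n,
      indices = full$indices[idx]
    ),
    class = "conformation_set"
  )
}

# evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Coordinates of one conformation
#'
#' @param set A `conformation_set`.
#' @param i Conformation index within the set.
#' @return A 27 x 3 integer matrix of (x, y, z) positions in 0..2, in chain
#'   order.
#' @export
conformation_coords <- function(set, i) {
  stopifnot(inherits(set, "conformation_set"), i >= 1, i <= set$count)
  s <- set$paths[i, ]
  cbind(x = s %% 3L, y = (s %/% 3L) %% 3L, z = s %/% 9L)
}
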