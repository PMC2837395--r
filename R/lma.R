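#' Solve the law-of-mass-action equilibrium
#'
#' Given total per-protein concentrations `C` and the symmetric binding
#' constant matrix `K`, solves the monomer-dimer mass-action system
#'
#'   F_i = C_i / (1 + sum_j K_ij F_j)
#'
#' for the free-monomer concentrations F_i by fixed-point iteration, stopping
#' when the relative change of every F_i falls below `rel_tol` (default 0.1%
#' of the new value). Dimer concentrations follow as F_ij = K_ij F_i F_j for
#' i != j and F_ii = K_ii F_i^2 / 2 for homodimers (the symmetry-number
#' convention under which mass is conserved as C_i = F_i + 2 F_ii +
#' sum_{j != i} F_ij).
#'
#' If the plain iteration has not converged after `plain_iter` sweeps it
#' switches to 0.5-damped iteration, which converges for this system without
#' changing the fixed point.
#'
#' @param C Non-negative numeric vector of total concentrations.
#' @param K Symmetric non-negative matrix of binding constants,
#'   `length(C)` squared.
#' @param rel_tol Relative convergence tolerance (> 0).
#' @param max_iter Iteration budget; exceeding it raises a convergence error
#'   carrying the last state in its `state` field.
#' @param plain_iter Sweeps of undamped iteration before damping kicks in.
#' @return An `equilibrium_state`: `F` (free monomers), `F_pair` (dimer
#'   concentration matrix with homodimers on the diagonal), `converged`,
#'   `iterations`.
#' @export
solve_lma <- function(C, K, rel_tol = 0.001, max_iter = 10000, plain_iter = 100) {
  n <- length(C)
  K <- as.matrix(K)
  stopifnot(all(C >= 0), nrow(K) == n, ncol(K) == n, all(K >= 0), rel_tol > 0)
  if (!isTRUE(all.equal(unname(K), unname(t(K)))))
    abort("`K` must be symmetric", class = "mutatorsim_lma_error")
  f <- C
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    f_new <- C / (1 + as.vector(K %*% f))
    if (it > plain_iter) f_new <- (f_new + f) / 2
    delta <- abs(f_new - f) / pmax(f_new, .Machine$double.xmin)
    ok <- all(delta[C > 0] < rel_tol)
    f <- f_new
    if (ok) { converged <- TRUE; break }
  }
  fp <- K * outer(f, f)
  diag(fp) <- diag(fp) / 2
  state <- structure(list(F = f, F_pair = fp, converged = converged, iterations = it),
                     class = "equilibrium_state")
  if (!converged)
    abort("law-of-mass-action iteration did not converge",
          class = "mutatorsim_convergence_error", state = state)
  state
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("<equilibrium_state>", x$iterations, "iterations, converged:", x$converged, "\n")
  cat("F:", format(x$F, digits = 4), "\n")
  invisible(x)
}

# vectorized fixed-point LMA over N cells; Cmat N x 4, Karr N x 10 in
# pair-column order (see PAIR_IDX). Always 0.5-damped: same fixed point as
# the scalar solver, iterated to the same tolerance.
PAIR_IDX <- cbind(i = c(1, 1, 1, 1, 2, 2, 2, 3, 3, 4),
                  j = c(1, 2, 3, 4, 2, 3, 4, 3, 4, 4))
# column of the pair store holding K[i,j]
pair_col <- function(i, j) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  match(paste(lo, hi), paste(PAIR_IDX[, 1], PAIR_IDX[, 2]))
}

solve_lma_matrix <- function(Cmat, Karr, rel_tol = 0.001, max_iter = 10000) {
  res <- .lma_matrix_cpp(Cmat, Karr, rel_tol, max_iter)
  list(F = res$F, F_pair = res$F_pair, iterations = res$iterations)
}

#' Concentration of functional mismatch-repair dimers
#'
#' The mutation-suppressing species is the MMR homodimer in its functional
#' docking mode with both partners natively folded:
#' G44 = F_44 * P_int^44 * (P_nat^4)^2.
#'
#' @param eq An `equilibrium_state` for the cell's four proteins.
#' @param p_int_44 Native-mode binding probability of the MMR homodimer.
#' @param p_nat_4 Thermal stability of the MMR protein.
#' @return The functional MMR dimer concentration (scalar).
#' @export
functional_mmr_concentration <- function(eq, p_int_44, p_nat_4) {
  stopifnot(p_int_44 >= 0, p_int_44 <= 1, p_nat_4 >= 0, p_nat_4 <= 1)
  eq$F_pair[4, 4] * p_int_44 * p_nat_4^2
}

#' Functional concentrations of the replication-controlling proteins
#'
#' The growth rate is proportional to the functional monomer concentration of
#' protein 1 and the functional heterodimer concentration of proteins 2 and 3:
#' G1 = F_1 * P_nat^1 and G23 = F_23 * P_int^23 * P_nat^2 * P_nat^3 (both
#' partners folded, complex in its native docking mode).
#'
#' @param eq An `equilibrium_state`.
#' @param p_nat_1,p_nat_2,p_nat_3 Stabilities of proteins 1..3.
#' @param p_int_23 Native-mode binding probability of the 2-3 heterodimer.
#' @return Named list with `G1` and `G23`.
#' @export
functional_rcg_concentrations <- function(eq, p_nat_1, p_nat_2, p_nat_3, p_int_23) {
  list(G1 = eq$F[1] * p_nat_1,
       G23 = eq$F_pair[2, 3] * p_int_23 * p_nat_2 * p_nat_3)
}
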