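#' The Miyazawa-Jernigan contact-energy table
#'
#' Reads the residue-residue contact energies e_ij (1996 variant, dimensionless
#' RT units) shipped with the package as a plain-text 20x20 symmetric matrix.
#' These energies score both intra-chain contacts (folding) and the 9
#' interface contacts of each rigid docking mode (binding).
#'
#' @return A symmetric 20x20 numeric matrix with one-letter residue dimnames.
#' @export
mj_contact_energies <- function() {
  if (is.null(the$mj)) {
    path <- system.file("extdata", "mj1996_table5.txt", package = "mutatorsim",
                        mustWork = TRUE)
    m <- as.matrix(read.table(path, header = TRUE, row.names = 1,
                              comment.char = "#", check.names = FALSE))
    storage.mode(m) <- "double"
    stopifnot(identical(rownames(m), RES_ORDER), isSymmetric(unname(m)))
    the$mj <- m
  }
  the$mj
}

#' Build an energy model
#'
#' Bundles the pairwise contact-energy table with the environmental
#' temperature. Temperature is expressed in the dimensionless energy units of
#' the contact table; the reference environment uses T = 0.85 and the
#' heat-shock environment T = 1.00.
#'
#' @param temperature Positive dimensionless temperature.
#' @param contact_energy Symmetric 20x20 matrix of residue-pair contact
#'   energies with rows/columns in the package residue order; defaults to the
#'   Miyazawa-Jernigan 1996 table.
#' @return An `energy_model` object.
#' @export
energy_model <- function(temperature = 0.85, contact_energy = mj_contact_energies()) {
  stopifnot(is.numeric(temperature), length(temperature) == 1, temperature > 0)
  contact_energy <- as.matrix(contact_energy)
  if (!isTRUE(all.equal(unname(contact_energy), unname(t(contact_energy)))))
    abort("`contact_energy` must be symmetric", class = "mutatorsim_energy_error")
  stopifnot(nrow(contact_energy) == 20, ncol(contact_energy) == 20)
  if (is.null(rownames(contact_energy))) dimnames(contact_energy) <- list(RES_ORDER, RES_ORDER)
  structure(list(contact_energy = contact_energy, temperature = temperature),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model> T =", x$temperature, "(dimensionless contact-energy units)\n")
  invisible(x)
}

# amino-acid string (27 letters) -> 0-based residue indices
aa_to_int <- function(aa_seq) {
  ch <- strsplit(aa_seq, "")[[1]]
  idx <- match(ch, RES_ORDER)
  if (anyNA(idx))
    abort(paste0("invalid residue letter(s): ",
                 paste(unique(ch[is.na(idx)]), collapse = ", ")),
          class = "mutatorsim_alphabet_error")
  as.integer(idx - 1L)
}

int_to_aa <- function(aa_int) paste(RES_ORDER[aa_int + 1L], collapse = "")
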