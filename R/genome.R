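# codon machinery: the standard genetic code, built once from seqinr
codon_table <- function() {
  if (is.null(the$codons)) {
    nts <- c("a", "c", "g", "t")
    grid <- expand.grid(n3 = nts, n2 = nts, n1 = nts, stringsAsFactors = FALSE)
    tripl <- paste0(grid$n1, grid$n2, grid$n3)
    aa <- vapply(tripl, function(cd) seqinr::translate(strsplit(cd, "")[[1]]), "")
    # index = 16*n1 + 4*n2 + n3 + 1 with A,C,G,T = 0..3
    idx <- 16L * (match(grid$n1, nts) - 1L) + 4L * (match(grid$n2, nts) - 1L) +
      (match(grid$n3, nts) - 1L) + 1L
    tab <- character(64)
    tab[idx] <- aa
    the$codons <- tab
    the$codon_aa_int <- ifelse(tab == "*", -1L, match(tab, RES_ORDER) - 1L)
    the$syn_codons <- split(seq_len(64) - 1L, tab)  # 0-based codon ids per aa
  }
  the$codons
}

nt_to_int <- function(gene) {
  ch <- strsplit(toupper(gene), "")[[1]]
  idx <- match(ch, NT_ORDER)
  if (anyNA(idx))
    abort("gene contains characters outside {A,C,G,T}",
          class = "mutatorsim_sequence_error")
  as.integer(idx - 1L)
}

int_to_nt <- function(g) paste(NT_ORDER[g + 1L], collapse = "")

# 81 nucleotide ints -> 27 residue ints (0-based), or NA where a stop codon
# falls in frame
CODON_P1 <- seq(1L, 81L, 3L)
CODON_P2 <- seq(2L, 81L, 3L)
CODON_P3 <- seq(3L, 81L, 3L)

translate_int <- function(g) {
  codon_table()
  cid <- 16L * g[CODON_P1] + 4L * g[CODON_P2] + g[CODON_P3] + 1L
  aa <- the$codon_aa_int[cid]
  aa[aa < 0L] <- NA_integer_
  aa
}

#' Translate an 81-nucleotide gene into its 27-mer protein
#'
#' Uses the standard genetic code. An in-frame stop codon yields `NA` with the
#' attribute `stop = TRUE`; downstream, a truncated product cannot fill the
#' 3x3x3 cube and is treated as lethal.
#'
#' @param gene A single 81-character string over {A, C, G, T}.
#' @return The 27-letter amino-acid string, or `NA_character_` (with attribute
#'   `stop = TRUE`) if translation hits a stop codon.
#' @export
translate_gene <- function(gene) {
  if (!is.character(gene) || length(gene) != 1 || nchar(gene) != 81)
    abort("`gene` must be a single 81-nucleotide string",
          class = "mutatorsim_sequence_error")
  aa <- translate_int(nt_to_int(gene))
  if (anyNA(aa)) return(structure(NA_character_, stop = TRUE))
  int_to_aa(aa)
}

# 27 residue ints -> 81 nucleotide ints using uniformly random synonymous
# codons (caller controls the RNG state)
back_translate_int <- function(aa) {
  codon_table()
  letters1 <- RES_ORDER[aa + 1L]
  cids <- vapply(letters1, function(a) {
    opts <- the$syn_codons[[a]]
    opts[sample.int(length(opts), 1)]
  }, integer(1))
  g <- integer(81)
  g[seq(1, 81, 3)] <- cids %/% 16L
  g[seq(2, 81, 3)] <- (cids %/% 4L) %% 4L
  g[seq(3, 81, 3)] <- cids %% 4L
  g
}

# apply `n` random single-nucleotide substitutions (uniform positions, uniform
# over the three alternative bases); returns list(gene, pos, from, to)
mutate_gene_int <- function(g, n) {
  pos <- sample.int(81, n, replace = TRUE)
  from <- to <- integer(n)
  for (k in seq_len(n)) {  # sequential so repeated hits at one site compose
    from[k] <- g[pos[k]]
    to[k] <- (from[k] + sample.int(3, 1)) %% 4L
    g[pos[k]] <- to[k]
  }
  list(gene = g, pos = pos, from = from, to = to)
}
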