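#' Frequency of the mutator phenotype
#'
#' Fraction of cells whose mutation rate exceeds 0.01 per gene per
#' replication.
#'
#' @param x An `evolution_run` (final population), an internal population
#'   state, or a numeric vector of mutation rates.
#' @return Fraction in \[0, 1\]; empty populations are an error.
#' @export
mutator_frequency <- function(x) {
  m <- if (inherits(x, "evolution_run")) x$population$m
  else if (is.numeric(x)) x
  else if (is.list(x) && !is.null(x$m)) x$m
  else abort("cannot extract mutation rates from `x`",
             class = "mutatorsim_input_error")
  if (!length(m))
    abort("mutator frequency of an empty population is undefined",
          class = "mutatorsim_input_error")
  mean(m > 0.01)
}

#' Classify population-level mutator transitions by proximal cause
#'
#' A population-level transition is a crossing of the mutator frequency
#' through 0.5 with hysteresis: an M (to-mutator) transition requires the
#' frequency to have been below `low` since the previous transition, a W
#' (to-non-mutator) transition requires it to have been above `high`. For
#' each transition, the per-cell mutator flips logged in the window between
#' arming and crossing are tallied by proximal cause -- Env (an environmental
#' change), Mut (a gene-4 substitution at replication), SS (a fluctuation of
#' the MMR protein's production level) -- and the majority cause is assigned,
#' with precedence Env > Mut > SS > unattributed on ties. W transitions are
#' never attributed to Env.
#'
#' @param run An `evolution_run`, or any list with `time_series` (columns
#'   `t`, `mutator_freq`) and `events` (flip rows with `t`, `direction`,
#'   `cause`).
#' @param low,high Hysteresis thresholds (arm M below `low`, W above `high`).
#' @return A tibble with one row per transition: `t`, `direction` (`"M"` or
#'   `"W"`), `cause`, `n_flips`, and per-cause flip counts.
#' @export
classify_transitions <- function(run, low = 0.25, high = 0.75) {
  ts <- run$time_series
  flips <- dplyr::filter(run$events, .data$type == "flip")
  freq <- ts$mutator_freq
  tt <- ts$t
  armed_M <- freq[1] < low
  armed_W <- freq[1] > high
  t_armed_M <- if (armed_M) tt[1] else NA_integer_
  t_armed_W <- if (armed_W) tt[1] else NA_integer_
  out <- list()
  for (i in seq_along(tt)[-1]) {
    if (is.na(freq[i])) break
    if (freq[i] < low && !armed_M) { armed_M <- TRUE; t_armed_M <- tt[i] }
    if (freq[i] > high && !armed_W) { armed_W <- TRUE; t_armed_W <- tt[i] }
    up <- freq[i - 1] <= 0.5 && freq[i] > 0.5 && armed_M
    down <- freq[i - 1] >= 0.5 && freq[i] < 0.5 && armed_W
    if (up || down) {
      dir_flip <- if (up) "to_mutator" else "to_nonmutator"
      t0 <- if (up) t_armed_M else t_armed_W
      win <- dplyr::filter(flips, .data$t > t0, .data$t <= tt[i],
                           .data$direction == dir_flip)
      counts <- c(Env = sum(win$cause == "Env"),
                  Mut = sum(win$cause == "Mut"),
                  SS = sum(win$cause == "SS"),
                  unattributed = sum(win$cause == "unattributed"))
      if (!up) counts["Env"] <- 0L  # W transitions are never environmental
      cause <- if (sum(counts) == 0) "unattributed" else
        names(counts)[which.max(counts)]  # which.max respects precedence order
      out[[length(out) + 1]] <- tibble(
        t = tt[i], direction = if (up) "M" else "W", cause = cause,
        n_flips = nrow(win), n_env = counts[["Env"]], n_mut = counts[["Mut"]],
        n_ss = counts[["SS"]], n_unattributed = counts[["unattributed"]])
      armed_M <- armed_W <- FALSE
      t_armed_M <- t_armed_W <- NA_integer_
    }
  }
  if (!length(out))
    return(tibble(t = integer(), direction = character(), cause = character(),
                  n_flips = integer(), n_env = integer(), n_mut = integer(),
                  n_ss = integer(), n_unattributed = integer()))
  dplyr::bind_rows(out)
}

#' Assign an adapted population to its fitness class
#'
#' Populations settle, after initial adaptation, into broad fitness classes
#' around b ~ 0.33, ~ 0.62 and ~ 1; the class is the nearest of the three
#' (ties resolve to the lower class).
#'
#' @param mean_b Numeric vector of post-adaptation mean birth rates in (0, 1].
#' @param classes The class centres.
#' @return Numeric vector of class labels.
#' @export
fitness_class <- function(mean_b, classes = c(0.33, 0.62, 1.0)) {
  stopifnot(all(mean_b > 0), all(mean_b <= 1))
  classes[vapply(mean_b, function(b) which.min(abs(classes - b)), 0L)]
}

#' Local fitness landscape of a cell
#'
#' Applies `n_mutants` independent single non-synonymous point mutations to
#' fresh copies of the cell's genome (synonymous draws are rejected and
#' redrawn), recomputes the birth rate of each mutant with total protein
#' concentrations held fixed, and histograms the relative fitness change
#' x = (b_mut - b) / b. Lethal mutants (stop codon, or a mutated protein
#' below the stability threshold) are assigned x = -1, a complete fitness
#' loss, and land in the terminal bin.
#'
#' @param cell A `cell` (see [make_cell()]).
#' @param set,em Conformation set and energy model the cell was built with.
#' @param params A `fitness_params`.
#' @param n_mutants Number of point mutants (default 1000).
#' @param bin_width Histogram bin width on x.
#' @return A `landscape_histogram`: list with `bins` (tibble `bin_left`,
#'   `bin_right`, `bin_mid`, `count`), `x` (per-mutant fitness changes),
#'   `n_mutants`, `n_lethal`.
#' @export
local_fitness_landscape <- function(cell, set, em, params = fitness_params(),
                                    n_mutants = 1000, bin_width = 0.05) {
  stopifnot(inherits(cell, "cell"), n_mutants >= 1)
  x <- numeric(n_mutants)
  n_lethal <- 0L
  geno <- lapply(cell$genome, nt_to_int)
  for (k in seq_len(n_mutants)) {
    # rejection-sample a non-synonymous single-nucleotide substitution
    repeat {
      g <- sample.int(4, 1)
      mut <- mutate_gene_int(geno[[g]], 1L)
      aa_new <- translate_int(mut$gene)
      acols <- (27L * (g - 1L) + 1L):(27L * g)
      if (anyNA(aa_new) || !identical(aa_new, cell$aa[acols])) break
    }
    if (anyNA(aa_new)) { x[k] <- -1; n_lethal <- n_lethal + 1L; next }
    aa108 <- cell$aa
    aa108[acols] <- aa_new
    ph <- genome_phenotype_update(cell$phenotype, aa108, g, set, em)
    if (ph$pnat[g] < params$theta_nat) {
      x[k] <- -1; n_lethal <- n_lethal + 1L; next
    }
    eq <- solve_lma_matrix(matrix(cell$C, 1), matrix(ph$K10, 1))
    G1 <- eq$F[1, 1] * ph$pnat[1]
    G23 <- eq$F_pair[1, P23] * ph$pint10[P23] * ph$pnat[2] * ph$pnat[3]
    b_mut <- birth_rate_value(G1, G23, sum(cell$C), params)
    x[k] <- (b_mut - cell$b) / cell$b
  }
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(max(x), bin_width) / bin_width) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE, right = FALSE,
                      include.lowest = TRUE)
  structure(list(
    bins = tibble(bin_left = head(h$breaks, -1), bin_right = tail(h$breaks, -1),
                  bin_mid = h$mids, count = h$counts),
    x = x, n_mutants = n_mutants, n_lethal = n_lethal
  ), class = "landscape_histogram")
}

#' @export
print.landscape_histogram <- function(x, ...) {
  cat("<landscape_histogram>", x$n_mutants, "point mutants,", x$n_lethal,
      "lethal\n")
  invisible(x)
}
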