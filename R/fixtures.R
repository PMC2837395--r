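#' Deterministic test fixtures
#'
#' Builds small, fully deterministic objects that exercise every layer of the
#' model without the full 103,346-conformation enumeration: a 200-structure
#' conformation set (a stored sample of the enumeration), a toy cell, a toy
#' population, and a constructed event log with a predetermined Env/Mut/SS
#' transition split.
#'
#' @param kind One of `"tiny_structure_set"`, `"toy_cell"`,
#'   `"toy_population"`, `"constructed_event_log"`.
#' @param rng_seed Seed controlling any randomness in the fixture.
#' @return The fixture object (type depends on `kind`).
#' @export
make_fixture <- function(kind = c("tiny_structure_set", "toy_cell",
                                  "toy_population", "constructed_event_log"),
                         rng_seed = 1) {
  kind <- match.arg(kind)
  switch(kind,
    tiny_structure_set = tiny_structure_set(),
    toy_cell = toy_cell(rng_seed),
    toy_population = toy_population(rng_seed),
    constructed_event_log = constructed_event_log()
  )
}

tiny_structure_set <- function() {
  if (is.null(the$tiny_set)) {
    path <- system.file("extdata", "tiny_conformations.txt",
                        package = "mutatorsim", mustWork = TRUE)
    m <- as.matrix(read.table(path, comment.char = "#"))
    dimnames(m) <- NULL
    storage.mode(m) <- "integer"
    the$tiny_set <- new_conformation_set(m, indices = seq_len(nrow(m)))
  }
  the$tiny_set
}

toy_genome <- function(rng_seed) {
  set <- tiny_structure_set()
  em <- energy_model()
  withr_seed(rng_seed, {
    cfg <- design_config(p_nat_threshold = 0.62, p_int_threshold = 0.2,
                         max_steps = 20000)
    des <- design_seed_genome(set, em, cfg)
    des$genome
  })
}

toy_cell <- function(rng_seed) {
  genome <- toy_genome(rng_seed)
  make_cell(genome, C = rep(0.1, 4), set = tiny_structure_set(),
            em = energy_model(), params = fitness_params())
}

toy_population <- function(rng_seed, n = 20) {
  set <- tiny_structure_set()
  em <- energy_model()
  genome <- toy_genome(rng_seed)
  params <- fitness_params()
  aa108 <- unlist(lapply(genome, function(g) translate_int(nt_to_int(g))))
  geno324 <- unlist(lapply(genome, nt_to_int))
  ph <- genome_phenotype(aa108, set, em)
  new_population(geno324, aa108, ph, rep(0.1, 4), params, n)
}

# a hand-built trajectory: one Env-caused M transition, one Mut-caused W
# transition, one SS-caused M transition
constructed_event_log <- function() {
  freq <- c(rep(0, 9), rep(0.6, 5), rep(0.9, 5), rep(0.4, 5), rep(0.1, 5),
            rep(0.55, 6))
  ts <- tibble(t = 0:(length(freq) - 1L), mutator_freq = freq)
  flips <- dplyr::bind_rows(
    tibble(t = 9L, cell = 1:4, direction = "to_mutator",
           cause = c("Env", "Env", "Env", "SS")),
    tibble(t = 19L, cell = 5:6, direction = "to_nonmutator", cause = "Mut"),
    tibble(t = 29L, cell = 7:8, direction = "to_mutator", cause = "SS"))
  flips$type <- "flip"
  flips$seq <- seq_len(nrow(flips))
  list(time_series = ts, events = flips)
}
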