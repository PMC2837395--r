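# memoized heavy fixtures shared across test files (built once per test run)
.fixture_env <- new.env(parent = emptyenv())

cached_fixture <- function(name, fn) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- fn()
  .fixture_env[[name]]
}

full_set <- function() cached_fixture("full", enumerate_compact_conformations)

set1000 <- function() cached_fixture("s1000", function()
  sample_structure_set(full_set(), 1000, rng_seed = 11))

tiny_set <- function() make_fixture("tiny_structure_set")

# a 3-conformation micro-set for hand-computed partition functions
micro_set <- function() {
  ts <- tiny_set()
  structure(list(paths = ts$paths[1:3, , drop = FALSE],
                 contacts = ts$contacts[1:3, , drop = FALSE],
                 faces = ts$faces[1:3, , drop = FALSE],
                 count = 3L, indices = ts$indices[1:3]),
            class = "conformation_set")
}

random_aa <- function(n = 27) {
  paste(sample(c("C","M","F","I","L","V","W","Y","A","G",
                 "T","S","N","Q","D","E","H","R","K","P"), n, TRUE),
        collapse = "")
}

# scalar LMA residual: mass conservation with the 2*F_ii homodimer factor
lma_residual <- function(eq, C) {
  vapply(seq_along(C), function(i) {
    F_off <- sum(eq$F_pair[i, -i])
    C[i] - (eq$F[i] + 2 * eq$F_pair[i, i] + F_off)
  }, 0)
}
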