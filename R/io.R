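TRAJECTORY_FORMAT_VERSION <- 1L

#' Write a trajectory to disk
#'
#' Persists an `evolution_run` as plain tabular files inside a directory:
#' `time_series.csv`, `events.csv` and `meta.yaml` (configuration, calibrated
#' parameters, row counts for integrity checking, format version).
#'
#' @param run An `evolution_run`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(run, path) {
  stopifnot(inherits(run, "evolution_run"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(run$time_series, file.path(path, "time_series.csv"))
  readr::write_csv(run$events, file.path(path, "events.csv"), na = "")
  meta <- list(
    format_version = TRAJECTORY_FORMAT_VERSION,
    n_time_series = nrow(run$time_series),
    n_events = nrow(run$events),
    config = unclass(run$config),
    params = unclass(run$params),
    meta = run$meta[setdiff(names(run$meta), "design")]
  )
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' Verifies the format version and the recorded row counts; a truncated or
#' tampered table raises a corruption error.
#'
#' @param path Directory written by [write_trajectory()].
#' @return An `evolution_run` (without the final population state).
#' @export
read_trajectory <- function(path) {
  metafile <- file.path(path, "meta.yaml")
  if (!file.exists(metafile))
    abort("not a trajectory directory (meta.yaml missing)",
          class = "mutatorsim_format_error")
  meta <- yaml::read_yaml(metafile)
  if (!identical(as.integer(meta$format_version), TRAJECTORY_FORMAT_VERSION))
    abort(paste0("unsupported trajectory format version: ", meta$format_version),
          class = "mutatorsim_format_error")
  ts <- readr::read_csv(file.path(path, "time_series.csv"),
                        show_col_types = FALSE, progress = FALSE)
  proto <- empty_event_log()
  ev <- readr::read_csv(file.path(path, "events.csv"),
                        col_types = paste(substr(vapply(proto, function(x)
                          class(x)[1], ""), 1, 1), collapse = ""),
                        na = "", show_col_types = FALSE, progress = FALSE)
  if (nrow(ts) != meta$n_time_series || nrow(ev) != meta$n_events)
    abort("trajectory file is corrupted (row count mismatch)",
          class = "mutatorsim_corruption_error")
  cfg <- meta$config
  if (!is.null(cfg$C_init)) cfg$C_init <- as.numeric(cfg$C_init)
  cfg <- do.call(run_config, cfg[names(cfg) %in% names(formals(run_config))])
  structure(list(time_series = ts, events = ev, config = cfg,
                 params = meta$params, population = NULL, meta = meta$meta),
            class = "evolution_run")
}

#' Write a 4-gene genome as FASTA
#'
#' One record per gene; headers carry the gene index and optional provenance
#' (designed native structure index, achieved stability).
#'
#' @param genome Character vector of 4 genes (81 nt each).
#' @param path Output FASTA path.
#' @param annotations Optional character vector of 4 header suffixes.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, annotations = NULL) {
  stopifnot(length(genome) == 4, all(nchar(genome) == 81))
  names_ <- paste0("gene", 1:4,
                   if (is.null(annotations)) "" else paste0(" ", annotations))
  seqinr::write.fasta(lapply(genome, function(g) strsplit(g, "")[[1]]),
                      names = names_, file.out = path)
  invisible(path)
}

#' Read a 4-gene genome from FASTA
#'
#' @param path FASTA file with exactly 4 records of 81 nucleotides, in gene
#'   order.
#' @return Character vector of 4 genes (uppercase).
#' @export
read_genome_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, forceDNAtolower = FALSE)
  if (length(recs) != 4)
    abort("genome FASTA must contain exactly 4 records",
          class = "mutatorsim_sequence_error")
  genome <- toupper(vapply(recs, paste, "", collapse = ""))
  if (any(nchar(genome) != 81))
    abort("each gene must be 81 nucleotides", class = "mutatorsim_sequence_error")
  unname(genome)
}

#' Replay an event log
#'
#' Reconstructs the final population's genomes and concentrations from the
#' initial state and a complete event log (a run recorded with
#' `log_divisions = TRUE`, which also logs deaths and culls). Used to verify
#' event-log completeness: replaying must reproduce the surviving cells
#' exactly.
#'
#' @param run An `evolution_run` recorded with full provenance.
#' @return A tibble with one row per surviving cell: `cell`, `lineage`,
#'   `genome` (321-character concatenated gene string is avoided; one column
#'   per gene `gene1..gene4`) and `C1..C4`.
#' @export
replay_event_log <- function(run) {
  stopifnot(inherits(run, "evolution_run"))
  if (!isTRUE(run$config$log_divisions))
    abort("replay requires a run recorded with log_divisions = TRUE",
          class = "mutatorsim_input_error")
  n0 <- run$config$n_seed
  genome0 <- run$meta$seed_genome
  C0v <- run$config$C_init %||% rep(run$config$C0 / 4, 4)
  cells <- new.env(parent = emptyenv())
  n_start <- if (!is.null(run$meta$n_start)) run$meta$n_start else n0
  for (i in seq_len(n_start))
    assign(as.character(i), list(genome = genome0, C = C0v, lineage = i),
           envir = cells)
  ev <- run$events
  for (i in seq_len(nrow(ev))) {
    row <- ev[i, ]
    key <- as.character(row$cell)
    switch(row$type,
      division = {
        mother <- get(as.character(row$mother), envir = cells)
        assign(key, list(genome = mother$genome, C = mother$C,
                         lineage = row$lineage), envir = cells)
      },
      mutation = {
        cl <- get(key, envir = cells)
        g <- nt_to_int(cl$genome[row$gene])
        g[row$pos] <- match(row$to, NT_ORDER) - 1L
        cl$genome[row$gene] <- int_to_nt(g)
        assign(key, cl, envir = cells)
      },
      fluctuation = {
        cl <- get(key, envir = cells)
        cl$C[row$gene] <- row$new
        assign(key, cl, envir = cells)
      },
      death = rm(list = key, envir = cells),
      cull = rm(list = key, envir = cells),
      lethal = rm(list = key, envir = cells),
      NULL)
  }
  # mothers are replaced by their daughters at division
  mothers <- unique(ev$mother[ev$type == "division"])
  mothers <- setdiff(as.character(mothers[!is.na(mothers)]), character(0))
  for (k in intersect(mothers, ls(cells))) rm(list = k, envir = cells)
  keys <- ls(cells)
  dplyr::arrange(dplyr::bind_rows(lapply(keys, function(k) {
    cl <- get(k, envir = cells)
    tibble(cell = as.integer(k), lineage = as.integer(cl$lineage),
           gene1 = cl$genome[1], gene2 = cl$genome[2], gene3 = cl$genome[3],
           gene4 = cl$genome[4], C1 = cl$C[1], C2 = cl$C[2], C3 = cl$C[3],
           C4 = cl$C[4])
  })), cell)
}
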