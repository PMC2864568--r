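## shared fixtures, built in code and memoised for the whole test run

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## small labeled assembly shared across test files
tiny_config <- function() {
  sim_config(seed = 7, genome_length = 4e5, n_het_tracts = 11L,
             true_dup_count = 10L, n_clean_unplaced = 2L)
}

tiny_bundle <- function() memo("tiny_bundle", simulate_assembly(tiny_config()))

tiny_result <- function() {
  memo("tiny_result", {
    b <- tiny_bundle()
    run_all(list(contigs = b$contigs, agp = b$agp, layout = b$layout,
                 libraries = b$libraries))
  })
}

## a toy two-contig chromosome with hand-placed reads, for precise
## likelihood/unplaced tests: one anchor contig of 20 kb at chrom 0,
## forward, and a library of known normal model
toy_models <- function(mean = 4000, sd = 400, tail = 1e-4) {
  m <- normal_model(data.frame(library_id = "libA", ta_mean = mean,
                               ta_sd = sd), floor_tail = tail)
  list(libA = m)
}

## construct an agp object from a placements-like data.frame
toy_agp <- function(placements, gaps = NULL) {
  p <- data.table::as.data.table(placements)
  if (!"placed" %in% names(p)) p[, placed := TRUE]
  if (!"component_type" %in% names(p)) p[, component_type := "W"]
  if (!"component_beg" %in% names(p)) p[, component_beg := 1L]
  if (!"component_end" %in% names(p)) p[, component_end := end - start]
  g <- if (is.null(gaps)) {
    data.table::data.table(chrom = character(), start = integer(),
                           end = integer(), length = integer(),
                           gap_type = character(), linkage = character(),
                           evidence = character())
  } else data.table::as.data.table(gaps)
  structure(list(placements = p, gaps = g), class = "agp")
}

toy_layout <- function(...) {
  rows <- list(...)
  data.table::rbindlist(lapply(rows, function(r) {
    data.table::data.table(read_id = r[[1]], contig_id = r[[2]],
                           start = as.integer(r[[3]]),
                           end = as.integer(r[[4]]),
                           orientation = r[[5]], library_id = r[[6]],
                           mate_id = if (is.na(r[[7]])) NA_character_
                                     else r[[7]])
  }))
}
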