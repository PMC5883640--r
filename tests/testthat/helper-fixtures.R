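# Shared fixtures. The 18-genome synthetic panel and its clustering are
# expensive, so they are built once per test run and memoized.

fixture_env <- new.env(parent = emptyenv())

PANEL_SEED <- 101L

get_panel <- function() {
  if (is.null(fixture_env$panel)) {
    fixture_env$panel <- synthetic_prophage_panel(seed = PANEL_SEED)
  }
  fixture_env$panel
}

get_panel_clusters <- function() {
  if (is.null(fixture_env$clusters)) {
    fixture_env$clusters <- cluster_phages(get_panel()$genomes)
  }
  fixture_env$clusters
}

# a small random genome (with gene architecture) for quick tests
small_genome <- function(len = 10000, seed = 7L, id = "g1") {
  random_phage_genome(len, id = id, seed = seed)$genome
}

# write a temporary FASTA and return its path
temp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

# O(n*m) oracle: every maximal exact match of length >= k, one strand;
# returned as sorted "start_a:start_b:len" keys (1-based)
oracle_mems <- function(a, b, k) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  out <- list()
  for (d in (-(na - 1)):(nb - 1)) {
    i <- max(1L, 1L - d); j <- i + d
    run <- 0L
    while (i <= na && j <= nb) {
      if (ca[i] == cb[j]) run <- run + 1L else {
        if (run >= k) out[[length(out) + 1L]] <- c(i - run, j - run, run)
        run <- 0L
      }
      i <- i + 1L; j <- j + 1L
    }
    if (run >= k) out[[length(out) + 1L]] <- c(i - run, j - run, run)
  }
  if (!length(out)) return(character(0))
  sort(vapply(out, paste, character(1), collapse = ":"))
}
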