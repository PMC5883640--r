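#' Construct a table of phage genomes
#'
#' The central container of the package: one row per phage or prophage
#' nucleotide sequence, with identifier, display name, sequence and length.
#'
#' @param id character vector of unique identifiers.
#' @param sequence character vector of DNA sequences over A/C/G/T/N.
#' @param name optional display names (defaults to `id`).
#' @param host_species optional host species annotation.
#' @param proposed_genus optional genus annotation.
#' @return a `data.frame` with class `phage_genome_set` and columns
#'   `id`, `name`, `sequence`, `length_bp`, `host_species`, `proposed_genus`.
#' @export
phage_genome_set <- function(id, sequence, name = id,
                             host_species = NA_character_,
                             proposed_genus = NA_character_) {
  sequence <- toupper(sequence)
  sequence <- gsub("U", "T", sequence, fixed = TRUE)
  if (anyDuplicated(id)) {
    stop("duplicate genome ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) {
    stop("sequence for '", id[which(bad)[1]],
         "' contains characters outside A/C/G/T/N", call. = FALSE)
  }
  if (any(nchar(sequence) == 0L)) {
    stop("empty sequence for '", id[which(nchar(sequence) == 0L)[1]], "'",
         call. = FALSE)
  }
  out <- data.frame(
    id = as.character(id), name = as.character(name),
    sequence = sequence, length_bp = nchar(sequence),
    host_species = host_species, proposed_genus = proposed_genus,
    stringsAsFactors = FALSE
  )
  class(out) <- c("phage_genome_set", "data.frame")
  out
}

#' Read phage genomes from a FASTA file
#'
#' Headers are kept verbatim as `name`; the `id` is the first whitespace
#' token. Sequences are upper-cased and RNA `U` is mapped to `T`. IUPAC
#' ambiguity characters other than `N` are rejected so that downstream
#' alignment identities stay unambiguous.
#'
#' @param path path to a (multi-)FASTA file.
#' @return a [phage_genome_set()] table, one row per record.
#' @export
read_phage_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA at line ", first,
         ": expected a '>' header before sequence data", call. = FALSE)
  }
  hdr_idx <- which(startsWith(lines, ">"))
  seq_lines <- setdiff(nonblank, hdr_idx)
  bad <- seq_lines[grepl("[^ACGTNUacgtnu]", lines[seq_lines])]
  if (length(bad)) {
    stop("malformed FASTA at line ", bad[1],
         ": sequence contains characters outside A/C/G/T/N/U", call. = FALSE)
  }
  grp <- findInterval(seq_lines, hdr_idx)
  headers <- sub("^>", "", trimws(lines[hdr_idx]))
  seqs <- vapply(seq_along(hdr_idx), function(i) {
    paste(lines[seq_lines[grp == i]], collapse = "")
  }, character(1))
  if (any(nchar(seqs) == 0L)) {
    stop("record '", headers[which(nchar(seqs) == 0L)[1]],
         "' has no sequence", call. = FALSE)
  }
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  phage_genome_set(id = ids, sequence = seqs, name = headers)
}

#' Write phage genomes to FASTA
#'
#' @param genomes a [phage_genome_set()] table.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_phage_fasta <- function(genomes, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(genomes))) {
    writeLines(paste0(">", genomes$name[i]), con)
    s <- genomes$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

START_CODONS <- c("ATG", "GTG", "TTG")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# translate in-frame DNA (no stop) under the bacterial code; start codon -> M
translate_orf <- function(dna) {
  if (length(dna) == 0L) return(character(0))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(dna),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X"
  ))
  paste0("M", substring(aa, 2L))
}

#' Predict open reading frames on both strands
#'
#' Stop-to-stop scan of the six reading frames under the bacterial genetic
#' code (table 11): within each stop-bounded segment the leftmost permitted
#' start codon (ATG/GTG/TTG) opens the ORF, so one (the longest) ORF is
#' reported per stop/frame. Coordinates are 0-based half-open on the forward
#' strand and include the stop codon; the translated protein excludes it.
#'
#' @param genome a one-row [phage_genome_set()], a list with `sequence`
#'   and `id`, or a plain DNA string.
#' @param min_aa minimum protein length in amino acids (stop excluded).
#' @return a `data.frame` with columns `genome_id`, `start`, `end`, `strand`,
#'   `protein`, ordered by (`start`, `strand`).
#' @export
predict_orfs <- function(genome, min_aa = 30L) {
  stopifnot(min_aa >= 1L)
  seq <- genome_sequence(genome)
  gid <- genome_id_of(genome)
  n <- nchar(seq)
  if (n == 0L || !grepl("[ACGT]", seq)) {
    warning("genome '", gid, "' has no unambiguous sequence; no ORFs called")
    return(data.frame(genome_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      protein = character(0), stringsAsFactors = FALSE))
  }
  scan_strand <- function(s, strand) {
    ns <- nchar(s)
    res <- vector("list", 3L)
    for (frame in 0:2) {
      ncod <- (ns - frame) %/% 3L
      if (ncod < min_aa + 1L) next
      starts_nt <- seq.int(frame + 1L, by = 3L, length.out = ncod)
      codons <- substring(s, starts_nt, starts_nt + 2L)
      is_stop <- codons %in% STOP_CODONS
      is_start <- codons %in% START_CODONS
      stop_idx <- which(is_stop)
      if (length(stop_idx) == 0L) next
      seg_begin <- c(1L, head(stop_idx, -1L) + 1L)
      orf <- list()
      for (si in seq_along(stop_idx)) {
        b <- seg_begin[si]; e <- stop_idx[si]
        if (e - b < min_aa) next
        cand <- which(is_start[b:(e - 1L)])
        if (length(cand) == 0L) next
        c0 <- b + cand[1L] - 1L
        if (e - c0 < min_aa) next
        nt0 <- starts_nt[c0] - 1L            # 0-based on this strand
        nt1 <- starts_nt[e] + 2L             # exclusive, includes stop
        orf[[length(orf) + 1L]] <- c(nt0, nt1)
      }
      if (length(orf)) {
        m <- do.call(rbind, orf)
        res[[frame + 1L]] <- data.frame(s0 = m[, 1], s1 = m[, 2],
                                        strand = strand)
      }
    }
    do.call(rbind, res[!vapply(res, is.null, logical(1))])
  }
  fwd <- scan_strand(seq, "+")
  rcs <- revcomp(seq)
  rev <- scan_strand(rcs, "-")
  out <- list()
  if (!is.null(fwd) && nrow(fwd)) {
    dna <- substring(seq, fwd$s0 + 1L, fwd$s1 - 3L)
    out[[1]] <- data.frame(genome_id = gid, start = as.integer(fwd$s0),
                           end = as.integer(fwd$s1), strand = "+",
                           protein = translate_orf(dna),
                           stringsAsFactors = FALSE)
  }
  if (!is.null(rev) && nrow(rev)) {
    dna <- substring(rcs, rev$s0 + 1L, rev$s1 - 3L)
    out[[2]] <- data.frame(genome_id = gid,
                           start = as.integer(n - rev$s1),
                           end = as.integer(n - rev$s0), strand = "-",
                           protein = translate_orf(dna),
                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(genome_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      protein = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an ORF table as TSV
#'
#' @param orfs output of [predict_orfs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orf_table <- function(orfs, path) {
  utils::write.table(orfs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
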