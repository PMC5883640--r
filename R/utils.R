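#' @importFrom stats pnorm median rbinom rnorm runif setNames uniroot
#' @importFrom utils adist head tail
#' @import data.table
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  "kmer", "pos", "pos_a", "pos_b", "d", "run_id", "i.pos", "len",
  "qi", "sj", "score", "evalue", "pid", "start_a", "start_b",
  "end_a", "end_b", "J", "N", "."
))

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# 0-based half-open interval sanity check
check_interval <- function(interval, upper = NULL, what = "interval") {
  if (length(interval) != 2L || anyNA(interval) || interval[1] < 0 ||
      interval[2] <= interval[1]) {
    stop(sprintf("%s must be a 0-based half-open [start, end) with start < end",
                 what), call. = FALSE)
  }
  if (!is.null(upper) && interval[2] > upper) {
    stop(sprintf("%s end (%d) exceeds sequence length (%d)",
                 what, as.integer(interval[2]), as.integer(upper)),
         call. = FALSE)
  }
  invisible(as.integer(interval))
}

# Extract the sequence string from a phage_genome row, plain string, or list
genome_sequence <- function(genome) {
  if (is.character(genome) && length(genome) == 1L) return(toupper(genome))
  if (is.data.frame(genome)) {
    if (nrow(genome) != 1L) stop("expected a single genome", call. = FALSE)
    return(genome$sequence)
  }
  if (is.list(genome) && !is.null(genome$sequence)) return(genome$sequence)
  stop("cannot interpret 'genome': supply a sequence string or a one-row genome table",
       call. = FALSE)
}

genome_id_of <- function(genome, default = "genome") {
  if (is.data.frame(genome) && !is.null(genome$id)) return(genome$id[1])
  if (is.list(genome) && !is.null(genome$id)) return(genome$id)
  default
}
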