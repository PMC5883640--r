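#' Shared proteins between two proteomes
#'
#' For each protein of the first proteome, its best-scoring Smith-Waterman
#' local alignment (BLOSUM62, affine gaps 11/1) against the second proteome
#' is computed; if its Karlin-Altschul E-value is below `evalue_max` the
#' protein counts as shared. The count is unidirectional (a -> b, best hit
#' per query, ties broken by subject order); the shared fraction divides by
#' the smaller proteome size, and the mean amino-acid identity is averaged
#' over the shared best-hit pairs.
#'
#' @param proteome_a,proteome_b character vectors of protein sequences, or
#'   ORF tables from [predict_orfs()] (the `protein` column is used).
#' @param evalue_max E-value threshold for calling a hit shared.
#' @param genome_a,genome_b labels used in the result and error messages.
#' @return one-row `data.frame`: `genome_a`, `genome_b`, `n_shared`,
#'   `prop_shared`, `mean_aa_identity`.
#' @export
shared_proteins <- function(proteome_a, proteome_b, evalue_max = 1e-3,
                            genome_a = "a", genome_b = "b") {
  pa <- proteome_vector(proteome_a, genome_a)
  pb <- proteome_vector(proteome_b, genome_b)
  sc <- aa_pair_scores(pa, pb)
  shared_from_scores(sc, length(pa), length(pb), evalue_max,
                     genome_a, genome_b)
}

proteome_vector <- function(p, label) {
  if (is.data.frame(p)) {
    if (!is.null(p$genome_id) && nrow(p)) label <- p$genome_id[1]
    p <- p$protein
  }
  if (length(p) == 0L) {
    stop("empty proteome for genome '", label, "'", call. = FALSE)
  }
  as.character(p)
}

# derive the unidirectional a -> b best-hit summary from a score table
shared_from_scores <- function(sc, na, nb, evalue_max, genome_a, genome_b) {
  if (nrow(sc)) {
    best <- sc[order(qi, -score, sj)][, head(.SD, 1L), by = qi]
    best <- best[evalue <= evalue_max]
  } else {
    best <- sc
  }
  n_shared <- nrow(best)
  data.frame(
    genome_a = genome_a, genome_b = genome_b, n_shared = n_shared,
    prop_shared = n_shared / min(na, nb),
    mean_aa_identity = if (n_shared > 0) mean(best$pid) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Pairwise shared-protein matrix for a set of genomes
#'
#' Computes, for every unordered pair of genomes, the shared-protein summary
#' in both directions (a query-side best-hit rule is not symmetric) from a
#' single score table per pair, and returns the long table of results. The
#' symmetric value used for genus clustering is the maximum of the two
#' directions.
#'
#' @param genomes a [phage_genome_set()] table.
#' @param min_aa minimum ORF length passed to [predict_orfs()].
#' @param evalue_max shared-protein E-value threshold.
#' @param proteomes optional precomputed list of protein vectors named by
#'   genome id (skips ORF calling).
#' @return `data.frame` with one row per ordered pair: `genome_a`,
#'   `genome_b`, `n_shared`, `prop_shared`, `mean_aa_identity`.
#' @export
shared_protein_matrix <- function(genomes, min_aa = 30L, evalue_max = 1e-3,
                                  proteomes = NULL) {
  ids <- genomes$id
  if (is.null(proteomes)) {
    proteomes <- lapply(seq_len(nrow(genomes)), function(i) {
      predict_orfs(genomes[i, ], min_aa = min_aa)$protein
    })
    names(proteomes) <- ids
  }
  proteomes <- lapply(ids, function(id) {
    proteome_vector(proteomes[[id]], id)
  })
  names(proteomes) <- ids
  tabs <- lapply(proteomes, proteome_kmer_table)
  res <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      pa <- proteomes[[ids[i]]]
      pb <- proteomes[[ids[j]]]
      sc <- aa_pair_scores(pa, pb, tab_a = tabs[[ids[i]]],
                           tab_b = tabs[[ids[j]]])
      ab <- shared_from_scores(sc, length(pa), length(pb), evalue_max,
                               ids[i], ids[j])
      # b -> a direction: best hit per subject index of the same score table
      scr <- data.table::copy(sc)
      data.table::setnames(scr, c("qi", "sj"), c("sj", "qi"))
      ba <- shared_from_scores(scr, length(pb), length(pa), evalue_max,
                               ids[j], ids[i])
      res[[length(res) + 1L]] <- rbind(ab, ba)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Whole-genome identity between two phage genomes
#'
#' Anchor-based comparison: maximal exact matches of at least `word_length`
#' nucleotides are collected on both strands, the strand carrying more
#' anchor sequence is kept, anchors are chained colinearly (weighted longest
#' increasing subsequence) and the gaps between consecutive anchors are
#' aligned globally. Identity is computed over all aligned columns; the
#' aligned fraction is relative to the shorter genome.
#'
#' @param a,b one-row [phage_genome_set()] tables or DNA strings.
#' @param word_length minimum exact-match anchor length.
#' @param max_gap gap segments longer than this on either genome are left
#'   unaligned (treated as non-homologous insertions).
#' @return list with `identity_percent`, `aligned_fraction`, `strand`.
#' @export
genome_identity <- function(a, b, word_length = 11L, max_gap = 2000L) {
  sa <- genome_sequence(a); sb <- genome_sequence(b)
  if (nchar(sa) == 0L || nchar(sb) == 0L) stop("empty genome", call. = FALSE)
  short_len <- min(nchar(sa), nchar(sb))
  if (sa == sb) {
    return(list(identity_percent = 100, aligned_fraction = 1, strand = "+"))
  }
  mem <- maximal_exact_matches(sa, sb, word_length)
  tot <- tapply(mem$len, mem$strand, sum)
  if (length(tot) == 0L) {
    return(list(identity_percent = 0, aligned_fraction = 0, strand = "+"))
  }
  strand <- names(tot)[which.max(tot)]
  if (strand == "-") sb <- revcomp(sb)
  anchors <- merge_diagonal_runs(kmer_hits(sa, sb, word_length, max_occ = 64L),
                                 word_length)
  data.table::setorder(anchors, start_a, start_b)
  # genomes sharing almost no exact sequence: skip chaining and gap
  # alignment; whatever matches exactly is reported as-is and the aligned
  # fraction is bounded by the anchor total (far below any species gate)
  if (sum(anchors$len) < 0.02 * short_len) {
    return(list(identity_percent = 100,
                aligned_fraction = sum(anchors$len) / short_len,
                strand = strand))
  }
  chain <- chain_anchors(anchors)
  stats <- chained_identity(sa, sb, chain, max_gap)
  list(identity_percent = stats$identity,
       aligned_fraction = stats$aligned_short / short_len,
       strand = strand)
}

# weighted LIS chaining of anchors (start_a, start_b, len); anchors must be
# sorted by start_a. Returns the chained subset in order.
chain_anchors <- function(anchors) {
  n <- nrow(anchors)
  if (n == 0L) return(anchors)
  if (n > 600L) {  # keep DP quadratic cost bounded: drop shortest anchors
    keep <- order(anchors$len, decreasing = TRUE)[seq_len(600L)]
    anchors <- anchors[sort(keep)]
    n <- nrow(anchors)
  }
  s_a <- anchors$start_a; s_b <- anchors$start_b; L <- anchors$len
  e_a <- s_a + L; e_b <- s_b + L
  dp <- as.numeric(L)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (i == 1L) next
    j <- seq_len(i - 1L)
    ok <- e_a[j] <= s_a[i] & e_b[j] <= s_b[i]
    if (any(ok)) {
      cand <- j[ok]
      bi <- cand[which.max(dp[cand])]
      dp[i] <- L[i] + dp[bi]
      prev[i] <- bi
    }
  }
  i <- which.max(dp)
  path <- integer(0)
  while (!is.na(i)) {
    path <- c(i, path)
    i <- prev[i]
  }
  anchors[path]
}

# identity and aligned-length bookkeeping over a colinear chain. Gap pairs
# whose own alignment identity falls below gap_min_identity are treated as
# non-homologous (unaligned): chance anchors in biased-composition sequence
# must not stitch unrelated segments into the aligned fraction.
chained_identity <- function(sa, sb, chain, max_gap, gap_min_identity = 70) {
  if (nrow(chain) == 0L) {
    return(list(identity = 0, aligned_short = 0))
  }
  matches <- sum(chain$len)
  columns <- sum(chain$len)
  cov_a <- sum(chain$len); cov_b <- sum(chain$len)
  n <- nrow(chain)
  if (n > 1L) {
    i <- seq_len(n - 1L)
    ga0 <- chain$start_a[i] + chain$len[i]; ga1 <- chain$start_a[i + 1L] - 1L
    gb0 <- chain$start_b[i] + chain$len[i]; gb1 <- chain$start_b[i + 1L] - 1L
    la <- ga1 - ga0 + 1L; lb <- gb1 - gb0 + 1L
    small <- pmax(la, lb) <= max_gap
    indel <- small & pmin(la, lb) == 0L & pmax(la, lb) > 0L
    columns <- columns + sum(pmax(la[indel], lb[indel])[
      pmax(la[indel], lb[indel]) <= 50L])
    todo <- which(small & la > 0L & lb > 0L)
    if (length(todo)) {
      aln <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAStringSet(substring(sa, ga0[todo], ga1[todo])),
        subject = Biostrings::DNAStringSet(substring(sb, gb0[todo], gb1[todo])),
        type = "global", substitutionMatrix = nt_submat(1, -1),
        gapOpening = 2, gapExtension = 1
      )
      nm <- Biostrings::nmatch(aln)
      nc <- Biostrings::nchar(aln)
      # the identity floor only guards long gaps: a short gap between two
      # anchors is local divergence, not a candidate unrelated insertion
      ok <- pmax(la[todo], lb[todo]) <= 30L | 100 * nm / nc >= gap_min_identity
      matches <- matches + sum(nm[ok])
      columns <- columns + sum(nc[ok])
      cov_a <- cov_a + sum(la[todo][ok]); cov_b <- cov_b + sum(lb[todo][ok])
    }
  }
  aligned_short <- if (nchar(sa) <= nchar(sb)) cov_a else cov_b
  list(identity = 100 * matches / columns, aligned_short = aligned_short)
}

#' Group genomes into species by whole-genome identity
#'
#' Single-linkage clustering on the relation "identity above
#' `min_identity` percent over at least `min_fraction` of the shorter
#' genome", the usual nucleotide-level species demarcation for phages.
#'
#' @param genomes a [phage_genome_set()] table.
#' @param min_identity species identity threshold (percent, strict).
#' @param min_fraction minimum aligned fraction of the shorter genome.
#' @param identities optional precomputed pair table from
#'   [genome_identity_matrix()].
#' @return `data.frame` with `genome_id`, `species_id`; species are numbered
#'   by their lexicographically smallest member id.
#' @export
cluster_species <- function(genomes, min_identity = 95, min_fraction = 0.8,
                            identities = NULL) {
  ids <- genomes$id
  if (is.null(identities)) identities <- genome_identity_matrix(genomes)
  edges <- identities[identities$identity_percent > min_identity &
                      identities$aligned_fraction >= min_fraction,
                      c("genome_a", "genome_b"), drop = FALSE]
  partition_from_edges(ids, edges, "species_id")
}

#' All-pairs whole-genome identity
#'
#' @param genomes a [phage_genome_set()] table.
#' @param ... passed to [genome_identity()].
#' @return `data.frame` of unordered pairs with `identity_percent` and
#'   `aligned_fraction`.
#' @export
genome_identity_matrix <- function(genomes, ...) {
  ids <- genomes$id
  res <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      gi <- genome_identity(genomes[i, ], genomes[j, ], ...)
      res[[length(res) + 1L]] <- data.frame(
        genome_a = ids[i], genome_b = ids[j],
        identity_percent = gi$identity_percent,
        aligned_fraction = gi$aligned_fraction, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Group genomes into genera by shared-protein content
#'
#' Single-linkage components of the graph connecting genomes whose
#' symmetric shared-protein fraction (max of the two directions) reaches
#' `threshold`. The default 0.40 is the usual proteome-sharing genus
#' demarcation for phages.
#'
#' @param shared a long pair table from [shared_protein_matrix()], or a
#'   symmetric numeric matrix of shared fractions with genome ids as
#'   dimnames.
#' @param threshold genus threshold on the shared fraction (inclusive).
#' @param ids genome ids defining the universe (required when `shared` is a
#'   pair table; singletons would otherwise be lost).
#' @return `data.frame` with `genome_id`, `genus_id`; genera numbered by
#'   smallest member id.
#' @export
cluster_genera <- function(shared, threshold = 0.40, ids = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  if (is.matrix(shared)) {
    ids <- rownames(shared)
    pt <- which(upper.tri(shared), arr.ind = TRUE)
    tab <- data.frame(genome_a = ids[pt[, 1]], genome_b = ids[pt[, 2]],
                      prop_shared = pmax(shared[pt], t(shared)[pt]),
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(ids)) ids <- sort(unique(c(shared$genome_a, shared$genome_b)))
    key <- function(x, y) paste(pmin(x, y), pmax(x, y))
    agg <- tapply(shared$prop_shared, key(shared$genome_a, shared$genome_b), max)
    cmb <- t(utils::combn(sort(ids), 2L))
    wanted <- paste(cmb[, 1], cmb[, 2])
    if (!all(wanted %in% names(agg))) {
      stop("missing shared-protein value for pair(s): ",
           paste(utils::head(setdiff(wanted, names(agg)), 3L), collapse = "; "),
           call. = FALSE)
    }
    tab <- data.frame(genome_a = cmb[, 1], genome_b = cmb[, 2],
                      prop_shared = as.numeric(agg[wanted]),
                      stringsAsFactors = FALSE)
  }
  edges <- tab[tab$prop_shared >= threshold, c("genome_a", "genome_b"),
               drop = FALSE]
  partition_from_edges(ids, edges, "genus_id")
}

# single-linkage components with deterministic numbering by smallest member
partition_from_edges <- function(ids, edges, col) {
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership
  rep_id <- tapply(names(comp), comp, min)
  renum <- setNames(seq_along(sort(rep_id)), sort(rep_id))
  out <- data.frame(genome_id = ids,
                    cluster = as.integer(renum[rep_id[as.character(comp[ids])]]),
                    stringsAsFactors = FALSE)
  names(out)[2] <- col
  out
}

#' Full species + genus classification of a genome set
#'
#' Computes the shared-protein matrix and whole-genome identities, then
#' assigns species (identity) and genus (protein sharing) labels. Genomes of
#' the same species are forced into the same genus: species-level edges are
#' added to the genus graph before taking components.
#'
#' @param genomes a [phage_genome_set()] table.
#' @param genus_threshold shared-protein genus threshold.
#' @param species_identity species identity threshold (percent).
#' @param species_fraction minimum aligned fraction for species calls.
#' @param min_aa ORF length cutoff for proteomes.
#' @return list with `assignments` (`genome_id`, `species_id`, `genus_id`),
#'   `shared` (pair table) and `identity` (pair table).
#' @export
cluster_phages <- function(genomes, genus_threshold = 0.40,
                           species_identity = 95, species_fraction = 0.8,
                           min_aa = 30L) {
  shared <- shared_protein_matrix(genomes, min_aa = min_aa)
  idm <- genome_identity_matrix(genomes)
  species <- cluster_species(genomes, species_identity, species_fraction,
                             identities = idm)
  sp_edges <- merge(species, species, by = "species_id")
  sp_edges <- sp_edges[sp_edges$genome_id.x < sp_edges$genome_id.y,
                       c("genome_id.x", "genome_id.y")]
  names(sp_edges) <- c("genome_a", "genome_b")
  key <- function(x, y) paste(pmin(x, y), pmax(x, y))
  agg <- tapply(shared$prop_shared, key(shared$genome_a, shared$genome_b), max)
  pairs <- do.call(rbind, strsplit(names(agg), " "))
  tab <- data.frame(genome_a = pairs[, 1], genome_b = pairs[, 2],
                    prop_shared = as.numeric(agg), stringsAsFactors = FALSE)
  edges <- rbind(tab[tab$prop_shared >= genus_threshold, 1:2], sp_edges)
  genus <- partition_from_edges(genomes$id, edges, "genus_id")
  assignments <- merge(species, genus, by = "genome_id")
  assignments <- assignments[order(assignments$genome_id), ]
  rownames(assignments) <- NULL
  list(assignments = assignments, shared = shared, identity = idm)
}

#' Dotplot match coordinates for two genomes
#'
#' All maximal exact matches of at least `word_length` nucleotides between
#' the two sequences, on both strands. For a minus-strand match, `pos_b` is
#' the 0-based start of the matching segment on the forward strand of `b`.
#'
#' @param a,b genomes or DNA strings.
#' @param word_length minimal exact match length (>= 4).
#' @return `data.frame` with `pos_a`, `pos_b` (0-based starts), `length`,
#'   `strand`, sorted by `pos_a`.
#' @export
dotplot <- function(a, b, word_length = 11L) {
  stopifnot(word_length >= 4L)
  sa <- genome_sequence(a); sb <- genome_sequence(b)
  mem <- maximal_exact_matches(sa, sb, word_length)
  out <- data.frame(pos_a = mem$start_a - 1L, pos_b = mem$start_b - 1L,
                    length = mem$len, strand = mem$strand,
                    stringsAsFactors = FALSE)
  out[order(out$pos_a, out$pos_b), , drop = FALSE]
}

#' Plot dotplot matches
#'
#' @param matches output of [dotplot()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `matches`.
#' @export
plot_dotplot <- function(matches, ...) {
  graphics::plot(NA, xlim = range(c(matches$pos_a, matches$pos_a + matches$length)),
                 ylim = range(c(matches$pos_b, matches$pos_b + matches$length)),
                 xlab = "genome a (bp)", ylab = "genome b (bp)", ...)
  fw <- matches$strand == "+"
  graphics::segments(matches$pos_a[fw], matches$pos_b[fw],
                     matches$pos_a[fw] + matches$length[fw],
                     matches$pos_b[fw] + matches$length[fw])
  graphics::segments(matches$pos_a[!fw],
                     matches$pos_b[!fw] + matches$length[!fw],
                     matches$pos_a[!fw] + matches$length[!fw],
                     matches$pos_b[!fw], col = "red3")
  invisible(matches)
}
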