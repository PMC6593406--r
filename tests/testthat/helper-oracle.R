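# Independent oracles used to check the package's engines. These are
# deliberately separate implementations: plain-R dynamic programming for
# local alignment, and full enumeration for the resampling curves.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Plain-R Gotoh local alignment, score only. A gap of length L costs
# gapOpen + L * gapExt.
swOracleScore <- function(q, s, mat = blosum62, gapOpen = 11, gapExt = 1) {
  qi <- strsplit(q, "")[[1]]
  si <- strsplit(s, "")[[1]]
  m <- length(qi); n <- length(si)
  if (m == 0 || n == 0) return(0)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  for (i in seq_len(m) + 1) {
    for (j in seq_len(n) + 1) {
      E[i, j] <- max(H[i, j - 1] - gapOpen - gapExt, E[i, j - 1] - gapExt)
      F[i, j] <- max(H[i - 1, j] - gapOpen - gapExt, F[i - 1, j] - gapExt)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[qi[i - 1], si[j - 1]],
                     E[i, j], F[i, j])
    }
  }
  max(H)
}

# All peptides of lengths 1..maxLen over an alphabet.
allPeptides <- function(alphabet, maxLen) {
  unlist(lapply(seq_len(maxLen), function(l) {
    g <- do.call(expand.grid, rep(list(alphabet), l))
    apply(g, 1, paste, collapse = "")
  }))
}

# Exhaustive-mean accumulation curves: average core/pan over every one of
# the N^N equally likely ordered with-replacement draws, computed directly
# from the membership table (no package code).
enumAccumulationOracle <- function(membership, genomeIds) {
  N <- length(genomeIds)
  clusters <- split(membership$genome_id, membership$cluster_id)
  coreSize <- function(set) sum(vapply(clusters, function(g)
    all(set %in% g), logical(1)))
  panSize <- function(set) sum(vapply(clusters, function(g)
    any(set %in% g), logical(1)))
  orders <- as.matrix(do.call(expand.grid, rep(list(seq_len(N)), N)))
  core <- pan <- matrix(0, nrow(orders), N)
  for (d in seq_len(nrow(orders))) {
    for (k in seq_len(N)) {
      set <- unique(genomeIds[orders[d, seq_len(k)]])
      core[d, k] <- coreSize(set)
      pan[d, k] <- panSize(set)
    }
  }
  list(core_mean = colMeans(core), pan_mean = colMeans(pan))
}

# Closed-form Bray-Curtis for two count vectors.
brayOracle <- function(u, v) {
  tot <- sum(u + v)
  if (tot == 0) return(0)
  sum(abs(u - v)) / tot
}

# Fixed-codon reverse translation (first codon in alphabetical order per
# residue) -- used to build reads that must recruit to a peptide.
naiveBackTranslate <- function(pep) {
  gc <- Biostrings::GENETIC_CODE
  aa <- strsplit(pep, "")[[1]]
  paste(vapply(aa, function(a) sort(names(gc)[gc == a])[1], character(1)),
        collapse = "")
}

revcompChr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
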