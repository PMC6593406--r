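# Six-frame translation and peptide local alignment.

#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames `+1..+3` translate the forward strand from offsets 0..2, frames
#' `-1..-3` the reverse complement likewise, under the standard genetic
#' code. Stop codons are emitted as `*`; codons touching an ambiguous base
#' (N) become `X`. Frames too short for a full codon yield empty strings.
#'
#' @param dna a single nucleotide sequence (character or
#'   [Biostrings::DNAString]).
#' @return named character vector of six peptides
#'   (`"+1" "+2" "+3" "-1" "-2" "-3"`).
#' @examples
#' sixFrameTranslate("ATGGCC")  # frame +1 "MA", frame -1 "GH"
#' @export
sixFrameTranslate <- function(dna) {
  dna <- Biostrings::DNAString(as.character(dna))
  fr <- function(s, off) {
    n <- length(s) - off
    if (n < 3L) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(s, off + 1L, off + (n %/% 3L) * 3L),
      if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  rc <- Biostrings::reverseComplement(dna)
  c("+1" = fr(dna, 0L), "+2" = fr(dna, 1L), "+3" = fr(dna, 2L),
    "-1" = fr(rc, 0L), "-2" = fr(rc, 1L), "-3" = fr(rc, 2L))
}

# Internal: BLOSUM62 (from Biostrings' data) expanded to the 27-letter
# A..Z,'*' index space used by the C++ engine; letters without a BLOSUM62
# row (J in old releases, U, O) score as X. Cached per session.
.scoreMatrixCache <- new.env(parent = emptyenv())

.aaScoreMatrix <- function(name = "BLOSUM62") {
  if (!is.null(.scoreMatrixCache[[name]])) return(.scoreMatrixCache[[name]])
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  base <- e[[name]]
  letters27 <- c(LETTERS, "*")
  pick <- function(l) if (l %in% rownames(base)) l else "X"
  m <- matrix(0L, 27, 27, dimnames = list(letters27, letters27))
  for (i in letters27) for (j in letters27)
    m[i, j] <- as.integer(base[pick(i), pick(j)])
  .scoreMatrixCache[[name]] <- m
  m
}

#' Optimal local alignment of two peptides
#'
#' Smith-Waterman alignment under BLOSUM62 with affine gap penalties (a gap
#' of length L costs `gapOpen + L * gapExt`). Identity is computed over all
#' aligned columns (gap columns count against identity); subject coverage is
#' the aligned subject span as a percentage of subject length.
#'
#' @param query,subject peptide strings.
#' @param gapOpen,gapExt gap opening / extension penalties (positive).
#' @param matrix substitution matrix name (a Biostrings data matrix).
#' @return list with `score`, `percent_identity`, `align_len`,
#'   `subject_cov`, and the 1-based aligned spans `qstart`, `qend`,
#'   `sstart`, `send`. Empty input gives score 0 and an empty alignment.
#' @examples
#' localAlignPeptide("MKV", "MKV")$score  # 14 under BLOSUM62
#' @export
localAlignPeptide <- function(query, subject, gapOpen = 11, gapExt = 1,
                              matrix = "BLOSUM62") {
  r <- cpp_sw_pair(toupper(as.character(query)), toupper(as.character(subject)),
                   .aaScoreMatrix(matrix), gapOpen, gapExt)
  slen <- nchar(subject)
  list(score = r$score,
       percent_identity = if (r$align_len > 0) 100 * r$n_identical / r$align_len else 0,
       align_len = r$align_len,
       subject_cov = if (r$align_len > 0 && slen > 0)
         100 * (r$send - r$sstart + 1) / slen else 0,
       qstart = r$qstart, qend = r$qend,
       sstart = r$sstart, send = r$send)
}
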