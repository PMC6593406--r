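# Translated read recruitment: built-in search engine, tabular-hit parsing
# and best-hit filtering.

# Karlin-Altschul parameters used for the approximate E-value of the
# built-in engine: gapped BLOSUM62 with gap open 11 / extend 1.
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

#' Construct a read library
#'
#' @param reads named [Biostrings::DNAStringSet] (or named character) of
#'   read records; in a paired library each mate is one record.
#' @param libraryId single string.
#' @param layout `"single"` or `"paired"`.
#' @param truth optional per-read provenance table (see [generateReads()]).
#' @return a [ReadLibrary-class].
#' @export
ReadLibrary <- function(reads, libraryId = "library1", layout = "single",
                        truth = data.frame()) {
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  new("ReadLibrary", libraryId = libraryId, reads = reads, layout = layout,
      truth = truth)
}

#' Read a library of raw reads from FASTQ or FASTA
#'
#' Format is chosen from the file extension (`.fastq`/`.fq` vs
#' `.fasta`/`.fa`/`.fna`, optionally `.gz`).
#'
#' @param path input file.
#' @param libraryId library id; defaults to the file name stem.
#' @param layout `"single"` or `"paired"` (records of a paired library are
#'   interleaved or concatenated mates; each record counts once).
#' @return a [ReadLibrary-class].
#' @export
readReadLibrary <- function(path, libraryId = NULL, layout = "single") {
  stem <- sub("\\.gz$", "", basename(path))
  fmt <- if (grepl("\\.(fastq|fq)$", stem, ignore.case = TRUE)) "fastq" else "fasta"
  reads <- Biostrings::readDNAStringSet(path, format = fmt)
  names(reads) <- sub("\\s.*$", "", names(reads))
  if (is.null(libraryId)) libraryId <- sub("\\.[^.]*$", "", stem)
  ReadLibrary(reads, libraryId, layout)
}

#' Write a read library to FASTQ
#'
#' @param lib a [ReadLibrary-class].
#' @param path output file path (`.gz` allowed).
#' @return `path`, invisibly.
#' @export
writeReadLibrary <- function(lib, path) {
  r <- readSequences(lib)
  q <- Biostrings::BStringSet(vapply(Biostrings::width(r), function(w)
    paste(rep("I", w), collapse = ""), character(1)))
  Biostrings::writeXStringSet(r, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Recruit reads to protein panels by translated local alignment
#'
#' Emulates a blastx-style screen at desk scale: each read is translated in
#' all six frames and aligned (Smith-Waterman, BLOSUM62, affine gaps 11/1)
#' against every panel member sharing an exact `seedLength`-mer amino-acid
#' seed with the frame; alignments scoring below `minScore` are suppressed.
#' An approximate E-value is attached via the Karlin-Altschul form
#' `E = K * m * n * exp(-lambda * S)` with the gapped BLOSUM62 defaults
#' (lambda 0.267, K 0.041) and search space `m * n` = (read length / 3) x
#' total panel residues; it is reported for comparability with external
#' tools, while thresholding inside the engine uses the raw score.
#'
#' The default `minScore` of 110 (about 43 bits) was calibrated on the
#' Karlin-Altschul null so that libraries of millions of unrelated 100-150 bp
#' reads are expected to yield no spurious hit; lower it to trade
#' specificity for sensitivity to shorter in-frame overlaps.
#'
#' @param lib a [ReadLibrary-class].
#' @param ps a [PanelSet-class]; must pass [validatePanels()].
#' @param minScore raw-score reporting floor of the engine.
#' @param seedLength exact amino-acid seed length (2-6).
#' @param gapOpen,gapExt affine gap penalties.
#' @return data.frame of read hits with columns `read_id`, `subject_id`,
#'   `panel_id`, `percent_identity`, `alignment_length_aa`, `subject_cov`,
#'   `score`, `bitscore`, `evalue`, `frame`. Zero rows for an empty library.
#' @seealso [filterBestHits()], [parseTabularHits()]
#' @export
searchReads <- function(lib, ps, minScore = 110, seedLength = 5,
                        gapOpen = 11, gapExt = 1) {
  issues <- validatePanels(ps)
  if (nrow(issues))
    stop("invalid panel set: ", paste(issues$issue, collapse = "; "))
  stopifnot(seedLength >= 2, seedLength <= 6)
  reads <- readSequences(lib)
  members <- .panelMemberTable(ps)
  if (length(reads) == 0L) return(.emptyHits())
  hits <- cpp_search_reads(as.character(reads),
                           as.character(.panelMemberSeqs(ps)),
                           .aaScoreMatrix(), gapOpen, gapExt,
                           as.integer(seedLength), minScore)
  if (nrow(hits) == 0L) return(.emptyHits())
  m <- pmax(Biostrings::width(reads)[hits$read] %/% 3L, 1L)
  n <- sum(members$length_aa)
  bitscore <- (.KA_LAMBDA * hits$score - log(.KA_K)) / log(2)
  data.frame(
    read_id = names(reads)[hits$read],
    subject_id = members$seq_id[hits$subject],
    panel_id = members$panel_id[hits$subject],
    percent_identity = 100 * hits$n_identical / hits$align_len,
    alignment_length_aa = hits$align_len,
    subject_cov = 100 * (hits$send - hits$sstart + 1) /
      members$length_aa[hits$subject],
    score = as.numeric(hits$score),
    bitscore = bitscore,
    evalue = m * n * 2^(-bitscore),
    frame = hits$frame,
    stringsAsFactors = FALSE)
}

.emptyHits <- function() {
  data.frame(read_id = character(), subject_id = character(),
             panel_id = character(), percent_identity = numeric(),
             alignment_length_aa = integer(), subject_cov = numeric(),
             score = numeric(), bitscore = numeric(), evalue = numeric(),
             frame = integer(), stringsAsFactors = FALSE)
}

#' Parse 12-column tabular translated-search output
#'
#' Accepts the standard blastx-style tabular format (`qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore`, as
#' produced with `diamond blastx`/`blastx -outfmt 6`) as an alternative to
#' the built-in engine. Subject coverage is recomputed as the aligned
#' subject span over the subject length known from the panel set.
#'
#' @param path tabular hit file (no header).
#' @param ps a [PanelSet-class]; rows whose subject is not a panel member
#'   are dropped (with the count reported as attribute `n_dropped` and a
#'   message) unless `strict = TRUE`, in which case they are an error.
#' @param strict error on unknown subjects?
#' @return data.frame of read hits in the same shape as [searchReads()]
#'   (column `frame` is `NA`, `score` duplicates `bitscore`).
#' @export
parseTabularHits <- function(path, ps, strict = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(.emptyHits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad))
    stop("malformed row at line ", bad[1], ": expected 12 tab-separated ",
         "columns, got ", lengths(fields)[bad[1]])
  tab <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(tab) <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                  "bitscore")
  num <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
           "sstart", "send", "evalue", "bitscore")
  for (col in num) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v))
      stop("malformed row at line ", which(is.na(v))[1],
           ": non-numeric '", col, "'")
    tab[[col]] <- v
  }
  members <- .panelMemberTable(ps)
  idx <- match(tab$sseqid, members$seq_id)
  if (anyNA(idx)) {
    if (strict)
      stop("unknown subject at line ", which(is.na(idx))[1], ": '",
           tab$sseqid[which(is.na(idx))[1]], "'")
    nd <- sum(is.na(idx))
    message(nd, " row(s) for non-panel subjects dropped")
    tab <- tab[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  } else nd <- 0L
  out <- data.frame(
    read_id = tab$qseqid,
    subject_id = tab$sseqid,
    panel_id = members$panel_id[idx],
    percent_identity = tab$pident,
    alignment_length_aa = as.integer(tab$length),
    subject_cov = 100 * (pmax(tab$sstart, tab$send) -
                           pmin(tab$sstart, tab$send) + 1) /
      members$length_aa[idx],
    score = tab$bitscore,
    bitscore = tab$bitscore,
    evalue = tab$evalue,
    frame = NA_integer_,
    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- nd
  out
}

#' Keep each read's single best hit passing the screening thresholds
#'
#' Applies the screening thresholds as strict inequalities — E-value below
#' `evalueMax`, amino-acid identity above `minIdentity` percent, subject
#' coverage above `minSubjectCov` percent — then keeps, per read, the single
#' best-scoring surviving hit. Score ties are broken by lexicographically
#' smallest `subject_id`, so the result is invariant to input order.
#'
#' @param hits data.frame as from [searchReads()] or [parseTabularHits()].
#' @param evalueMax,minIdentity,minSubjectCov strict thresholds. The
#'   defaults (`1e-5`, 30, 0) are the read-screening configuration; the
#'   protein-vs-protein transporter census additionally requires
#'   `minSubjectCov = 70`.
#' @return data.frame with at most one row per `read_id`.
#' @export
filterBestHits <- function(hits, evalueMax = 1e-5, minIdentity = 30,
                           minSubjectCov = 0) {
  keep <- hits$evalue < evalueMax & hits$percent_identity > minIdentity &
    hits$subject_cov > minSubjectCov
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$read_id, -hits$score, hits$subject_id)
  hits <- hits[o, , drop = FALSE]
  hits <- hits[!duplicated(hits$read_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
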