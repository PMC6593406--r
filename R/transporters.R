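# Transporter-family census: hit filtering, transmembrane screening,
# count matrices and Bray-Curtis NMDS ordination.

#' Built-in demonstration shortlist of uptake transporter families
#'
#' A small set of Transporter Classification (TC) families and subfamilies
#' known as energy-dependent uptake systems for organic substrates: ABC
#' uptake subfamilies (carbohydrate and peptide/opine/nickel and polar/
#' hydrophobic amino-acid uptake transporters), TRAP-T, SSS, CNT, DAACS and
#' NSS. Real analyses should supply their own curated shortlist; this one
#' exists so the census is runnable and testable out of the box.
#'
#' @return data.frame with columns `family_id` (TC prefix) and
#'   `family_name`.
#' @export
uptakeFamilyShortlist <- function() {
  data.frame(
    family_id = c("3.A.1.1", "3.A.1.2", "3.A.1.3", "3.A.1.4", "3.A.1.5",
                  "2.A.56", "2.A.21", "2.A.41", "2.A.23", "2.A.22"),
    family_name = c("ABC CUT1 (carbohydrate uptake)",
                    "ABC CUT2 (carbohydrate uptake)",
                    "ABC PAAT (polar amino acid uptake)",
                    "ABC HAAT (hydrophobic amino acid uptake)",
                    "ABC PepT (peptide/opine/nickel uptake)",
                    "TRAP-T (tripartite ATP-independent periplasmic)",
                    "SSS (solute:sodium symporter)",
                    "CNT (concentrative nucleoside transporter)",
                    "DAACS (dicarboxylate/amino acid:cation symporter)",
                    "NSS (neurotransmitter:sodium symporter)"),
    stringsAsFactors = FALSE)
}

#' Extract the TC family/subfamily id from a subject identifier
#'
#' TCDB subject ids carry a TC number such as `2.A.23.1.5`, either bare or
#' after an accession (`P12345|2.A.23.1.5`). The id is truncated to
#' `levels` components (3 = family, 4 = subfamily).
#'
#' @param sseqid character vector of subject ids.
#' @param levels number of TC components to keep.
#' @return character vector (`NA` where no TC number is found).
#' @examples
#' tcFamily("Q9KQR9|2.A.23.1.5")        # "2.A.23"
#' tcFamily("3.A.1.5.1", levels = 4)    # "3.A.1.5"
#' @export
tcFamily <- function(sseqid, levels = 3) {
  m <- regmatches(sseqid,
                  regexpr("[0-9]+\\.[A-Z]\\.[0-9]+(\\.[0-9]+)*", sseqid))
  tc <- rep(NA_character_, length(sseqid))
  tc[regexpr("[0-9]+\\.[A-Z]\\.[0-9]+(\\.[0-9]+)*", sseqid) > 0] <- m
  vapply(tc, function(x) {
    if (is.na(x)) return(NA_character_)
    parts <- strsplit(x, ".", fixed = TRUE)[[1]]
    paste(parts[seq_len(min(levels, length(parts)))], collapse = ".")
  }, character(1), USE.NAMES = FALSE)
}

# Internal: does each TC id fall under any shortlist prefix (at component
# boundaries)?
.inShortlist <- function(tcid, shortlist) {
  if (is.data.frame(shortlist)) shortlist <- shortlist$family_id
  vapply(tcid, function(x) {
    if (is.na(x)) return(FALSE)
    any(x == shortlist | startsWith(x, paste0(shortlist, ".")))
  }, logical(1), USE.NAMES = FALSE)
}

# Internal: map each TC id to the shortlist family it falls under.
.shortlistFamily <- function(tcid, shortlist) {
  if (is.data.frame(shortlist)) shortlist <- shortlist$family_id
  vapply(tcid, function(x) {
    if (is.na(x)) return(NA_character_)
    hit <- shortlist[x == shortlist | startsWith(x, paste0(shortlist, "."))]
    if (length(hit)) hit[1] else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Filter protein-vs-TCDB hits down to shortlisted uptake families
#'
#' Applies the census thresholds as strict inequalities — E-value below
#' `evalueMax`, identity above `minIdentity`%, subject coverage above
#' `minSubjectCov`% of the reference sequence — keeps only hits whose TC
#' family is on the uptake shortlist, and retains per query (ORF) the single
#' best-scoring surviving hit. Rows whose subject id yields no TC number are
#' dropped with a warning.
#'
#' @param hits data.frame in 12-column tabular form (`qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`).
#' @param subjectLengths named numeric: reference (subject) lengths in
#'   residues, for subject coverage.
#' @param shortlist uptake family ids (character or the data.frame of
#'   [uptakeFamilyShortlist()]).
#' @param evalueMax,minIdentity,minSubjectCov strict thresholds (defaults
#'   1e-5, 30, 70).
#' @return the surviving hit rows with a `family` column (the shortlist
#'   family the hit falls under), one row per query.
#' @export
filterTransporterHits <- function(hits, subjectLengths,
                                  shortlist = uptakeFamilyShortlist(),
                                  evalueMax = 1e-5, minIdentity = 30,
                                  minSubjectCov = 70) {
  tc <- tcFamily(hits$sseqid, levels = 5)
  if (anyNA(tc)) {
    warning(sum(is.na(tc)), " hit(s) with unresolvable TC id dropped")
    hits <- hits[!is.na(tc), , drop = FALSE]
    tc <- tc[!is.na(tc)]
  }
  slen <- subjectLengths[hits$sseqid]
  if (anyNA(slen)) stop("missing subject length for: ",
                        paste(unique(hits$sseqid[is.na(slen)]), collapse = ", "))
  scov <- 100 * (pmax(hits$sstart, hits$send) -
                   pmin(hits$sstart, hits$send) + 1) / slen
  fam <- .shortlistFamily(tc, shortlist)
  keep <- hits$evalue < evalueMax & hits$pident > minIdentity &
    scov > minSubjectCov & !is.na(fam)
  hits <- hits[keep, , drop = FALSE]
  hits$family <- fam[keep]
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$qseqid, -hits$bitscore, hits$sseqid)
  hits <- hits[o, , drop = FALSE]
  hits <- hits[!duplicated(hits$qseqid), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Kyte-Doolittle hydropathy values.
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
         G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
         P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0)

#' Predict transmembrane segments by hydropathy
#'
#' Sliding-window Kyte-Doolittle hydropathy (window 19): every window with
#' mean hydropathy above the threshold marks a candidate membrane-spanning
#' stretch, and overlapping windows are merged into segments. This is an
#' explicit, simple stand-in for HMM-based transmembrane predictors — it
#' distinguishes clearly hydrophobic spans from soluble sequence, which is
#' all the census needs; supply a precomputed annotation to
#' [buildFamilyMatrix()] when a dedicated predictor's calls are available.
#'
#' @param protein one peptide (character or [Biostrings::AAStringSet]
#'   element). Residues without a hydropathy value (X) score 0.
#' @param window window size in residues (default 19).
#' @param threshold mean-hydropathy cutoff (default 1.6).
#' @return data.frame with columns `start`, `end` (residue coordinates of
#'   merged segments); zero rows when the sequence is shorter than the
#'   window or no window passes.
#' @examples
#' nrow(predictTMSegments(strrep("L", 30)))  # 1
#' nrow(predictTMSegments(strrep("D", 30)))  # 0
#' @export
predictTMSegments <- function(protein, window = 19, threshold = 1.6) {
  s <- strsplit(toupper(as.character(protein)), "")[[1]]
  n <- length(s)
  empty <- data.frame(start = integer(), end = integer())
  if (n < window) return(empty)
  h <- .KD[s]
  h[is.na(h)] <- 0
  cs <- c(0, cumsum(h))
  means <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  hit <- which(means > threshold)
  if (length(hit) == 0L) return(empty)
  brk <- c(0, which(diff(hit) > 1), length(hit))
  data.frame(
    start = hit[brk[-length(brk)] + 1],
    end = hit[brk[-1]] + window - 1L)
}

#' Count transmembrane segments for a set of proteins
#'
#' @param proteins [Biostrings::AAStringSet] or character vector.
#' @param ... passed to [predictTMSegments()].
#' @return integer vector of segment counts, named as the input.
#' @export
countTMSegments <- function(proteins, ...) {
  out <- vapply(as.character(proteins),
                function(p) nrow(predictTMSegments(p, ...)),
                integer(1), USE.NAMES = FALSE)
  names(out) <- names(proteins)
  out
}

#' Build the genome-by-family transporter count matrix
#'
#' Tabulates, per genome and shortlist family, how many ORFs have their kept
#' hit in that family (`total` assay) and how many of those ORFs carry at
#' least one transmembrane segment (`tm` assay). Families with no hit in any
#' genome appear as zero rows, so matrices from different genome sets share
#' a common family space.
#'
#' @param hits filtered hits ([filterTransporterHits()]) across all genomes,
#'   with an added `genome_id` column and a logical `has_tm` column (e.g.
#'   `countTMSegments(orfs)[hits$qseqid] > 0`, or an external predictor's
#'   calls).
#' @param genomes character vector of all genome ids (zero columns are kept
#'   for genomes without hits).
#' @param families family ids defining the rows; defaults to the shortlist
#'   families present plus [uptakeFamilyShortlist()].
#' @param genomeSizeOrfs optional named numeric, genome size in ORFs (kept
#'   in `colData`).
#' @return a [FamilyCountMatrix-class].
#' @export
buildFamilyMatrix <- function(hits, genomes,
                              families = uptakeFamilyShortlist()$family_id,
                              genomeSizeOrfs = NULL) {
  if (length(genomes) == 0L) stop("genome list is empty")
  if (nrow(hits) && !all(c("genome_id", "family", "has_tm") %in% names(hits)))
    stop("hits need columns genome_id, family, has_tm")
  families <- union(families, unique(hits$family))
  fg <- function(sel) {
    t(table(factor(hits$family[sel], levels = families),
            factor(hits$genome_id[sel], levels = genomes)))
  }
  total <- t(unclass(fg(rep(TRUE, nrow(hits)))))
  tm <- t(unclass(fg(if (nrow(hits)) hits$has_tm else logical(0))))
  cd <- S4Vectors::DataFrame(
    n_orfs = if (is.null(genomeSizeOrfs)) rep(NA_real_, length(genomes)) else
      as.numeric(genomeSizeOrfs[genomes]),
    row.names = genomes)
  new("FamilyCountMatrix", SummarizedExperiment::SummarizedExperiment(
    assays = list(total = total, tm = tm), colData = cd))
}

#' Bray-Curtis dissimilarity between genomes' transporter repertoires
#'
#' `d(u, v) = sum |u_f - v_f| / sum (u_f + v_f)` over families. Computed
#' with [vegan::vegdist()]; a pair of all-zero repertoires has no defined
#' dissimilarity and is set to 0 with a warning.
#'
#' @param x a [FamilyCountMatrix-class] or a plain genomes-by-families
#'   count matrix.
#' @param which `"total"` or `"tm"` counts (for a `FamilyCountMatrix`).
#' @return symmetric matrix of dissimilarities in `[0, 1]`, zero diagonal.
#' @export
brayCurtisMatrix <- function(x, which = c("total", "tm")) {
  which <- match.arg(which)
  m <- if (is(x, "FamilyCountMatrix"))
    t(SummarizedExperiment::assay(x, which)) else as.matrix(x)
  if (nrow(m) < 2L) stop("need at least two genomes")
  d <- as.matrix(suppressWarnings(vegan::vegdist(m, method = "bray")))
  if (anyNA(d)) {
    warning("all-zero repertoire pair(s): dissimilarity set to 0")
    d[is.na(d)] <- 0
  }
  diag(d) <- 0
  d
}

#' Nonmetric multidimensional scaling of a dissimilarity matrix
#'
#' NMDS minimizing Kruskal stress-1 over monotone regression, taking the
#' best of `restarts` random starts ([vegan::metaMDS()]); the result is
#' deterministic given `seed`. Coordinates are centered.
#'
#' @param d symmetric dissimilarity matrix (or `dist`), zero diagonal.
#' @param dims number of ordination dimensions (default 2).
#' @param restarts number of random starts (default 2000, matching a
#'   thorough published configuration; far fewer suffice for small
#'   matrices).
#' @param seed integer seed.
#' @param distanceMetric label recorded for the dissimilarity supplied.
#' @return an [OrdinationResult-class].
#' @export
nmdsOrdinate <- function(d, dims = 2, restarts = 2000, seed = 1,
                         distanceMetric = "bray") {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("distance matrix must be symmetric")
  set.seed(seed)
  fit <- suppressMessages(suppressWarnings(
    vegan::metaMDS(stats::as.dist(m), k = dims, try = restarts,
                   trymax = restarts, autotransform = FALSE, trace = 0,
                   wascores = FALSE)))
  pts <- sweep(fit$points, 2, colMeans(fit$points))
  rownames(pts) <- rownames(m)
  colnames(pts) <- paste0("NMDS", seq_len(dims))
  new("OrdinationResult", points = pts, stress = fit$stress,
      distanceMetric = distanceMetric, nRestarts = as.integer(restarts),
      seed = as.integer(seed))
}
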