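# Shared fixtures, built in code.

# Tiny two-panel set with fixed, hand-chosen peptides.
tinyPanelSet <- function() {
  PanelSet(
    ProteinPanel("rubisco", "target",
                 c(rbcL_1 = "MSPQTETKASVGFKAGVKDYKLTYYTPDYETKDTDILAAFRVT"),
                 ecNumbers = "4.1.1.39", pathwayLabel = "CBB"),
    ProteinPanel("gltA", "reference",
                 c(gltA_1 = "MADTKAKLTLNGDTAVELDVLKGTLGQDVIDIRTLGSKGVFTFD"),
                 ecNumbers = "2.3.3.16", pathwayLabel = "TCA reference"))
}

# One hit-table row with overridable fields.
mkHit <- function(read_id = "r1", subject_id = "s1", panel_id = "p1",
                  percent_identity = 90, alignment_length_aa = 40L,
                  subject_cov = 95, score = 150, bitscore = 60,
                  evalue = 1e-20, frame = 1L) {
  data.frame(read_id = read_id, subject_id = subject_id, panel_id = panel_id,
             percent_identity = percent_identity,
             alignment_length_aa = alignment_length_aa,
             subject_cov = subject_cov, score = score, bitscore = bitscore,
             evalue = evalue, frame = frame, stringsAsFactors = FALSE)
}

# One 12-column tabular (m8) row as a tab-joined line.
m8Line <- function(qseqid = "r1", sseqid = "s1", pident = 90, length = 40,
                   mismatch = 2, gapopen = 0, qstart = 1, qend = 120,
                   sstart = 1, send = 40, evalue = 1e-20, bitscore = 80) {
  paste(qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
        sstart, send, evalue, bitscore, sep = "\t")
}

# Small ortholog table: G1 = {a,b}, G2 = {b,c}.
toyOrthologTable <- function() {
  OrthologTable(data.frame(
    cluster_id = c("a", "b", "b", "c"),
    genome_id = c("G1", "G1", "G2", "G2"),
    gene_id = c("g1", "g2", "g3", "g4"),
    stringsAsFactors = FALSE))
}

randomAA <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(rownames(blosum62)[1:20], len, replace = TRUE),
          collapse = ""), character(1))
}
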