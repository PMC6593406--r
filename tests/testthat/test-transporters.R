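mkTcHit <- function(qseqid = "orf1", sseqid = "P1|2.A.23.1.5", pident = 50,
                    length = 100, sstart = 1, send = 95, evalue = 1e-20,
                    bitscore = 200) {
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
             length = length, mismatch = 0, gapopen = 0, qstart = 1,
             qend = 100, sstart = sstart, send = send, evalue = evalue,
             bitscore = bitscore, stringsAsFactors = FALSE)
}

test_that("TC family ids are extracted from subject identifiers", {
  expect_equal(tcFamily("Q9KQR9|2.A.23.1.5"), "2.A.23")
  expect_equal(tcFamily("3.A.1.5.1", levels = 4), "3.A.1.5")
  expect_true(is.na(tcFamily("no-tc-here")))
})

test_that("transporter hit filtering enforces the strict census thresholds", {
  slen <- c("P1|2.A.23.1.5" = 100, "P2|2.A.21.3.1" = 100,
            "P3|9.B.99.1.1" = 100)
  hits <- rbind(
    mkTcHit("keep", pident = 35, send = 80, evalue = 1e-6),
    mkTcHit("lowid", pident = 29),                    # fails > 30
    mkTcHit("id30", pident = 30),                     # boundary fails (strict)
    mkTcHit("lowcov", send = 70),                     # 70% fails > 70
    mkTcHit("bade", evalue = 1e-4),                   # fails < 1e-5
    mkTcHit("offlist", sseqid = "P3|9.B.99.1.1"),     # family not shortlisted
    mkTcHit("two", sseqid = "P1|2.A.23.1.5", bitscore = 100),
    mkTcHit("two", sseqid = "P2|2.A.21.3.1", bitscore = 150))
  out <- filterTransporterHits(hits, slen)
  expect_setequal(out$qseqid, c("keep", "two"))
  expect_equal(out$family[out$qseqid == "keep"], "2.A.23")
  expect_equal(out$family[out$qseqid == "two"], "2.A.21")  # higher bitscore
  expect_equal(anyDuplicated(out$qseqid), 0L)

  expect_warning(
    filterTransporterHits(rbind(mkTcHit("q", sseqid = "noTC")),
                          c(noTC = 100)),
    "unresolvable")
})

test_that("hydropathy windows find hydrophobic spans and skip soluble ones", {
  expect_equal(nrow(predictTMSegments(strrep("L", 30))), 1L)
  expect_equal(nrow(predictTMSegments(strrep("D", 30))), 0L)
  expect_equal(nrow(predictTMSegments("LLLL")), 0L)  # shorter than window
  # two hydrophobic helices separated by a charged loop -> two segments
  seq2 <- paste0(strrep("L", 22), strrep("D", 25), strrep("I", 22))
  expect_equal(nrow(predictTMSegments(seq2)), 2L)
  expect_equal(countTMSegments(c(a = strrep("L", 30), b = strrep("D", 30))),
               c(a = 1L, b = 0L))
})

test_that("the family count matrix tabulates totals and TM subsets", {
  hits <- data.frame(
    genome_id = c("G1", "G1", "G1", "G2"),
    qseqid = c("o1", "o2", "o3", "o4"),
    family = c("2.A.23", "2.A.23", "2.A.23", "2.A.21"),
    has_tm = c(TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  m <- buildFamilyMatrix(hits, genomes = c("G1", "G2", "G3"))
  expect_s4_class(m, "FamilyCountMatrix")
  expect_equal(countsTotal(m)["2.A.23", "G1"], 3)
  expect_equal(countsTM(m)["2.A.23", "G1"], 2)
  expect_equal(countsTotal(m)["2.A.21", "G2"], 1)
  expect_true(all(countsTotal(m)[, "G3"] == 0))
  expect_true(all(countsTM(m) <= countsTotal(m)))
  # column sums over genomes equal kept hits per family
  expect_equal(sum(countsTotal(m)["2.A.23", ]), 3)
  expect_equal(sum(countsTotal(m)), nrow(hits))
  # empty hits: declared zero matrix
  m0 <- buildFamilyMatrix(hits[0, ], genomes = "G1")
  expect_true(all(countsTotal(m0) == 0))
  expect_equal(nrow(m0), nrow(uptakeFamilyShortlist()))
})

test_that("Bray-Curtis matches the closed form and its bounds", {
  expect_equal(brayCurtisMatrix(rbind(a = c(1, 1), b = c(1, 1)))["a", "b"], 0)
  expect_equal(brayCurtisMatrix(rbind(a = c(2, 0), b = c(0, 2)))["a", "b"], 1)
  expect_equal(brayCurtisMatrix(rbind(a = c(1, 0), b = c(1, 1)))["a", "b"],
               1 / 3)
  expect_warning(
    d0 <- brayCurtisMatrix(rbind(a = c(0, 0), b = c(0, 0), c = c(1, 1))),
    "all-zero")
  expect_equal(d0["a", "b"], 0)
  set.seed(14)
  for (i in 1:10) {
    m <- matrix(rpois(40, 3), nrow = 5)
    d <- brayCurtisMatrix(m)
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_equal(d[1, 2], brayOracle(m[1, ], m[2, ]))
  }
})

test_that("NMDS embeds planar-realizable distances near-perfectly and is deterministic", {
  pts <- rbind(a = c(0, 0), b = c(3, 0), c = c(0, 4), d = c(3, 4))
  d <- as.matrix(dist(pts))
  o1 <- nmdsOrdinate(d, restarts = 20, seed = 42)
  expect_lt(ordinationStress(o1), 1e-3)
  expect_equal(colMeans(ordinationScores(o1)), c(NMDS1 = 0, NMDS2 = 0),
               tolerance = 1e-8)
  o2 <- nmdsOrdinate(d, restarts = 20, seed = 42)
  expect_identical(ordinationScores(o1), ordinationScores(o2))
  # duplicated genomes coincide
  d2 <- as.matrix(dist(rbind(pts, a2 = c(0, 0))))
  o3 <- nmdsOrdinate(d2, restarts = 20, seed = 1)
  sc <- ordinationScores(o3)
  expect_equal(sc["a", ], sc["a2", ], tolerance = 1e-3)
  expect_error(nmdsOrdinate(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})
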