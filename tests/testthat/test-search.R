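test_that("reads back-translated from a panel member recruit at 100% identity", {
  ps <- tinyPanelSet()
  pep <- as.character(panelSequences(panels(ps)$rubisco))[[1]]
  cds <- naiveBackTranslate(pep)  # 129 nt
  # tile the CDS in 60-nt windows, forward and reverse-complement
  starts <- seq(1, nchar(cds) - 59, by = 15)
  fwd <- substring(cds, starts, starts + 59)
  reads <- c(fwd, vapply(fwd, revcompChr, character(1)))
  lib <- ReadLibrary(setNames(reads, paste0("r", seq_along(reads))))
  hits <- searchReads(lib, ps, minScore = 60)
  best <- filterBestHits(hits)
  expect_equal(sort(unique(best$read_id)), sort(names(readSequences(lib))))
  expect_true(all(best$panel_id == "rubisco"))
  expect_true(all(best$percent_identity == 100))
  expect_true(all(best$evalue < 1e-5))
})

test_that("random reads yield no hits against an unrelated panel", {
  set.seed(99)
  reads <- vapply(1:500, function(i)
    paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = ""),
    character(1))
  lib <- ReadLibrary(setNames(reads, paste0("r", 1:500)))
  hits <- searchReads(lib, tinyPanelSet())
  expect_equal(nrow(hits), 0L)
})

test_that("a read and its reverse complement get identical best scores", {
  ps <- tinyPanelSet()
  pep <- as.character(panelSequences(panels(ps)$gltA))[[1]]
  cds <- naiveBackTranslate(pep)
  read <- substr(cds, 10, 90)
  lib <- ReadLibrary(c(fwd = read, rev = revcompChr(read)))
  best <- filterBestHits(searchReads(lib, ps, minScore = 50))
  expect_equal(nrow(best), 2L)
  expect_equal(best$score[best$read_id == "fwd"],
               best$score[best$read_id == "rev"])
  expect_equal(best$subject_id[1], best$subject_id[2])
})

test_that("empty libraries and invalid panel sets are handled", {
  ps <- tinyPanelSet()
  expect_equal(nrow(searchReads(ReadLibrary(character(0)), ps)), 0L)
  noRef <- PanelSet(ProteinPanel("t", "target", c(a = "MKVAW")))
  expect_error(searchReads(ReadLibrary(c(r1 = "ACGT")), noRef),
               "invalid panel set")
})

test_that("tabular hits are parsed with subject coverage recomputed", {
  ps <- PanelSet(
    ProteinPanel("p", "target", c(P1 = strrep("M", 33)), "1.1.1.1"),
    ProteinPanel("r", "reference", c(R1 = strrep("K", 50))))
  f <- tempfile()
  writeLines(m8Line("r1", "P1", pident = 97, length = 33, qstart = 1,
                    qend = 99, sstart = 1, send = 33, evalue = 1e-10,
                    bitscore = 70), f)
  h <- parseTabularHits(f, ps)
  expect_equal(h$subject_cov, 100)  # (33 - 1 + 1) / 33
  expect_equal(h$panel_id, "p")

  file.create(f2 <- tempfile())
  expect_equal(nrow(parseTabularHits(f2, ps)), 0L)

  writeLines(c(m8Line("r1", "P1"), m8Line("r2", "UNKNOWN")), f)
  expect_message(h <- parseTabularHits(f, ps), "1 row")
  expect_equal(nrow(h), 1L)
  expect_equal(attr(h, "n_dropped"), 1L)
  expect_error(parseTabularHits(f, ps, strict = TRUE), "line 2")

  writeLines("r1\tP1\tonly-three-columns", f)
  expect_error(parseTabularHits(f, ps), "line 1")
})

test_that("best-hit filtering applies strict thresholds and the max rule", {
  hits <- rbind(
    mkHit("r1", "A", score = 70),
    mkHit("r1", "B", score = 50),
    mkHit("r2", "A", evalue = 1e-4),             # fails E < 1e-5
    mkHit("r3", "A", percent_identity = 30),     # fails identity > 30
    mkHit("r4", "A", subject_cov = 70),          # fails cov > 70 when asked
    mkHit("r5", "B", score = 60),
    mkHit("r5", "A", score = 60))                # tie -> subject A
  out <- filterBestHits(hits, evalueMax = 1e-5, minIdentity = 30,
                        minSubjectCov = 70)
  expect_equal(out$subject_id[out$read_id == "r1"], "A")
  expect_false("r2" %in% out$read_id)
  expect_false("r3" %in% out$read_id)
  expect_false("r4" %in% out$read_id)
  expect_equal(out$subject_id[out$read_id == "r5"], "A")
  expect_equal(anyDuplicated(out$read_id), 0L)

  # invariant to input order
  perm <- hits[sample(nrow(hits)), ]
  out2 <- filterBestHits(perm, evalueMax = 1e-5, minIdentity = 30,
                         minSubjectCov = 70)
  expect_equal(out2[order(out2$read_id), ], out[order(out$read_id), ],
               ignore_attr = TRUE)
})
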