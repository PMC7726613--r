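test_that("sample assignment is exact-match only", {
  bc <- c(S1 = "ACGTACGT", S7 = "TTTTCCCC")
  expect_equal(assignSample("TTTTCCCCAAAA", bc), "S7")
  expect_equal(assignSample("TTTTCCCGAAAA", bc), "UNASSIGNED")  # Hamming 1
  expect_equal(assignSample("TTTT", bc), "UNASSIGNED")          # too short
  expect_equal(assignSample(c("ACGTACGTA", "GGGGGGGGG"), bc),
               c("S1", "UNASSIGNED"))
})

test_that("locus identification anchors at the read start, longest wins", {
  primers <- c(locA = "ACGTACGTACGTACGTAC",            # 18 nt
               locB = "ACGTACGTACGTACGTACGTAC",        # locA is its prefix
               locC = "GGGGCCCCGGGGCCCCGGGG")
  read <- paste0(primers[["locB"]], "AAAA")
  expect_equal(identifyLocus(read, primers), "locB")
  expect_equal(identifyLocus(paste0(primers[["locA"]], "TTTT"), primers),
               "locA")
  expect_equal(identifyLocus("TTTTTTTTTTTTTTTTTTTTTTTT", primers), "UNKNOWN")
  ## not anchored: a primer somewhere inside the read does not count
  expect_equal(identifyLocus(paste0("T", primers[["locC"]]), primers),
               "UNKNOWN")
  expect_error(identifyLocus("A", c(x = "ACGT")), "18-27")
})

test_that("pair merging honours the 12-base overlap floor", {
  set.seed(42)
  left <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  ov12 <- "ACGTTGCACGTA"
  right <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  r1 <- paste0(left, ov12)
  r2 <- rcOracle(paste0(ov12, right))
  m <- mergePairs(r1, r2)
  expect_equal(nchar(m), nchar(r1) + nchar(r2) - 12L)
  expect_equal(m, paste0(left, ov12, right))
  ## 11-base overlap fails
  r1b <- paste0(left, substr(ov12, 1, 11))
  r2b <- rcOracle(paste0(substr(ov12, 1, 11), right))
  expect_true(is.na(mergePairs(r1b, r2b)))
  ## full-overlap identity: read2 = revcomp(read1) merges to read1
  expect_equal(mergePairs(r1, rcOracle(r1)), r1)
})

test_that("consensus takes the higher-quality base at overlap mismatches", {
  r1 <- "AAAACCCCGGGGTTTT"
  r2rc <- "AAAACCCCGGGGTTTT"
  substr(r2rc, 5, 5) <- "G"                 # disagree at position 5
  r2 <- rcOracle(r2rc)
  hiQ2 <- mergePairs(r1, r2, qual1 = strrep("#", 16), qual2 = strrep("I", 16))
  expect_equal(substr(hiQ2, 5, 5), "G")
  hiQ1 <- mergePairs(r1, r2, qual1 = strrep("I", 16), qual2 = strrep("#", 16))
  expect_equal(substr(hiQ1, 5, 5), "C")
  ## quality tie goes to read 1
  tie <- mergePairs(r1, r2, qual1 = strrep("I", 16), qual2 = strrep("I", 16))
  expect_equal(substr(tie, 5, 5), "C")
})

test_that("merging equals the brute-force offset scan on toy reads", {
  set.seed(7)
  for (case in 1:150) {
    L1 <- sample(12:30, 1); L2 <- sample(12:30, 1)
    r1 <- paste(sample(c("A", "C", "G", "T"), L1, TRUE), collapse = "")
    r2 <- paste(sample(c("A", "C", "G", "T"), L2, TRUE), collapse = "")
    ## half the cases share a planted overlap so merges actually occur
    if (case %% 2 == 0) {
      ov <- sample(12:min(L1, L2), 1)
      r2 <- rcOracle(paste0(substr(r1, L1 - ov + 1L, L1),
                            substr(r2, 1L, L2 - ov)))
    }
    q1 <- paste(sample(c("#", "5", "I"), nchar(r1), TRUE), collapse = "")
    q2 <- paste(sample(c("#", "5", "I"), nchar(r2), TRUE), collapse = "")
    got <- mergePairs(r1, r2, q1, q2, minOverlap = 12, maxMismatchFrac = 0.25)
    want <- bruteMerge(r1, q1, r2, q2, 12L, 0.25)
    expect_identical(got, want)
  }
})

test_that("primer trimming follows the two-primer / 50-bp rules", {
  fwd <- "ACGTACGTACGTACGTACGT"          # 20 nt
  rev <- "TTGGTTGGTTGGTTGGTTGG"
  insert <- strrep("CA", 60)             # 120 bp
  full <- paste0(fwd, insert, rcOracle(rev))
  expect_equal(trimAmplicon(full, fwd, rev, expectedLen = 160), insert)
  ## reverse primer missing, short-amplicon locus: 50 bp off the 5' end
  noRev <- paste0(fwd, insert)
  expect_equal(trimAmplicon(noRev, fwd, rev, expectedLen = 250),
               substr(insert, 51, 120))
  ## reverse primer missing, long-amplicon locus: left untrimmed
  expect_equal(trimAmplicon(noRev, fwd, rev, expectedLen = 350), insert)
  ## forward primer absent: unroutable
  expect_true(is.na(trimAmplicon(insert, fwd, rev, expectedLen = 160)))
})

test_that("the length filter keeps only sequences longer than 90 bp", {
  expect_true(lengthFilter(strrep("A", 91)))
  expect_false(lengthFilter(strrep("A", 90)))
  expect_false(lengthFilter(""))
  expect_equal(lengthFilter(c(strrep("A", 95), NA, strrep("A", 10))),
               c(TRUE, FALSE, FALSE))
})

test_that("routing conserves every read pair and recovers truth", {
  truth <- simulateCohort(8, nSites = 2, siteEffectSize = 0, seed = 21)
  ids <- truthTable(truth)$sample_id
  panel <- buildPanel(nBarcodes = length(ids), sampleIds = ids, seed = 21)
  cfg <- runConfig(depth = c(bact16S = 80, kdr = 60, S200X6.1 = 60,
                             cox1 = 60, mamm16S = 60, parasite = 40),
                   dispersion = 0, errorRate = 0, contaminationRate = 0,
                   seed = 21)
  d <- withr::local_tempdir()
  paths <- emitRun(truth, panel, cfg, d)
  ## append junk pairs: unknown barcode, and known barcode + junk primer
  bc <- panelBarcodes(panel)
  junk1 <- c(strrep("N", 100), paste0(bc[[1]], strrep("T", 92)))
  cat(sprintf("@junk_%d\n%s\n+\n%s\n", seq_along(junk1), junk1,
              strrep("I", nchar(junk1))),
      file = paths$fastq1, append = TRUE, sep = "")
  cat(sprintf("@junk_%d\n%s\n+\n%s\n", seq_along(junk1),
              rev(junk1), strrep("I", nchar(rev(junk1)))),
      file = paths$fastq2, append = TRUE, sep = "")
  routed <- demuxRun(paths$fastq1, paths$fastq2, panel)
  expect_equal(sum(routed@summary$n), routed@nPairs)
  tally <- setNames(routed@summary$n, routed@summary$disposition)
  expect_equal(unname(tally["unassigned-barcode"]), 1L)
  expect_equal(unname(tally["unknown-locus"]), 1L)
  ## error-free reads all land on their true sample and locus
  derep <- dereplicate(routed, "kdr")
  tt <- truthTable(truth)
  expect_setequal(colnames(derep), tt$sample_id)
  expect_equal(unname(colSums(seqCounts(derep))), rep(60, 8))
})
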