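panel <- buildPanel(nBarcodes = 4, seed = 1)
kdrIns <- AmpliScreen:::referenceInserts(panel, "kdr")
resAllele <- unname(kdrIns[["kdr_L1014F"]])
wtAllele <- unname(kdrIns[["kdr_L1014L"]])

kdrTable <- function(...) {
  cols <- list(...)
  seqs <- unique(unlist(lapply(cols, names)))
  counts <- vapply(cols, function(x) {
    v <- integer(length(seqs)); names(v) <- seqs
    v[names(x)] <- as.integer(x); v
  }, integer(length(seqs)))
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = length(cols),
                                             dimnames = list(seqs, names(cols)))
  toySeqTable(as.matrix(counts), seqs, locus = "kdr")
}

test_that("kdr ratio cut-offs drive the genotype call", {
  err <- sub("A", "C", resAllele)  # an error variant of the resistant allele
  tab <- kdrTable(
    S_rr = setNames(c(990L, 10L), c(resAllele, err)),       # ratio 0.01
    S_rs = setNames(c(520L, 480L), c(resAllele, wtAllele)), # ratio 0.48
    S_nc = setNames(c(700L, 300L), c(resAllele, wtAllele)), # ratio 0.30
    S_ss = setNames(c(1200L, 40L), c(wtAllele, err)),
    S_low = setNames(c(600L, 300L), c(resAllele, wtAllele)))
  calls <- callKdr(tab, panel)
  byId <- setNames(calls$call, calls$sample_id)
  expect_equal(unname(byId[c("S_rr", "S_rs", "S_nc", "S_ss", "S_low")]),
               c("RR", "RS", "NO_CALL", "SS", "NO_CALL"))
  reasons <- setNames(calls$reason, calls$sample_id)
  expect_equal(unname(reasons["S_nc"]), "ambiguous_ratio")
  expect_equal(unname(reasons["S_low"]), "low_depth")
  expect_equal(calls$ratio[calls$sample_id == "S_rs"], 0.48)
  ## ratio stays in [0, 0.5]: Seq1 is always the more abundant sequence
  expect_true(all(calls$ratio <= 0.5 & calls$ratio >= 0, na.rm = TRUE))
})

test_that("kdr calling is scale invariant and handles single alleles", {
  tab1 <- kdrTable(S = setNames(c(900L, 150L), c(resAllele, wtAllele)))
  tab7 <- kdrTable(S = setNames(7L * c(900L, 150L), c(resAllele, wtAllele)))
  expect_equal(callKdr(tab1, panel)$call, callKdr(tab7, panel)$call)
  ## a single unique sequence gives ratio 0 and a homozygous call
  solo <- kdrTable(S = setNames(1500L, wtAllele))
  call <- callKdr(solo, panel)
  expect_equal(call$ratio, 0)
  expect_equal(call$call, "SS")
  ## count ties break lexicographically by sequence
  tie <- kdrTable(S = setNames(c(800L, 800L), sort(c(resAllele, wtAllele))))
  ct <- callKdr(tie, panel)
  expect_equal(ct$seq1, sort(c(resAllele, wtAllele))[1])
  expect_equal(ct$call, "RS")
})

test_that("reference matching applies the 70% identity floor", {
  set.seed(5)
  refA <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  refs <- c(refA = refA)
  expect_equal(matchReference(refA, refs)$identity, 100)
  ## substitute k of 100 positions (cyclic base shift, never a match)
  substituted <- function(k) {
    q <- strsplit(refA, "")[[1]]
    pos <- sample(100, k)
    for (p in pos) q[p] <- chartr("ACGT", "CGTA", q[p])
    paste(q, collapse = "")
  }
  q69 <- substituted(31)    # 69% identical: below the floor, suppressed
  expect_equal(matchReference(q69, refs, minIdentity = 0)$identity, 69)
  expect_equal(nrow(matchReference(q69, refs)), 0L)
  q70 <- substituted(30)    # 70% identical: reported
  expect_equal(nrow(matchReference(q70, refs)), 1L)
  ## exact ties are all returned
  two <- c(r1 = strrep("AC", 30), r2 = strrep("AC", 30))
  hits <- matchReference(strrep("AC", 30), two)
  expect_equal(nrow(hits), 2L)
  ## short queries return no call with a reason
  short <- matchReference("ACGTACGT", refs)
  expect_equal(nrow(short), 0L)
  expect_equal(attr(short, "reason"), "query_too_short")
})

test_that("matched identity equals the dynamic-programming oracle on toys", {
  set.seed(31)
  base <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  cases <- list(
    identical = base,
    subs2 = local({ x <- base
      substr(x, 5, 5) <- "N"; substr(x, 5, 5) <- ifelse(substr(base, 5, 5) == "A", "C", "A")
      substr(x, 20, 20) <- ifelse(substr(base, 20, 20) == "G", "T", "G"); x }),
    del1 = paste0(substr(base, 1, 9), substr(base, 11, 40)),
    prefix = substr(base, 1, 30))
  for (nm in names(cases)) {
    got <- matchReference(cases[[nm]], c(ref = base), minIdentity = 0)
    expect_equal(got$identity, dpIdentity(cases[[nm]], base),
                 tolerance = 1e-9, label = nm)
  }
})

test_that("species calls use S200X6.1 first, cox1 as rescue", {
  s200Ins <- AmpliScreen:::referenceInserts(panel, "S200X6.1")
  cox1Ins <- AmpliScreen:::referenceInserts(panel, "cox1")
  s200 <- toySeqTable(cbind(
    gamb = c(2917L, 0L, 0L), hyb = c(550L, 450L, 0L), low = c(0L, 0L, 400L)),
    unname(s200Ins[c("Anopheles_gambiae", "Anopheles_coluzzii",
                     "Anopheles_melas")]), locus = "S200X6.1")
  cox1 <- toySeqTable(cbind(gamb = 0L, hyb = 0L, low = 1300L),
                      unname(cox1Ins["Anopheles_nili"]), locus = "cox1")
  calls <- callSpecies(s200, cox1, panel)
  byId <- setNames(calls$species, calls$sample_id)
  expect_equal(unname(byId["gamb"]), "Anopheles_gambiae")
  expect_equal(unname(byId["hyb"]),
               "Anopheles_coluzzii x Anopheles_gambiae")
  expect_true(calls$hybrid[calls$sample_id == "hyb"])
  expect_equal(unname(byId["low"]), "Anopheles_nili")
  expect_equal(calls$evidence_locus[calls$sample_id == "low"], "cox1")
  ## both loci under depth: no call
  under <- callSpecies(
    toySeqTable(cbind(S = 900L), unname(s200Ins[1]), locus = "S200X6.1"),
    toySeqTable(cbind(S = 900L), unname(cox1Ins[1]), locus = "cox1"), panel)
  expect_equal(under$species, "NO_CALL")
  expect_equal(under$reason, "low_depth")
})

test_that("blood-meal profiles apply the 1000-read fed floor", {
  ins <- AmpliScreen:::referenceInserts(panel, "mamm16S")
  tab <- toySeqTable(cbind(
    unfed = c(999L, 0L), multi = c(800L, 600L), none = c(0L, 0L)),
    unname(ins[c("Homo_sapiens", "Bos_indicus")]), locus = "mamm16S")
  bm <- callBloodMeal(tab, panel)
  expect_false(any(bm$fed[bm$sample_id == "unfed"]))
  multi <- bm[bm$sample_id == "multi", ]
  expect_true(all(multi$fed))
  expect_setequal(multi$host, c("Homo_sapiens", "Bos_indicus"))
  expect_equal(sort(multi$reads), c(600L, 800L))
  ## a sample absent from the table does not appear; zero-read columns are
  ## dropped at dereplication so "none" is treated as unfed upstream
  expect_false("none" %in% bm$sample_id[bm$fed])
})

test_that("infection detection reports best hits, controls and leakage", {
  ins <- AmpliScreen:::referenceInserts(panel, "parasite")
  junk <- paste(rep("A", 170), collapse = "")
  tab <- toySeqTable(cbind(
    m1 = c(1876L, 0L, 0L), m2 = c(40L, 5000L, 30L), c1 = c(54L, 0L, 0L)),
    c(unname(ins[c("Plasmodium_falciparum", "Theileria_sp")]), junk),
    locus = "parasite")
  det <- detectInfections(tab, panel, controlIds = "c1")
  ## nothing reaches 70% for the junk sequence
  expect_false(any(grepl("junk", det$species)))
  expect_true(all(det$identity >= 70))
  expect_true(det$control[det$sample_id == "c1"])
  flagged <- flagContamination(det, ratioThreshold = 2)
  pick <- function(s, sp) flagged$possible_contamination[
    flagged$sample_id == s & flagged$species == sp]
  expect_true(pick("m2", "Plasmodium_falciparum"))    # 40 < 2 * 54
  expect_false(pick("m2", "Theileria_sp"))            # 5000, no control hit
  expect_false(pick("m1", "Plasmodium_falciparum"))   # 1876 >= 2 * 54
  ## with no control detections nothing is annotated
  noCtrl <- flagContamination(det[!det$control, ])
  expect_false(any(noCtrl$possible_contamination))
})
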