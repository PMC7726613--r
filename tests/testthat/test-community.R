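mkAsv <- function(counts, taxonomy = NULL, site = NULL) {
  tab <- toySeqTable(counts, rownames(counts), locus = "bact16S")
  ord <- match(SummarizedExperiment::rowData(tab)$sequence, rownames(counts))
  md <- data.frame(sample_id = colnames(counts),
                   site = site %||% rep("site_1", ncol(counts)))
  buildAsvTable(tab, md, minDepth = 0,
                taxonomy = if (!is.null(taxonomy)) taxonomy[ord])
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the ASV table enforces depth floor and metadata coverage", {
  counts <- cbind(S1 = c(4999L, 0L), S2 = c(4000L, 1000L), S3 = c(0L, 5200L))
  rownames(counts) <- c(strrep("AC", 20), strrep("GT", 20))
  tab <- toySeqTable(counts, rownames(counts), locus = "bact16S")
  md <- data.frame(sample_id = c("S1", "S2", "S3"), site = "x")
  asv <- buildAsvTable(tab, md)
  expect_setequal(colnames(asv), c("S2", "S3"))      # 4999 is excluded
  expect_error(buildAsvTable(tab, md[md$sample_id != "S3", ]), "S3")
  expect_error(buildAsvTable(tab, md, minDepth = 6000), "floor")
  ## taxonomy is optional
  expect_true(is.null(SummarizedExperiment::rowData(asv)$taxonomy))
})

test_that("relative abundance pools ranks under the 1% threshold", {
  counts <- rbind(A1 = c(989L, 990L), A2 = c(6L, 5L), A3 = c(5L, 5L))
  colnames(counts) <- c("S1", "S2")
  tax <- c("Bacteria;PhylumBig;c;o;f;g", "Bacteria;PhylumTiny1;c;o;f;g",
           "Bacteria;PhylumTiny2;c;o;f;g")
  asv <- mkAsv(counts, taxonomy = tax)
  ra <- relativeAbundance(asv, rank = "phylum")
  expect_equal(colSums(ra), c(site_1 = 1), tolerance = 1e-9)
  expect_true("<1% abund." %in% rownames(ra))        # 0.5-0.6% each, pooled
  expect_false(any(grepl("Tiny", rownames(ra))))
  ## a single phylum has proportion 1
  one <- mkAsv(rbind(A1 = c(S1 = 10L, S2 = 20L)),
               taxonomy = "Bacteria;OnlyPhylum;c;o;f;g")
  expect_equal(unname(relativeAbundance(one)[1, 1]), 1)
  expect_error(relativeAbundance(asv, rank = "kingdomm"), "unknown rank")
})

test_that("Bray-Curtis matches the closed form", {
  m <- rbind(S1 = c(2, 1, 0), S2 = c(0, 1, 3), S3 = c(2, 1, 0))
  d <- as.matrix(brayCurtis(m))
  expect_equal(d["S1", "S2"], 5 / 7)      # 1 - 2*1/7
  expect_equal(d["S1", "S3"], 0)          # identical vectors
  expect_equal(d["S1", "S1"], 0)
  disjoint <- rbind(S1 = c(5, 0), S2 = c(0, 9))
  expect_equal(as.vector(brayCurtis(disjoint)), 1)
  expect_error(brayCurtis(rbind(S1 = c(1, 0), S2 = c(0, 0))), "zero-sum")
})

test_that("weighted UniFrac collapses correctly on a star tree", {
  star <- ape::read.tree(text = "(t1:1,t2:1,t3:1):0;")
  m <- rbind(S1 = c(t1 = 8, t2 = 2, t3 = 0), S2 = c(t1 = 2, t2 = 2, t3 = 6))
  d <- as.matrix(weightedUnifrac(m, star))
  pA <- m["S1", ] / 10; pB <- m["S2", ] / 10
  expect_equal(d["S1", "S2"], sum(abs(pA - pB)))
  expect_equal(d["S1", "S1"], 0)
  ## identical profiles at any scale are at distance zero
  m2 <- rbind(S1 = c(t1 = 10, t2 = 10, t3 = 0),
              S2 = c(t1 = 3, t2 = 3, t3 = 0))
  expect_equal(as.vector(weightedUnifrac(m2, star)), 0)
  expect_error(weightedUnifrac(
    rbind(S1 = c(tX = 1, t2 = 1), S2 = c(tX = 1, t2 = 2)), star), "tX")
})

test_that("weighted UniFrac equals a clade-membership oracle and phyloseq", {
  set.seed(91)
  tree <- ape::rcoal(12, tip.label = sprintf("t%02d", 1:12))
  m <- matrix(rpois(4 * 12, 20), 4, 12,
              dimnames = list(sprintf("S%d", 1:4), tree$tip.label))
  d <- as.matrix(weightedUnifrac(m, tree))
  ## oracle: per edge, collect descendant leaves independently via the
  ## subtree extraction utilities, then sum length * |pA - pB|
  prop <- m / rowSums(m)
  oracle <- function(a, b) {
    tot <- 0
    for (e in seq_len(nrow(tree$edge))) {
      node <- tree$edge[e, 2]
      leaves <- if (node <= length(tree$tip.label)) tree$tip.label[node]
                else ape::extract.clade(tree, node)$tip.label
      tot <- tot + tree$edge.length[e] *
        abs(sum(prop[a, leaves]) - sum(prop[b, leaves]))
    }
    tot
  }
  for (pair in list(c(1, 2), c(1, 4), c(2, 3)))
    expect_equal(d[pair[1], pair[2]], oracle(pair[1], pair[2]),
                 tolerance = 1e-12)
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(t(m), taxa_are_rows = TRUE),
    phyloseq::phy_tree(tree))
  expect_equal(as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                           normalized = FALSE)),
               d, tolerance = 1e-12)
  ## normalized variant is bounded by 1
  dn <- as.matrix(weightedUnifrac(m, tree, normalized = TRUE))
  expect_true(all(dn >= 0 & dn <= 1))
})

test_that("PCoA recovers geometry from distances", {
  ## two points at distance d: one axis at +-d/2 carrying 100% variance
  two <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ord <- pcoaOrdination(two)
  expect_equal(sort(ord$points[, 1]), c(-1.5, 1.5), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(ord$varExplained[1], 1)
  ## Euclidean round trip: embedded coordinates reproduce the distances
  set.seed(17)
  pts <- matrix(rnorm(20), 10, 2)
  d <- dist(pts)
  ord2 <- pcoaOrdination(d)
  expect_equal(as.matrix(dist(ord2$points)), as.matrix(d),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sum(ord2$varExplained), 1, tolerance = 1e-9)
  ## an all-zero dissimilarity yields all-zero coordinates
  z <- matrix(0, 3, 3)
  ordz <- pcoaOrdination(z)
  expect_true(all(ordz$points == 0))
  expect_error(pcoaOrdination(matrix(0, 1, 1)), "at least 2")
})
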