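test_that("a perfectly separating factor captures all the variance", {
  ## 2 groups of 2: within-group distance 0, between-group 1
  D <- matrix(1, 4, 4) - diag(4)
  D[1, 2] <- D[2, 1] <- 0
  D[3, 4] <- D[4, 3] <- 0
  md <- data.frame(g = c("a", "a", "b", "b"))
  res <- permanova(D, md, "g", nPerm = 0L)
  tab <- permanovaTable(res)
  expect_equal(res@ssTotal, 1)            # (1/n) * sum_{i<j} d_ij^2 = 4/4
  expect_equal(tab["g", "SumOfSqs"], 1)
  expect_equal(tab["g", "R2"], 1)
  expect_equal(tab["Residual", "SumOfSqs"], 0, tolerance = 1e-12)
})

test_that("degenerate factors get zero df and an NA p-value", {
  set.seed(3)
  D <- as.matrix(dist(rnorm(8)))
  md <- data.frame(flat = rep("only", 8), g = rep(c("a", "b"), 4))
  tab <- permanovaTable(permanova(D, md, c("flat", "g"), nPerm = 49))
  expect_equal(tab["flat", "Df"], 0)
  expect_equal(tab["flat", "SumOfSqs"], 0, tolerance = 1e-12)
  expect_true(is.na(tab["flat", "Pr"]))
  expect_false(is.na(tab["g", "Pr"]))
  ## a factor collinear with an earlier one adds nothing
  md$copy <- md$g
  tab2 <- permanovaTable(permanova(D, md, c("g", "copy"), nPerm = 0))
  expect_equal(tab2["copy", "Df"], 0)
  expect_equal(tab2["copy", "SumOfSqs"], 0, tolerance = 1e-12)
})

test_that("sequential partition agrees with vegan::adonis2 by terms", {
  set.seed(23)
  n <- 30
  md <- data.frame(
    site = sample(c("u", "v", "w"), n, TRUE),
    species = sample(c("x", "y"), n, TRUE),
    fed = sample(c(TRUE, FALSE), n, TRUE))
  m <- matrix(rpois(n * 15, 10 + 5 * as.integer(factor(md$site))), n, 15)
  rownames(m) <- sprintf("S%02d", 1:n)
  md$sample_id <- rownames(m)
  d <- brayCurtis(m)
  mine <- permanovaTable(permanova(d, md, c("site", "species", "fed"),
                                   nPerm = 999, seed = 4))
  ref <- vegan::adonis2(d ~ site + species + fed, data = md,
                        permutations = 999, by = "terms")
  for (term in c("site", "species", "fed")) {
    expect_equal(mine[term, "SumOfSqs"], ref[term, "SumOfSqs"],
                 tolerance = 1e-9)
    expect_equal(mine[term, "R2"], ref[term, "R2"], tolerance = 1e-9)
    expect_equal(mine[term, "F"], ref[term, "F"], tolerance = 1e-9)
  }
  expect_equal(mine["Residual", "SumOfSqs"], ref["Residual", "SumOfSqs"],
               tolerance = 1e-9)
  ## permutation p-values agree up to Monte-Carlo error
  expect_lt(abs(mine["site", "Pr"] - ref["site", "Pr(>F)"]), 0.05)
})

test_that("additivity holds for every term ordering", {
  set.seed(5)
  n <- 24
  md <- data.frame(a = sample(letters[1:3], n, TRUE),
                   b = sample(letters[4:5], n, TRUE),
                   c = sample(letters[6:8], n, TRUE))
  D <- as.matrix(dist(matrix(rnorm(n * 3), n)))
  ords <- list(c("a", "b", "c"), c("c", "a", "b"), c("b", "c", "a"))
  ssT <- NULL
  for (o in ords) {
    res <- permanova(D, md, o, nPerm = 0)
    tab <- permanovaTable(res)
    expect_equal(sum(tab$SumOfSqs), res@ssTotal, tolerance = 1e-9)
    expect_equal(sum(tab$R2), 1, tolerance = 1e-9)
    ssT <- c(ssT, res@ssTotal)
  }
  expect_equal(max(ssT) - min(ssT), 0, tolerance = 1e-12)
  ## the leading term's R2 does not depend on the terms after it
  r2_first <- vapply(list(c("a", "b", "c"), c("a", "c", "b")), function(o)
    permanovaTable(permanova(D, md, o, nPerm = 0))["a", "R2"], numeric(1))
  expect_equal(r2_first[1], r2_first[2], tolerance = 1e-12)
})

test_that("sampled permutation p matches exhaustive enumeration for small n", {
  set.seed(61)
  n <- 6
  D <- as.matrix(dist(c(0.1, 0.3, 0.2, 1.4, 1.1, 1.8)))
  md <- data.frame(g = rep(c("a", "b"), each = 3))
  res <- permanovaTable(permanova(D, md, "g", nPerm = 999, seed = 8))
  ## exhaustive oracle over all 720 label permutations
  Fstat <- function(perm) {
    Dp <- D[perm, perm]
    tab <- permanovaTable(permanova(Dp, md, "g", nPerm = 0))
    tab["g", "F"]
  }
  Fobs <- Fstat(seq_len(n))
  perms <- allPermutations(n)
  Fall <- apply(perms, 1, Fstat)
  pExact <- mean(Fall >= Fobs - 1e-12)
  ## Monte-Carlo tolerance: ~3 binomial standard errors at 999 draws
  tol <- 3 * sqrt(pExact * (1 - pExact) / 999) + 2 / 999
  expect_lt(abs(res["g", "Pr"] - pExact), tol)
  ## determinism of the permutation stream
  res2 <- permanovaTable(permanova(D, md, "g", nPerm = 999, seed = 8))
  expect_identical(res["g", "Pr"], res2["g", "Pr"])
  ## p cannot fall below the add-one floor
  expect_gte(res["g", "Pr"], 1 / 1000)
})

test_that("metadata alignment and validation are enforced", {
  D <- as.matrix(dist(1:5))
  rownames(D) <- colnames(D) <- sprintf("S%d", 1:5)
  md <- data.frame(sample_id = sprintf("S%d", 5:1),
                   g = c("a", "a", "b", "b", "b"))
  res <- permanovaTable(permanova(D, md, "g", nPerm = 0))
  ## matched by sample_id: S5..S1 order in metadata must not matter
  md2 <- md[5:1, ]
  res2 <- permanovaTable(permanova(D, md2, "g", nPerm = 0))
  expect_equal(res["g", "SumOfSqs"], res2["g", "SumOfSqs"])
  expect_error(permanova(D, md[1:4, ], "g"), "missing")
  expect_error(permanova(D, md, "nope"), "unknown factor")
  mdNA <- md; mdNA$g[2] <- NA
  expect_error(permanova(D, mdNA, "g"), "undefined")
})
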