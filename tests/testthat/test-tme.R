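# Signature scoring, ssGSEA (against a brute-force oracle), preranked GSEA,
# genome-alteration burden and TMB.

test_that("geomeanScore reproduces hand values and respects scale handling", {
  expr <- mkMat(c(2, 8, 8, 2), c("a", "b"), c("s1", "s2"))
  expect_equal(unname(geomeanScore(expr, c("a", "b"), pseudocount = 0,
                                   scaleTag = "linear")), c(4, 4))
  # all genes equal c -> score c
  exprC <- mkMat(rep(5, 4), c("a", "b"), c("s1", "s2"))
  expect_equal(unname(geomeanScore(exprC, c("a", "b"), pseudocount = 0,
                                   scaleTag = "linear")), c(5, 5))
  # zero value with pseudocount 1 stays finite
  expr0 <- mkMat(c(0, 8, 1, 3), c("a", "b"), c("s1", "s2"))
  s <- geomeanScore(expr0, c("a", "b"), scaleTag = "linear")
  expect_true(all(is.finite(s)))
  # log2-tagged input back-transforms: log2 values {1, 3} = linear {2, 8} with pc 0
  exprL <- mkMat(c(1, 3), c("a", "b"), "s1")
  expect_equal(unname(geomeanScore(exprL, c("a", "b"), pseudocount = 0,
                                   scaleTag = "log2")),
               sqrt((2^1 - 1) * (2^3 - 1)))
  expect_error(geomeanScore(expr, c("x", "y"), scaleTag = "linear"),
               "no signature gene")
})

test_that("populationScores average measured markers with set semantics", {
  expr <- mkMat(c(1, 3, 100), c("A", "B", "C"), "s1")
  sets <- new("SignatureSet",
              signatures = list(pop1 = c("A", "B"),
                                pop2 = c("A", "B", "unmeasured"),
                                pop3 = c("A", "A", "B"),
                                popEmpty = "missing"))
  expect_warning(sc <- populationScores(expr, sets), "popEmpty")
  expect_equal(unname(sc[1, "pop1"]), 2)
  expect_equal(unname(sc[1, "pop2"]), 2)   # unmeasured marker ignored
  expect_equal(unname(sc[1, "pop3"]), 2)   # duplicate counted once
  expect_false("popEmpty" %in% colnames(sc))
})

test_that("ssgsea matches the brute-force oracle on random profiles", {
  set.seed(10)
  genes <- paste0("g", 1:20)
  maxDiff <- 0
  for (r in 1:100) {
    x <- setNames(rnorm(20), genes)
    members <- sample(genes, 5)
    expr <- matrix(x, 20, 1, dimnames = list(genes, "s1"))
    got <- ssgsea(expr, members, alpha = 0.25)
    want <- ssgseaOracle(x, members, 0.25)
    maxDiff <- max(maxDiff, abs(got - want))
  }
  expect_lt(maxDiff, 1e-10)

  # alpha = 0 reduces to the unweighted ECDF difference
  x <- setNames(rnorm(20), genes)
  members <- genes[c(2, 5, 9)]
  expr <- matrix(x, 20, 1, dimnames = list(genes, "s1"))
  expect_equal(unname(ssgsea(expr, members, alpha = 0)),
               unname(ssgseaOracle(x, members, 0)), tolerance = 1e-12)
})

test_that("ssgsea extremal/degenerate behavior and estimate scores", {
  set.seed(11)
  genes <- paste0("g", 1:30)
  x <- setNames(sort(rnorm(30), decreasing = TRUE), genes)
  expr <- matrix(x, 30, 1, dimnames = list(genes, "s1"))
  topSet <- genes[1:5]  # the top-ranked genes: maximal ES for size 5
  esTop <- ssgsea(expr, topSet)
  for (r in 1:20) {
    other <- sample(genes, 5)
    expect_lte(ssgsea(expr, other), esTop + 1e-12)
  }
  # constant profile -> 0
  exprC <- matrix(1, 30, 1, dimnames = list(genes, "s1"))
  expect_equal(unname(ssgsea(exprC, topSet)), 0)
  # permuting gene (row) order leaves scores unchanged
  perm <- sample(30)
  expect_equal(ssgsea(expr[perm, , drop = FALSE], topSet), ssgsea(expr, topSet))

  # immune-skewed profile scores IES > SES
  imm <- paste0("I", 1:10); str <- paste0("X", 1:10)
  prof <- matrix(c(rnorm(10, 5), rnorm(10, -5), rnorm(10)), 30, 1,
                 dimnames = list(c(imm, str, paste0("bg", 1:10)), "s1"))
  es <- estimateScores(prof, imm, str)
  expect_gt(es$IES, es$SES)
})

test_that("preranked GSEA matches a hand-enumerated running sum and its symmetries", {
  # 10 genes ranked by stat; 2-gene set at known positions
  stats <- setNames(c(5, 4, 3, 2, 1, -1, -2, -3, -4, -5), paste0("g", 1:10))
  members <- c("g1", "g2")
  # hand enumeration: weights |stat|^1, in-set total = 9; out step = 1/8
  run <- cumsum(c(5 / 9, 4 / 9, -1 / 8, -1 / 8, -1 / 8, -1 / 8, -1 / 8,
                  -1 / 8, -1 / 8, -1 / 8))
  esHand <- run[which.max(abs(run))]
  res <- prerankedGsea(stats, list(top = members), nPerm = 100L,
                       minSize = 2L, seed = 1L)
  expect_equal(res$es, esHand, tolerance = 1e-12)
  expect_gt(res$es, 0)
  expect_identical(strsplit(res$leadingEdge, ",")[[1]], c("g1", "g2"))

  # reversing the ranking negates the ES
  resRev <- prerankedGsea(-stats, list(top = members), nPerm = 100L,
                          minSize = 2L, seed = 1L)
  expect_equal(resRev$es, -esHand, tolerance = 1e-12)

  # cross-check the ES sign/magnitude against fgsea on a larger example
  set.seed(12)
  stats2 <- setNames(sort(rnorm(50), decreasing = TRUE), paste0("h", 1:50))
  set2 <- list(s = paste0("h", 1:8))
  mine <- prerankedGsea(stats2, set2, nPerm = 200L, seed = 2L)
  ref <- suppressWarnings(fgsea::fgsea(set2, stats2, nperm = 200))
  expect_equal(mine$es, ref$ES, tolerance = 0.02)

  expect_error(prerankedGsea(setNames(rep(0, 10), paste0("g", 1:10)),
                             list(s = paste0("g", 1:5))), "zero")
  expect_error(suppressMessages(prerankedGsea(stats, list(tiny = "g1"))),
               "size filter")
})

test_that("genome burden matches the 100 Mb toy and FGG + FGL = FGA always", {
  seg <- data.frame(sample = "s1",
                    chromosome = c("chr1", "chr1"),
                    start = c(1, 20000001), end = c(20000000, 100000000),
                    log2ratio = c(0.5, 0.0))
  b <- genomeBurden(seg)
  expect_equal(b$fga, 0.2)
  expect_equal(b$fgg, 0.2)
  expect_equal(b$fgl, 0)

  # boundary: exactly +0.3 counts as gained
  seg$log2ratio <- c(0.3, 0)
  expect_equal(genomeBurden(seg)$fgg, 0.2)
  # all-neutral genome
  seg$log2ratio <- c(0, 0)
  expect_equal(genomeBurden(seg)$fga, 0)

  sim <- smallSim(seed = 15L)
  bb <- genomeBurden(segmentTable(sim$bundle))
  expect_equal(bb$fga, bb$fgg + bb$fgl, tolerance = 1e-12)

  segBad <- data.frame(sample = "s1", chromosome = "chr1",
                       start = c(1, 50), end = c(100, 80), log2ratio = 0)
  expect_error(genomeBurden(segBad), "overlap")
})

test_that("tmb divides non-silent counts by panel size", {
  expect_equal(unname(tmb(c(a = 10), 1)), 10)
  expect_equal(unname(tmb(c(a = 0), 2)), 0)
  expect_equal(unname(tmb(c(a = 35), 3.5)), 10)
  expect_error(tmb(c(a = 1), 0), "panelMb")
})

test_that("external weighted risk scores are linear in the weights", {
  expr <- mkMat(c(1, 2, 3, 4), c("a", "b"), c("s1", "s2"))
  w1 <- c(a = 1, b = 1)
  expect_equal(unname(scoreExternalSignature(expr, w1)),
               unname(colSums(expr)))
  expect_equal(unname(scoreExternalSignature(expr, c(a = 0, b = 0))), c(0, 0))
  expect_equal(scoreExternalSignature(expr, -w1),
               -scoreExternalSignature(expr, w1))
  expect_warning(scoreExternalSignature(expr, c(a = 1, x = 1, y = 1)), "50%")
})

test_that("shipped signature fixtures parse and score a toy cohort", {
  sig <- readGmt(system.file("extdata", "tme_functional_signatures.gmt",
                             package = "MOSubtype"))
  expect_true("immunosuppression" %in% names(geneSets(sig)))
  expect_setequal(geneSets(sig)$immunosuppression,
                  c("CXCL12", "TGFB1", "TGFB3", "LGALS1"))
  ies <- readGmt(system.file("extdata", "ies_ses_synthetic.gmt",
                             package = "MOSubtype"))
  expect_length(geneSets(ies), 2L)

  set.seed(16)
  genes <- unique(c(unlist(geneSets(sig)), unlist(geneSets(ies)),
                    paste0("BG", 1:200)))
  expr <- matrix(abs(rnorm(length(genes) * 4, 5)), length(genes), 4,
                 dimnames = list(genes, paste0("s", 1:4)))
  sc <- populationScores(expr, sig)
  expect_equal(ncol(sc), length(geneSets(sig)))
  est <- estimateScores(expr, geneSets(ies)[[1]], geneSets(ies)[[2]])
  expect_true(all(is.finite(c(est$IES, est$SES))))
})
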