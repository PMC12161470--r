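# Differential expression, templates, NTP, PAM scores, panel, bagging.

test_that("moderated t behaves on null and planted genes and matches limma", {
  set.seed(1)
  n1 <- 30L; n2 <- 60L
  labels <- c(rep("A", n1), rep("B", n2))
  expr <- matrix(rnorm(200 * 90, 0, 0.5), 200, 90,
                 dimnames = list(paste0("g", 1:200),
                                 sprintf("s%02d", 1:90)))
  expr["g1", labels == "A"] <- expr["g1", labels == "A"] + 2  # planted
  expr["g2", ] <- 5                                            # zero variance
  tab <- differentialExpression(expr, labels, "A")

  g1 <- tab[tab$gene == "g1", ]
  expect_gte(g1$log2fc, 1)
  expect_lt(g1$fdr, 0.05)
  g2 <- tab[tab$gene == "g2", ]
  expect_equal(g2$p, 1)
  expect_true(g2$flagged)
  # null genes: log2fc near 0, mostly insignificant
  nulls <- tab[!tab$gene %in% c("g1", "g2"), ]
  expect_lt(max(abs(nulls$log2fc)), 1)

  # independent cross-check of the empirical-Bayes machinery against limma
  design <- cbind(1, labels == "A")
  fit <- limma::eBayes(limma::lmFit(expr, design))
  expect_equal(tab$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-9)
  expect_gt(cor(tab$t[!tab$flagged], fit$t[!tab$flagged, 2]), 0.99)

  expect_error(differentialExpression(expr[, 1:3], labels[1:3], "A"), ">= 2")
})

test_that("buildTemplates enforces thresholds, dedupe by max fold change, disjointness", {
  mk <- function(genes, lfc, fdr) data.frame(gene = genes, log2fc = lfc,
                                             t = 0, df = 10, p = fdr,
                                             fdr = fdr, flagged = FALSE)
  tabs <- list(
    s1 = mk(c("a", "b", "shared", "weak", "ns"), c(3, 2, 3, 0.5, 4),
            c(0.001, 0.001, 0.001, 0.001, 0.5)),
    s2 = mk(c("c", "shared", "d"), c(2.5, 2, 1.5), c(0.001, 0.001, 0.001)))
  expect_warning(tpl <- buildTemplates(tabs, topN = 3L), "qualifying")
  expect_identical(templateGenes(tpl)$s1, c("a", "shared", "b"))  # tie at FC 3: lexicographic
  expect_identical(templateGenes(tpl)$s2, c("c", "d"))
  expect_length(intersect(templateGenes(tpl)$s1, templateGenes(tpl)$s2), 0)

  # too few qualifying genes warns; an empty template warns too
  tabs$s2 <- mk("only", 2, 0.001)
  expect_warning(buildTemplates(tabs, topN = 3L), "only 1 qualifying")
  tabs$s2 <- mk("x", 0.2, 0.9)
  expect_warning(tpl2 <- buildTemplates(tabs, topN = 3L), "0 qualifying")
  expect_length(templateGenes(tpl2)$s2, 0)
})

test_that("templates derived from a labeled simulated cohort recover planted markers", {
  sim <- smallSim(seed = 71L)
  expr <- omicsLayer(sim$bundle, "expression")
  tpl <- deriveTemplates(expr, sim$labels, topN = 25L)
  expect_equal(sum(lengths(templateGenes(tpl))), 75L)
  for (s in 1:3)
    expect_setequal(templateGenes(tpl)[[paste0("subtype", s)]],
                    sim$markers$mrna[[s]])
})

test_that("ntp distances follow the cosine geometry of toy profiles", {
  # 40 genes; template for subtype A = genes 1:5, B = genes 6:10
  genes <- paste0("g", 1:40)
  tpl <- new("SubtypeTemplates",
             templates = list(A = genes[1:5], B = genes[6:10]),
             weights = list(A = setNames(rep(1, 5), genes[1:5]),
                            B = setNames(rep(1, 5), genes[6:10])))
  # sample 1: z-profile proportional to A's indicator; needs cohort variation
  set.seed(2)
  expr <- matrix(rnorm(40 * 20, 0, 0.1), 40, 20,
                 dimnames = list(genes, paste0("s", 1:20)))
  expr[1:5, 1] <- expr[1:5, 1] + 10
  res <- ntpClassify(expr, tpl, nResamples = 200L, seed = 1L)
  tab <- ntpTable(res)
  expect_equal(tab$subtype[1], "A")
  expect_lt(tab$dist.A[1], 0.2)
  expect_equal(tab$p[1], 1 / 201, tolerance = 1e-9)
  expect_true(all(tab$dist.A >= 0 & tab$dist.A <= 2))

  # a z-vector orthogonal to both templates: distances ~1, unconfident
  expr2 <- expr
  expr2[1:10, 2] <- rep(c(10, -10), 5)   # alternating: orthogonal to both indicators
  res2 <- ntpClassify(expr2, tpl, nResamples = 200L, seed = 1L)
  d2 <- ntpTable(res2)[2, c("dist.A", "dist.B")]
  expect_true(all(abs(unlist(d2) - 1) < 0.25))
  expect_false(ntpTable(res2)$confident[2])

  # distances invariant to per-gene affine rescaling of raw expression
  exprScaled <- expr * 3 + 7
  res3 <- ntpClassify(exprScaled, tpl, nResamples = 50L, seed = 1L)
  expect_equal(ntpTable(res3)$dist.A, tab$dist.A, tolerance = 1e-9)

  # missing template genes: warning below 50%, error at 0%
  expect_warning(ntpClassify(expr[c(1:3, 11:40), ], tpl, nResamples = 10L,
                             seed = 1L), "%")
  expect_error(ntpClassify(expr[21:40, ], tpl, nResamples = 10L, seed = 1L),
               "no template genes")
})

test_that("ntp classifies held-out simulated samples accurately (pipeline closure)", {
  sim <- smallSim(seed = 81L)
  expr <- omicsLayer(sim$bundle, "expression")
  ids <- sampleIDs(sim$bundle)
  set.seed(8); train <- sort(sample(ids, 30L))
  test <- setdiff(ids, train)
  suppressWarnings(tpl <- deriveTemplates(expr[, train], sim$labels[train],
                                          topN = 25L))
  res <- ntpClassify(expr[, test], tpl, nResamples = 200L, seed = 8L)
  pred <- sub("subtype", "", subtypeLabels(res))
  acc <- mean(as.integer(pred) == sim$labels[test])
  expect_gte(acc, 0.9)
})

test_that("pamScores match the closed-form toy value and structural identities", {
  # class 1 values {3, 1}, class 2 {-3, -1}, s0 = 0 -> d_{g,1} = 2.828
  expr <- mkMat(c(3, 1, -3, -1), "g", paste0("s", 1:4))
  expr <- rbind(expr, other = c(1, -1, 1, -1))
  labels <- c(1, 1, 2, 2)
  sc <- pamScores(expr, labels, s0 = 0)
  expect_equal(sc["g", "subtype1"], 2 / (0.5 * sqrt(2)), tolerance = 1e-12)
  # numerator identity: sum_k n_k (xbar_gk - xbar_g) = 0  => scores weighted
  # by n_k m_k (s_g + s0) sum to zero per gene
  nk <- c(2, 2); n <- 4
  mk <- sqrt(1 / nk - 1 / n)
  num <- sweep(sc, 2, mk, "*")          # (xbar_gk - xbar_g)/(s_g+s0)
  expect_equal(unname(num %*% nk)[, 1], c(0, 0), tolerance = 1e-9)

  # class mean equal to overall mean -> 0; negation flips signs
  expect_equal(sc["other", "subtype1"],
               (0 - 0) / (sqrt(1 / 2 - 1 / 4)), tolerance = 1e-12)
  scNeg <- pamScores(-expr, labels, s0 = 0)
  expect_equal(unname(scNeg), unname(-sc), tolerance = 1e-12)

  expect_error(pamScores(expr, c(1, 1, 1, 2)), ">= 2 samples")
})

test_that("reducePanel selects strictly above per-subtype thresholds", {
  sc <- matrix(c(0.25, 0.1, 0.6, 0.4, 0.1, 0.55), 3, 2,
               dimnames = list(c("gA", "gB", "gC"),
                               c("subtype1", "subtype2")))
  pp <- reducePanel(sc, c(subtype1 = 0.2, subtype2 = 0.5))
  expect_setequal(pp@selected$subtype1, c("gA", "gC"))
  expect_setequal(pp@selected$subtype2, "gC")
  expect_setequal(panelGenes(pp), c("gA", "gC"))
  expect_error(reducePanel(sc, c(subtype1 = 5, subtype2 = 5)), "lower")
})

test_that("panel derived from a synthetic cohort contains only planted markers", {
  sim <- smallSim(seed = 91L)
  sc <- pamScores(omicsLayer(sim$bundle, "expression"), sim$labels)
  pp <- reducePanel(sc, setNames(rep(3.0, 3), colnames(sc)))
  planted <- unlist(sim$markers$mrna)
  expect_true(all(panelGenes(pp) %in% planted))
  for (s in 1:3)
    expect_true(all(pp@selected[[paste0("subtype", s)]] %in%
                      sim$markers$mrna[[s]]))
})

test_that("bagged accuracy is 1 on separable panels, ~1/k under permutation, reproducible", {
  sim <- smallSim(seed = 95L)
  expr <- omicsLayer(sim$bundle, "expression")
  panel <- unlist(sim$markers$mrna)[seq(1, 75, by = 5)]
  res <- baggedAccuracy(expr[panel, ], sim$labels, nClassifiers = 50L,
                        seed = 1L)
  expect_gte(res$mean, 0.95)

  set.seed(3); shuffled <- setNames(sample(sim$labels), names(sim$labels))
  resNull <- baggedAccuracy(expr[panel, ], shuffled, nClassifiers = 100L,
                            seed = 2L)
  expect_lt(abs(resNull$mean - 1 / 3), 0.1)

  resA <- baggedAccuracy(expr[panel, ], sim$labels, nClassifiers = 20L, seed = 5L)
  resB <- baggedAccuracy(expr[panel, ], sim$labels, nClassifiers = 20L, seed = 5L)
  expect_identical(resA$accuracies, resB$accuracies)
  expect_error(baggedAccuracy(expr[panel, ], rep(1, 60), seed = 1L),
               ">= 2 classes")
})
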