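# Subtype templates and classification: one-vs-rest moderated-t differential
# expression, per-subtype marker templates (50 genes each at defaults),
# nearest template prediction with resampling significance, reduction to a
# compact panel by nearest-shrunken-centroid scores, and bagged classifier
# validation of the panel.

.trigammaInverse <- function(x) {
  # Newton solve of trigamma(y) = x (x > 0), vectorized
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

.fitVariancePrior <- function(s2, df) {
  # empirical-Bayes prior on gene variances by method of moments on log s^2:
  # log s2_g ~ log s0^2 + log F(df, d0); matches the standard limma model
  ok <- s2 > 0
  z <- log(s2[ok])
  if (length(z) < 2L) return(list(d0 = Inf, s02 = mean(s2)))
  evar <- var(z) - trigamma(df / 2)
  if (evar <= 0) {
    d0 <- Inf
    s02 <- exp(mean(z) - digamma(df / 2) + log(df / 2))
  } else {
    d0 <- 2 * .trigammaInverse(evar)
    s02 <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

#' One-vs-rest moderated-t differential expression
#'
#' For one subtype against all others: per-gene log2 fold change (difference
#' of means on the log2 scale) and a moderated t-statistic whose residual
#' variance is shrunk toward an empirical-Bayes prior estimated by method of
#' moments on the log variances; Benjamini-Hochberg FDR across genes.
#' Genes with zero variance in both arms get p = 1 and are flagged.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param labels subtype labels (named by sample or in column order).
#' @param subtype the subtype tested against the rest.
#' @return data.frame: gene, log2fc, t, df, p, fdr, flagged.
#' @export
differentialExpression <- function(expr, labels, subtype) {
  if (!is.null(names(labels))) labels <- labels[colnames(expr)]
  inGrp <- labels == subtype
  n1 <- sum(inGrp); n2 <- sum(!inGrp)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples in each arm")
  m1 <- rowMeans(expr[, inGrp, drop = FALSE])
  m2 <- rowMeans(expr[, !inGrp, drop = FALSE])
  lfc <- m1 - m2
  rss <- rowSums((expr[, inGrp, drop = FALSE] - m1)^2) +
    rowSums((expr[, !inGrp, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2L
  s2 <- rss / df
  prior <- .fitVariancePrior(s2, df)
  s2post <- if (is.finite(prior$d0))
    (prior$d0 * prior$s02 + df * s2) / (prior$d0 + df) else rep(prior$s02, length(s2))
  dfTot <- if (is.finite(prior$d0)) df + prior$d0 else Inf
  se <- sqrt(s2post * (1 / n1 + 1 / n2))
  flagged <- s2 == 0 | se == 0   # no within-arm variance: t is undefined
  tstat <- ifelse(flagged, 0, lfc / pmax(se, .Machine$double.eps))
  p <- ifelse(flagged, 1, 2 * pt(-abs(tstat), df = dfTot))
  data.frame(gene = rownames(expr), log2fc = lfc, t = tstat,
             df = rep(dfTot, length(lfc)), p = p, fdr = p.adjust(p, "BH"),
             flagged = flagged, row.names = NULL, stringsAsFactors = FALSE)
}

#' Derive per-subtype template gene lists
#'
#' Per subtype, genes with FDR < `fdrMax` and log2 fold change >= `lfcMin`
#' qualify; a gene qualifying for several subtypes is assigned to the subtype
#' where its fold change is largest, each subtype's surviving qualifiers are
#' ranked by descending fold change, and the top `topN` are kept. The
#' resulting lists are pairwise disjoint (150 genes at the defaults when all
#' three lists fill).
#'
#' @param tables named list of [differentialExpression()] tables, one per
#'   subtype.
#' @param topN target genes per subtype.
#' @param fdrMax,lfcMin significance and effect-size thresholds.
#' @return a [SubtypeTemplates-class].
#' @export
buildTemplates <- function(tables, topN = 50L, fdrMax = 0.05, lfcMin = 1.0) {
  stopifnot(length(tables) >= 2L, !is.null(names(tables)))
  qual <- lapply(tables, function(tb)
    tb[tb$fdr < fdrMax & tb$log2fc >= lfcMin, c("gene", "log2fc")])
  allGenes <- unique(unlist(lapply(qual, `[[`, "gene")))
  assign <- setNames(character(length(allGenes)), allGenes)
  bestLfc <- setNames(rep(-Inf, length(allGenes)), allGenes)
  for (nm in names(qual)) {
    q <- qual[[nm]]
    upd <- q$log2fc > bestLfc[q$gene]
    assign[q$gene[upd]] <- nm
    bestLfc[q$gene[upd]] <- q$log2fc[upd]
  }
  templates <- list(); weights <- list()
  for (nm in names(qual)) {
    q <- qual[[nm]]
    q <- q[assign[q$gene] == nm, , drop = FALSE]
    q <- q[order(-q$log2fc, q$gene), , drop = FALSE]
    if (nrow(q) < topN)
      warning("subtype ", nm, ": only ", nrow(q), " qualifying genes (< ",
              topN, ")")
    q <- head(q, topN)
    templates[[nm]] <- q$gene
    weights[[nm]] <- setNames(q$log2fc, q$gene)
  }
  new("SubtypeTemplates", templates = templates, weights = weights,
      provenance = list(topN = topN, fdrMax = fdrMax, lfcMin = lfcMin))
}

#' Derive templates directly from a labeled cohort
#'
#' Convenience wrapper: runs one-vs-rest [differentialExpression()] for every
#' subtype and builds the templates.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param labels subtype labels (named by sample).
#' @param topN,fdrMax,lfcMin passed to [buildTemplates()].
#' @return a [SubtypeTemplates-class].
#' @export
deriveTemplates <- function(expr, labels, topN = 50L, fdrMax = 0.05,
                            lfcMin = 1.0) {
  subs <- sort(unique(labels))
  tabs <- lapply(subs, function(s) differentialExpression(expr, labels, s))
  names(tabs) <- paste0("subtype", subs)
  buildTemplates(tabs, topN = topN, fdrMax = fdrMax, lfcMin = lfcMin)
}

.cosineDist <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(1)
  1 - sum(a * b) / (na * nb)
}

#' Nearest template prediction
#'
#' Expression is z-scored per gene across the cohort. Each sample's z-vector,
#' restricted to the union of template genes, is compared by cosine distance
#' to each subtype's template vector (its genes marked 1 - or their log2
#' fold-change weights - and 0 elsewhere); the sample is assigned the
#' nearest template. Significance: the same distance is computed for
#' `nResamples` random gene sets of identical size drawn from the measured
#' genes; p is the fraction of null distances at or below the observed one
#' (with a +1 continuity floor of 1/(nResamples+1)); BH FDR across samples.
#'
#' @param expr genes x samples log2 expression matrix of the cohort to
#'   classify.
#' @param templates a [SubtypeTemplates-class].
#' @param nResamples random gene sets for the null.
#' @param fdrMax confidence threshold on the FDR.
#' @param weighting "binary" template vectors (default) or "lfc" weights.
#' @param seed RNG seed.
#' @return an [NtpResult-class]; unconfident samples keep their argmin label.
#' @export
ntpClassify <- function(expr, templates, nResamples = 1000L, fdrMax = 0.05,
                        weighting = c("binary", "lfc"), seed = 1L) {
  weighting <- match.arg(weighting)
  tg <- templateGenes(templates)
  union <- unlist(tg, use.names = FALSE)
  measured <- intersect(union, rownames(expr))
  cov <- length(measured) / length(union)
  if (cov == 0) stop("no template genes are measured in this cohort")
  if (cov < 0.5) warning("only ", round(100 * cov, 1),
                         "% of template genes are measured")
  gm <- rowMeans(expr)
  gs <- .rowSds(expr)
  z <- (expr - gm) / ifelse(gs > 0, gs, 1)   # per-gene z-score; constants -> 0
  zt <- z[measured, , drop = FALSE]
  tmplVec <- vapply(names(tg), function(nm) {
    v <- numeric(length(measured))
    idx <- match(intersect(tg[[nm]], measured), measured)
    v[idx] <- if (weighting == "binary") 1 else
      templateWeights(templates)[[nm]][measured[idx]]
    v
  }, numeric(length(measured)))
  dists <- t(apply(zt, 2L, function(x)
    apply(tmplVec, 2L, function(v) .cosineDist(x, v))))
  colnames(dists) <- names(tg)
  assigned <- colnames(dists)[max.col(-dists, ties.method = "first")]
  obs <- dists[cbind(seq_len(nrow(dists)), match(assigned, colnames(dists)))]

  nullD <- .withSeed(seed, {
    pool <- rownames(z)
    sapply(seq_len(nResamples), function(r) {
      g <- sample(pool, length(measured))
      zr <- z[g, , drop = FALSE]
      dr <- t(apply(zr, 2L, function(x)
        apply(tmplVec, 2L, function(v) .cosineDist(x, v))))
      dr[cbind(seq_len(nrow(dr)), match(assigned, colnames(dists)))]
    })
  })
  if (is.null(dim(nullD))) nullD <- matrix(nullD, ncol = nResamples)
  p <- (rowSums(nullD <= obs) + 1) / (nResamples + 1)
  fdr <- p.adjust(p, "BH")
  tab <- data.frame(sample = colnames(expr), subtype = assigned,
                    stringsAsFactors = FALSE)
  for (nm in colnames(dists)) tab[[paste0("dist.", nm)]] <- dists[, nm]
  tab$p <- p; tab$fdr <- fdr; tab$confident <- fdr < fdrMax
  new("NtpResult", table = tab, coverage = cov)
}

#' Nearest-shrunken-centroid (PAM) scores
#'
#' Standardized centroid deviations d_gk = (xbar_gk - xbar_g) /
#' (m_k (s_g + s0)) with m_k = sqrt(1/n_k - 1/n), s_g the pooled within-class
#' SD and s0 a fattening constant (median of s_g by default). No shrinkage is
#' applied before thresholding; a positive score means the gene is expressed
#' above average in that subtype.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param labels subtype labels (named by sample or in column order).
#' @param s0 "median_si" (default) or a numeric value.
#' @return numeric matrix genes x subtypes of scores.
#' @export
pamScores <- function(expr, labels, s0 = "median_si") {
  if (!is.null(names(labels))) labels <- labels[colnames(expr)]
  cls <- sort(unique(labels))
  if (any(table(labels) < 2L)) stop("need >= 2 samples per subtype")
  n <- ncol(expr)
  overall <- rowMeans(expr)
  wss <- 0
  cent <- matrix(0, nrow(expr), length(cls),
                 dimnames = list(rownames(expr), paste0("subtype", cls)))
  for (j in seq_along(cls)) {
    sel <- labels == cls[j]
    cm <- rowMeans(expr[, sel, drop = FALSE])
    cent[, j] <- cm
    wss <- wss + rowSums((expr[, sel, drop = FALSE] - cm)^2)
  }
  sg <- sqrt(wss / (n - length(cls)))
  s0v <- if (identical(s0, "median_si")) median(sg) else as.numeric(s0)
  scores <- cent
  for (j in seq_along(cls)) {
    nk <- sum(labels == cls[j])
    mk <- sqrt(1 / nk - 1 / n)
    denom <- mk * (sg + s0v)
    scr <- ifelse(denom == 0, 0, (cent[, j] - overall) / denom)
    scores[, j] <- scr
  }
  scores
}

#' Reduce the signature to a compact panel by PAM-score thresholds
#'
#' Per subtype, genes with score strictly above that subtype's threshold
#' (positive association only) are selected; the panel is their union.
#'
#' @param scores genes x subtypes matrix from [pamScores()].
#' @param thresholds positive numeric vector, one per subtype (recycled names
#'   must match the score columns; an unnamed vector is matched by position).
#' @return a [PamPanel-class].
#' @export
reducePanel <- function(scores, thresholds) {
  stopifnot(all(thresholds > 0))
  if (is.null(names(thresholds))) {
    stopifnot(length(thresholds) == ncol(scores))
    names(thresholds) <- colnames(scores)
  }
  selected <- lapply(colnames(scores), function(nm) {
    g <- rownames(scores)[scores[, nm] > thresholds[[nm]]]
    g[order(-scores[g, nm])]
  })
  names(selected) <- colnames(scores)
  panel <- unique(unlist(selected, use.names = FALSE))
  if (!length(panel))
    stop("no gene exceeds its subtype threshold; lower the thresholds")
  new("PamPanel", scores = scores, thresholds = thresholds,
      selected = selected, panel = panel)
}

#' Bagged classifier accuracy of a gene panel
#'
#' Repeatedly trains a bagged decision-tree (random forest) classifier on a
#' stratified `trainFrac` of the samples and evaluates its accuracy, either
#' on the held-out samples ("out_of_bag", default) or on all samples
#' including the training half ("all_samples").
#'
#' @param exprPanel panel-genes x samples expression matrix.
#' @param labels subtype labels (named by sample or in column order).
#' @param nClassifiers repetitions.
#' @param trainFrac training fraction per class.
#' @param eval evaluation mode (see above).
#' @param nTree trees per classifier.
#' @param seed RNG seed.
#' @return list with `mean`, `min`, `max`, `quantiles` (2.5/25/50/75/97.5%)
#'   and the full `accuracies` vector.
#' @export
baggedAccuracy <- function(exprPanel, labels, nClassifiers = 10000L,
                           trainFrac = 0.5,
                           eval = c("out_of_bag", "all_samples"),
                           nTree = 50L, seed = 1L) {
  eval <- match.arg(eval)
  if (!is.null(names(labels))) labels <- labels[colnames(exprPanel)]
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("labels must contain >= 2 classes")
  X <- t(exprPanel)
  acc <- .withSeed(seed, {
    vapply(seq_len(nClassifiers), function(r) {
      tr <- unlist(lapply(levels(y), function(cl) {
        idx <- which(y == cl)
        sample(idx, max(1L, floor(trainFrac * length(idx))))
      }))
      fit <- randomForest::randomForest(X[tr, , drop = FALSE], y[tr],
                                        ntree = nTree)
      te <- if (eval == "out_of_bag") setdiff(seq_along(y), tr) else seq_along(y)
      mean(predict(fit, X[te, , drop = FALSE]) == y[te])
    }, 1)
  })
  list(mean = mean(acc), min = min(acc), max = max(acc),
       quantiles = quantile(acc, c(0.025, 0.25, 0.5, 0.75, 0.975)),
       accuracies = acc)
}
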