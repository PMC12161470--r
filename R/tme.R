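# Tumor-microenvironment and pathway profiling: geometric-mean signature
# scores, marker-population means, single-sample gene-set enrichment (the
# basis of the immune and stromal enrichment scores), preranked GSEA, and
# genome-alteration burden metrics (FGA/FGG/FGL, TMB).

#' Geometric-mean signature score
#'
#' Per sample, exp(mean(log(x + pseudocount))) - pseudocount over the
#' signature genes, computed on the linear scale. If `expr` is tagged or
#' declared log2, it is back-transformed (2^x - 1) first.
#'
#' @param expr genes x samples matrix.
#' @param genes signature gene ids (unmeasured genes dropped with a message).
#' @param pseudocount added inside the log (default 1) so zeros stay finite.
#' @param scaleTag "linear" or "log2"; defaults to the matrix's `scale_tag`
#'   attribute, else "linear".
#' @return named numeric vector, one score per sample.
#' @export
geomeanScore <- function(expr, genes, pseudocount = 1, scaleTag = NULL) {
  if (is.null(scaleTag))
    scaleTag <- attr(expr, "scale_tag") %||% "linear"
  measured <- intersect(genes, rownames(expr))
  if (!length(measured))
    stop("no signature gene is measured (", paste(head(genes, 3), collapse = ","),
         " ...)")
  if (length(measured) < length(unique(genes)))
    message("geomeanScore: ", length(unique(genes)) - length(measured),
            " signature gene(s) not measured; dropped")
  x <- expr[measured, , drop = FALSE]
  if (scaleTag == "log2") x <- 2^x - 1
  if (any(x + pseudocount <= 0))
    stop("values + pseudocount must be positive for the geometric mean")
  exp(colMeans(log(x + pseudocount))) - pseudocount
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Marker-population abundance scores
#'
#' Per population, the arithmetic mean of log2 expression over its measured
#' marker genes (duplicated markers counted once; populations with no
#' measured marker are omitted with a warning).
#'
#' @param exprLog2 genes x samples log2 expression matrix.
#' @param markerSets a [SignatureSet-class] of marker lists.
#' @return samples x populations score matrix.
#' @export
populationScores <- function(exprLog2, markerSets) {
  sets <- geneSets(markerSets)
  out <- list()
  for (nm in names(sets)) {
    g <- intersect(unique(sets[[nm]]), rownames(exprLog2))
    if (!length(g)) {
      warning("population ", nm, " has no measured markers; omitted")
      next
    }
    out[[nm]] <- colMeans(exprLog2[g, , drop = FALSE])
  }
  if (!length(out)) stop("no population has measured markers")
  do.call(cbind, out)
}

#' Single-sample gene-set enrichment score
#'
#' Per sample, genes are ranked by expression (average ranks on ties; the
#' most expressed gene carries the largest rank). Walking down the ranking,
#' the enrichment score is the sum over all positions of the difference
#' between the weighted in-set empirical CDF (weights = rank^alpha) and the
#' unweighted out-of-set CDF.
#'
#' @param expr genes x samples matrix.
#' @param geneSet character vector of gene ids (>= 2 must be measured).
#' @param alpha rank-weighting exponent (default 0.25).
#' @param normalize if TRUE, scores are min-max scaled across samples.
#' @return named numeric vector of per-sample enrichment scores.
#' @export
ssgsea <- function(expr, geneSet, alpha = 0.25, normalize = FALSE) {
  measured <- intersect(unique(geneSet), rownames(expr))
  if (length(measured) < 2L) stop("fewer than 2 gene-set members measured")
  N <- nrow(expr)
  inSet <- rownames(expr) %in% measured
  es <- vapply(seq_len(ncol(expr)), function(j) {
    x <- expr[, j]
    if (max(x) == min(x)) return(0)  # constant profile carries no ranking
    rk <- rank(x, ties.method = "average")        # largest value -> rank N
    ord <- order(x, decreasing = TRUE)
    inOrd <- inSet[ord]
    w <- rk[ord]^alpha
    stepIn <- ifelse(inOrd, w, 0)
    cdfIn <- cumsum(stepIn) / sum(stepIn)
    stepOut <- ifelse(inOrd, 0, 1)
    cdfOut <- cumsum(stepOut) / (N - length(measured))
    sum(cdfIn - cdfOut)
  }, 1)
  names(es) <- colnames(expr)
  if (normalize && diff(range(es)) > 0)
    es <- (es - min(es)) / diff(range(es))
  es
}

#' Immune and stromal enrichment scores
#'
#' IES and SES are the [ssgsea()] scores of an immune and a stromal gene set.
#'
#' @param expr genes x samples matrix.
#' @param immuneSet,stromalSet character vectors of gene ids.
#' @param alpha passed to [ssgsea()].
#' @return data.frame with columns sample, IES, SES.
#' @export
estimateScores <- function(expr, immuneSet, stromalSet, alpha = 0.25) {
  data.frame(sample = colnames(expr),
             IES = ssgsea(expr, immuneSet, alpha = alpha),
             SES = ssgsea(expr, stromalSet, alpha = alpha),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running sum on a ranked gene list (weights
#' |stat|^weightP), with a gene-label permutation null: ES is the running
#' sum's extreme deviation, NES divides ES by the mean |null ES| of the same
#' sign, p is the same-sign permutation tail, and FDR is BH across sets.
#' Sets with fewer than `minSize` measured genes are skipped.
#'
#' @param ranked named numeric vector, gene-level statistics (e.g. log2 fold
#'   changes); ranking is by decreasing value.
#' @param geneSets a [SignatureSet-class] or named list of gene vectors.
#' @param nPerm permutations of the gene labels.
#' @param weightP weighting exponent on |stat|.
#' @param minSize minimum measured set size.
#' @param seed RNG seed.
#' @return data.frame: set, size, es, nes, p, fdr, leadingEdge (comma-joined).
#' @export
prerankedGsea <- function(ranked, geneSets, nPerm = 1000L, weightP = 1,
                          minSize = 5L, seed = 1L) {
  if (is(geneSets, "SignatureSet")) geneSets <- geneSets@signatures
  if (length(ranked) < 2L) stop("need >= 2 ranked genes")
  if (all(ranked == 0)) stop("all gene statistics are zero")
  ord <- order(ranked, decreasing = TRUE)
  stats <- ranked[ord]
  genes <- names(stats)
  N <- length(genes)

  esRun <- function(members) {
    hits <- genes %in% members
    w <- abs(stats)^weightP
    wIn <- ifelse(hits, w, 0)
    sIn <- sum(wIn)
    if (sIn == 0) return(list(es = 0, lead = character(0)))
    run <- cumsum(wIn / sIn - ifelse(hits, 0, 1 / (N - sum(hits))))
    iMax <- which.max(abs(run))
    es <- run[iMax]
    lead <- if (es >= 0) genes[seq_len(iMax)][hits[seq_len(iMax)]]
    else genes[seq(iMax, N)][hits[seq(iMax, N)]]
    list(es = es, lead = lead)
  }

  rows <- list()
  for (nm in names(geneSets)) {
    members <- intersect(unique(geneSets[[nm]]), genes)
    if (length(members) < minSize) {
      message("prerankedGsea: set ", nm, " has < ", minSize,
              " measured genes; skipped")
      next
    }
    obs <- esRun(members)
    nullEs <- .withSeed(.subSeed(seed, match(nm, names(geneSets))),
      vapply(seq_len(nPerm), function(r)
        esRun(sample(genes, length(members)))$es, 1))
    same <- nullEs[sign(nullEs) == sign(obs$es) | nullEs == 0]
    p <- if (!length(same)) 1 / (nPerm + 1) else
      (sum(abs(same) >= abs(obs$es)) + 1) / (length(same) + 1)
    mu <- mean(abs(same))
    nes <- if (is.na(mu) || mu == 0) 0 else obs$es / mu
    rows[[nm]] <- data.frame(set = nm, size = length(members), es = obs$es,
                             nes = nes, p = p,
                             leadingEdge = paste(obs$lead, collapse = ","),
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no gene set passed the size filter")
  out <- do.call(rbind, unname(rows))
  out$fdr <- p.adjust(out$p, "BH")
  out[, c("set", "size", "es", "nes", "p", "fdr", "leadingEdge")]
}

#' Genome-alteration burden from copy-number segments
#'
#' Per sample: FGA = altered length / total covered length at
#' |log2 ratio| >= `threshold`; FGG and FGL are the gained (>= +threshold)
#' and lost (<= -threshold) components, so FGG + FGL = FGA exactly. Segment
#' lengths are end - start + 1 (1-based inclusive coordinates).
#'
#' @param segments validated segment data.frame.
#' @param threshold absolute log2-ratio cutoff (default 0.3; the boundary
#'   value counts as altered).
#' @return data.frame: sample, fga, fgg, fgl, coveredBp.
#' @export
genomeBurden <- function(segments, threshold = 0.3) {
  validateSegmentTable(segments)
  len <- segments$end - segments$start + 1
  sp <- split(seq_len(nrow(segments)), segments$sample)
  rows <- lapply(names(sp), function(s) {
    i <- sp[[s]]
    tot <- sum(len[i])
    if (tot <= 0) stop("sample ", s, " has zero covered length")
    lr <- segments$log2ratio[i]
    data.frame(sample = s,
               fga = sum(len[i][abs(lr) >= threshold]) / tot,
               fgg = sum(len[i][lr >= threshold]) / tot,
               fgl = sum(len[i][lr <= -threshold]) / tot,
               coveredBp = tot, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tumor mutational burden
#'
#' @param variantCounts named numeric vector, non-silent variants per sample.
#' @param panelMb assayed territory in megabases (> 0).
#' @return named numeric vector, mutations per megabase.
#' @export
tmb <- function(variantCounts, panelMb) {
  if (!is.numeric(panelMb) || panelMb <= 0) stop("panelMb must be > 0")
  variantCounts / panelMb
}

#' Weighted-sum risk score from an external signature
#'
#' Sum over measured signature genes of weight x expression, per sample
#' (the construction of published prognostic panels such as LSC17).
#'
#' @param expr genes x samples matrix.
#' @param weights named numeric vector, gene weights.
#' @return named numeric vector of per-sample scores.
#' @export
scoreExternalSignature <- function(expr, weights) {
  stopifnot(!is.null(names(weights)))
  measured <- intersect(names(weights), rownames(expr))
  if (length(measured) < 0.5 * length(weights))
    warning("fewer than 50% of the weighted genes are measured")
  if (!length(measured)) return(setNames(rep(0, ncol(expr)), colnames(expr)))
  colSums(expr[measured, , drop = FALSE] * weights[measured])
}
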