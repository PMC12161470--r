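# Per-layer feature selection feeding the clustering ensemble: top-variance
# features for continuous layers, a frequency filter for binary mutations,
# and demethylation probe selection against a normal methylation reference.

.rowSds <- function(m) {
  # sample SD (n-1 denominator) per row
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(pmax(rowSums((m - mu)^2), 0) / (n - 1L))
}

#' Select the features with the largest standard deviation
#'
#' Rows are ranked by sample standard deviation (n-1 denominator), ties broken
#' lexicographically by feature id; the top `n` are returned in descending-SD
#' order.
#'
#' @param m features x samples matrix.
#' @param n number of features to keep.
#' @return data.frame with columns `feature` and `statistic` (the SD), one row
#'   per selected feature, ordered by descending SD.
#' @export
topSdFeatures <- function(m, n = 1000L) {
  stopifnot(n >= 1L)
  sds <- .rowSds(m)
  if (all(sds == 0)) warning("matrix is constant; all SDs are 0")
  ord <- order(-sds, rownames(m))
  if (n > nrow(m)) {
    warning("requested ", n, " features but only ", nrow(m), " available")
    n <- nrow(m)
  }
  sel <- ord[seq_len(n)]
  data.frame(feature = rownames(m)[sel], statistic = sds[sel],
             stringsAsFactors = FALSE)
}

#' Filter mutation genes by cohort frequency
#'
#' Keeps gene g iff the fraction of mutated samples is at least `minFrac`
#' (boundary equality kept).
#'
#' @param mut binary genes x samples matrix.
#' @param minFrac minimum mutated fraction (default 0.03, i.e. 3% of samples).
#' @return data.frame with columns `feature` and `statistic` (mutated
#'   fraction) for the retained genes.
#' @export
filterMutationsByFrequency <- function(mut, minFrac = 0.03) {
  stopifnot(minFrac > 0, minFrac <= 1)
  if (nrow(mut) == 0L)
    return(data.frame(feature = character(0), statistic = numeric(0)))
  frac <- rowMeans(mut)
  keep <- which(frac >= minFrac)
  keep <- keep[order(-frac[keep], rownames(mut)[keep])]
  data.frame(feature = rownames(mut)[keep], statistic = frac[keep],
             stringsAsFactors = FALSE)
}

#' Select demethylation probes against a normal reference
#'
#' A probe qualifies when it is strongly methylated in the normal reference
#' (mean beta strictly greater than `normalMinBeta`) and variable across the
#' tumor cohort (SD strictly greater than `sdMin`). `keepNormalHigh = TRUE`
#' (the default) retains normally hypermethylated probes, which is what the
#' demethylator concept requires; setting it to FALSE inverts the background
#' rule and excludes them instead.
#'
#' @param aml probes x samples tumor beta matrix.
#' @param normal probes x samples reference beta matrix.
#' @param normalMinBeta background threshold on the normal mean (default 0.8).
#' @param sdMin variability threshold on the tumor SD (default 0.2).
#' @param keepNormalHigh direction of the background rule (see above).
#' @return data.frame with columns `feature`, `statistic` (tumor SD) and
#'   `normal_mean`, ordered by descending SD.
#' @export
selectDemethylationProbes <- function(aml, normal, normalMinBeta = 0.8,
                                      sdMin = 0.2, keepNormalHigh = TRUE) {
  common <- intersect(rownames(aml), rownames(normal))
  if (!length(common)) stop("no common probes between tumor and normal matrices")
  aml <- aml[common, , drop = FALSE]
  normal <- normal[common, , drop = FALSE]
  nm <- rowMeans(normal)
  sds <- .rowSds(aml)
  bg <- if (keepNormalHigh) nm > normalMinBeta else nm <= normalMinBeta
  keep <- which(bg & sds > sdMin)
  keep <- keep[order(-sds[keep], common[keep])]
  data.frame(feature = common[keep], statistic = sds[keep],
             normal_mean = nm[keep], stringsAsFactors = FALSE)
}

#' Reduce a bundle to its cluster-ready feature set
#'
#' Applies the per-layer selections: top-SD features for the continuous
#' layers (the methylation layer is first restricted to demethylation probes
#' when a normal reference is supplied) and the mutation frequency filter.
#'
#' @param bundle an [OmicsBundle-class].
#' @param layers layers the selection spec requests; a requested layer absent
#'   from the bundle is an error. "expression" is always required.
#' @param nExpr,nLnc,nMeth top-SD feature counts per continuous layer.
#' @param mutMinFrac mutation frequency threshold.
#' @param normalReference optional probes x samples normal beta matrix.
#' @param normalMinBeta,sdMin demethylation thresholds
#'   (see [selectDemethylationProbes()]).
#' @return list with `bundle` (the reduced [OmicsBundle-class]) and `report`
#'   (data.frame: feature, layer, statistic, kept).
#' @export
buildClusterInput <- function(bundle,
                              layers = c("expression", "lncrna",
                                         "methylation", "mutations"),
                              nExpr = 1000L, nLnc = 1000L,
                              nMeth = 1000L, mutMinFrac = 0.03,
                              normalReference = NULL, normalMinBeta = 0.8,
                              sdMin = 0.2) {
  stopifnot(is(bundle, "OmicsBundle"))
  layers <- match.arg(layers, several.ok = TRUE)
  layers <- union("expression", layers)
  for (ly in layers)
    if (is.null(omicsLayer(bundle, ly)))
      stop("requested layer absent from bundle: ", ly)
  report <- list()
  addReport <- function(layer, allFeatures, sel) {
    data.frame(feature = allFeatures, layer = layer,
               statistic = sel$statistic[match(allFeatures, sel$feature)],
               kept = allFeatures %in% sel$feature, stringsAsFactors = FALSE)
  }

  expr <- omicsLayer(bundle, "expression")
  selE <- topSdFeatures(expr, nExpr)
  report$expression <- addReport("expression", rownames(expr), selE)
  exprR <- expr[selE$feature, , drop = FALSE]

  lncR <- NULL
  lnc <- omicsLayer(bundle, "lncrna")
  if ("lncrna" %in% layers) {
    selL <- topSdFeatures(lnc, nLnc)
    report$lncrna <- addReport("lncrna", rownames(lnc), selL)
    lncR <- lnc[selL$feature, , drop = FALSE]
  }

  methR <- NULL
  meth <- omicsLayer(bundle, "methylation")
  if ("methylation" %in% layers) {
    pool <- meth
    if (!is.null(normalReference)) {
      dem <- selectDemethylationProbes(meth, normalReference,
                                       normalMinBeta = normalMinBeta,
                                       sdMin = sdMin)
      if (!nrow(dem)) stop("no probes pass the demethylation rules")
      pool <- meth[dem$feature, , drop = FALSE]
    }
    selM <- suppressWarnings(topSdFeatures(pool, min(nMeth, nrow(pool))))
    report$methylation <- addReport("methylation", rownames(meth), selM)
    methR <- pool[selM$feature, , drop = FALSE]
  }

  mutR <- NULL
  mut <- omicsLayer(bundle, "mutations")
  if ("mutations" %in% layers) {
    selU <- filterMutationsByFrequency(mut, mutMinFrac)
    report$mutations <- addReport("mutations", rownames(mut), selU)
    mutR <- mut[selU$feature, , drop = FALSE]
  }

  reduced <- new("OmicsBundle", expression = exprR, lncrna = lncR,
                 methylation = methR, mutations = mutR,
                 segments = segmentTable(bundle),
                 clinical = clinicalTable(bundle),
                 scaleTag = bundle@scaleTag)
  list(bundle = reduced, report = do.call(rbind, unname(report)))
}
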