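# Accessor generics and show methods. Slots are never accessed directly by
# user code; these accessors are the supported surface.

#' Sample identifiers of an object
#' @param x an object with samples.
#' @return character vector of sample ids.
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' Number of samples
#' @param x an object with samples.
#' @return integer.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Extract a layer matrix from an OmicsBundle
#' @param x an `OmicsBundle`.
#' @param layer one of "expression", "lncrna", "methylation", "mutations".
#' @return the layer matrix, or NULL if absent.
#' @export
setGeneric("omicsLayer", function(x, layer) standardGeneric("omicsLayer"))

#' Segment table of a bundle
#' @param x an `OmicsBundle`.
#' @return data.frame of copy-number segments, or NULL.
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))

#' Clinical/survival table of a bundle
#' @param x an `OmicsBundle`.
#' @return data.frame, or NULL.
#' @export
setGeneric("clinicalTable", function(x) standardGeneric("clinicalTable"))

#' Consensus co-assignment matrix
#' @param x a `PartitionEnsemble`.
#' @return numeric matrix in \[0,1\].
#' @export
setGeneric("consensusMatrix", function(x) standardGeneric("consensusMatrix"))

#' Final subtype labels
#' @param x a `PartitionEnsemble` or `NtpResult`.
#' @return named integer (ensemble) or character (NTP) vector of labels.
#' @export
setGeneric("subtypeLabels", function(x) standardGeneric("subtypeLabels"))

#' Per-algorithm partition matrix
#' @param x a `PartitionEnsemble`.
#' @return integer matrix samples x algorithms.
#' @export
setGeneric("algorithmPartitions", function(x) standardGeneric("algorithmPartitions"))

#' Template gene lists
#' @param x a `SubtypeTemplates`.
#' @return named list of character vectors.
#' @export
setGeneric("templateGenes", function(x) standardGeneric("templateGenes"))

#' Template gene weights (log2 fold changes)
#' @param x a `SubtypeTemplates`.
#' @return named list of numeric vectors.
#' @export
setGeneric("templateWeights", function(x) standardGeneric("templateWeights"))

#' Gene sets of a SignatureSet
#' @param x a `SignatureSet`.
#' @return named list of character vectors.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' Per-gene weights of a SignatureSet
#' @param x a `SignatureSet`.
#' @return named list of numeric vectors (may be empty).
#' @export
setGeneric("geneSetWeights", function(x) standardGeneric("geneSetWeights"))

#' Selected panel genes
#' @param x a `PamPanel`.
#' @return character vector (union over subtypes).
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))

#' Nearest-shrunken-centroid score table
#' @param x a `PamPanel`.
#' @return numeric matrix genes x subtypes.
#' @export
setGeneric("pamScoreTable", function(x) standardGeneric("pamScoreTable"))

#' Result table of an NTP classification
#' @param x an `NtpResult`.
#' @return data.frame, one row per sample.
#' @export
setGeneric("ntpTable", function(x) standardGeneric("ntpTable"))

#' Chosen number of clusters
#' @param x a `KSelectionReport`.
#' @return integer.
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))

# ---- methods ---------------------------------------------------------------

#' @rdname sampleIDs
setMethod("sampleIDs", "OmicsBundle", function(x) colnames(x@expression))
#' @rdname sampleIDs
setMethod("sampleIDs", "PartitionEnsemble", function(x) names(x@labels))
#' @rdname nSamples
setMethod("nSamples", "OmicsBundle", function(x) ncol(x@expression))
#' @rdname nSamples
setMethod("nSamples", "PartitionEnsemble", function(x) length(x@labels))

#' @rdname omicsLayer
setMethod("omicsLayer", "OmicsBundle", function(x, layer) {
  layer <- match.arg(layer, c("expression", "lncrna", "methylation", "mutations"))
  slot(x, layer)
})
#' @rdname segmentTable
setMethod("segmentTable", "OmicsBundle", function(x) x@segments)
#' @rdname clinicalTable
setMethod("clinicalTable", "OmicsBundle", function(x) x@clinical)

#' @rdname consensusMatrix
setMethod("consensusMatrix", "PartitionEnsemble", function(x) x@consensus)
#' @rdname subtypeLabels
setMethod("subtypeLabels", "PartitionEnsemble", function(x) x@labels)
#' @rdname subtypeLabels
setMethod("subtypeLabels", "NtpResult", function(x)
  setNames(as.character(x@table$subtype), x@table$sample))
#' @rdname algorithmPartitions
setMethod("algorithmPartitions", "PartitionEnsemble", function(x) x@partitions)

#' @rdname templateGenes
setMethod("templateGenes", "SubtypeTemplates", function(x) x@templates)
#' @rdname templateWeights
setMethod("templateWeights", "SubtypeTemplates", function(x) x@weights)

#' @rdname geneSets
setMethod("geneSets", "SignatureSet", function(x) x@signatures)
#' @rdname geneSetWeights
setMethod("geneSetWeights", "SignatureSet", function(x) x@weights)

#' @rdname panelGenes
setMethod("panelGenes", "PamPanel", function(x) x@panel)
#' @rdname pamScoreTable
setMethod("pamScoreTable", "PamPanel", function(x) x@scores)

#' @rdname ntpTable
setMethod("ntpTable", "NtpResult", function(x) x@table)

#' @rdname chosenK
setMethod("chosenK", "KSelectionReport", function(x) x@chosenK)

# ---- show ------------------------------------------------------------------

setMethod("show", "OmicsBundle", function(object) {
  cat("OmicsBundle with", nSamples(object), "samples\n")
  cat("  expression :", nrow(object@expression), "genes (", object@scaleTag, ")\n")
  for (nm in c("lncrna", "methylation", "mutations")) {
    m <- slot(object, nm)
    if (!is.null(m)) cat("  ", format(nm, width = 11), ":", nrow(m), "features\n")
  }
  if (!is.null(object@segments))
    cat("  segments   :", nrow(object@segments), "records\n")
  if (!is.null(object@clinical))
    cat("  clinical   :", sum(object@clinical$event), "events /",
        nrow(object@clinical), "samples\n")
})

setMethod("show", "PartitionEnsemble", function(object) {
  cat("PartitionEnsemble: k =", object@k, ",", length(object@algorithms),
      "algorithms (", paste(object@algorithms, collapse = ", "), ")\n")
  print(table(subtype = object@labels))
  cat("mean consensus silhouette:", round(object@silhouette, 3), "\n")
})

setMethod("show", "SignatureSet", function(object) {
  cat("SignatureSet with", length(object@signatures), "gene sets; sizes:",
      paste(range(lengths(object@signatures)), collapse = "-"), "\n")
})

setMethod("show", "SubtypeTemplates", function(object) {
  cat("SubtypeTemplates:", length(object@templates), "subtypes;",
      sum(lengths(object@templates)), "genes total\n")
  for (nm in names(object@templates))
    cat("  ", nm, ":", length(object@templates[[nm]]), "genes\n")
})

setMethod("show", "PamPanel", function(object) {
  cat("PamPanel:", length(object@panel), "genes (",
      paste(vapply(object@selected, length, 1L), collapse = " + "), ")\n")
})

setMethod("show", "NtpResult", function(object) {
  cat("NtpResult for", nrow(object@table), "samples; template coverage",
      round(100 * object@coverage, 1), "%\n")
  print(table(subtype = object@table$subtype,
              confident = object@table$confident))
})

setMethod("show", "KSelectionReport", function(object) {
  cat("KSelectionReport over k =", paste(range(object@kRange), collapse = ".."),
      "; chosen k =", object@chosenK, "(", object@ruleUsed, ")\n")
})
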