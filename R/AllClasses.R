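#' @import methods
#' @importFrom stats sd var rexp runif rnorm rbeta rbinom quantile p.adjust
#'   kmeans hclust cutree as.dist dist cor pt median setNames aggregate
#' @importFrom utils read.delim write.table head packageVersion
NULL

# ---- matrix validators (layers are plain matrices with dimnames) -----------

.checkIds <- function(ids, what) {
  if (is.null(ids) || any(is.na(ids)) || any(ids == ""))
    stop(what, " must be named (non-empty, non-NA dimnames)", call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate ", what, ": ", paste(unique(head(dup, 5)), collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' Validate an expression matrix (genes x samples)
#'
#' Checks the invariants expected of every continuous layer: numeric matrix,
#' unique gene and sample identifiers, all values finite.
#'
#' @param x numeric matrix, genes in rows, samples in columns.
#' @param what label used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validateExpressionMatrix <- function(x, what = "expression") {
  if (!is.matrix(x) || !is.numeric(x)) stop(what, " must be a numeric matrix")
  .checkIds(rownames(x), paste(what, "gene ids"))
  .checkIds(colnames(x), paste(what, "sample ids"))
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop("non-finite value in ", what, " at [",
         rownames(x)[bad[1L]], ", ", colnames(x)[bad[2L]], "]")
  }
  invisible(x)
}

#' Validate a methylation beta matrix (probes x samples)
#'
#' Beta values are methylated fractions and must lie in \[0, 1\].
#'
#' @param x numeric matrix of beta values.
#' @return `x`, invisibly, if valid.
#' @export
validateBetaMatrix <- function(x) {
  validateExpressionMatrix(x, "methylation")
  if (any(x < 0 | x > 1)) {
    bad <- which(x < 0 | x > 1, arr.ind = TRUE)[1L, ]
    stop("beta value outside [0,1] at probe ", rownames(x)[bad[1L]],
         " (sample ", colnames(x)[bad[2L]], ")")
  }
  invisible(x)
}

#' Validate a binary mutation matrix (genes x samples)
#'
#' @param x matrix with entries in \{0, 1\} (1 = at least one somatic variant).
#' @return `x`, invisibly, if valid.
#' @export
validateMutationMatrix <- function(x) {
  validateExpressionMatrix(x, "mutation")
  if (!all(x %in% c(0, 1))) stop("mutation matrix entries must be 0 or 1")
  invisible(x)
}

#' Validate a copy-number segment table
#'
#' Columns: sample, chromosome, start, end, log2ratio. Coordinates are
#' 1-based inclusive; per-sample segments must not overlap on a chromosome.
#'
#' @param seg data.frame of segments.
#' @return `seg`, invisibly, if valid.
#' @export
validateSegmentTable <- function(seg) {
  need <- c("sample", "chromosome", "start", "end", "log2ratio")
  miss <- setdiff(need, names(seg))
  if (length(miss)) stop("segment table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(seg$start < 1 | seg$end < 1)) stop("segment coordinates must be >= 1")
  bad <- which(seg$start > seg$end)
  if (length(bad)) stop("segment start > end at row ", bad[1L])
  sp <- split(seg, list(seg$sample, seg$chromosome), drop = TRUE)
  for (s in sp) {
    if (nrow(s) < 2L) next
    s <- s[order(s$start), ]
    if (any(s$start[-1L] <= s$end[-nrow(s)]))
      stop("overlapping segments for sample ", s$sample[1L],
           " on chromosome ", s$chromosome[1L])
  }
  invisible(seg)
}

#' Validate a survival table
#'
#' Columns: sample, time (months, positive finite), event (0/1); optional
#' group and risk_score.
#'
#' @param x data.frame with survival data.
#' @return `x`, invisibly, if valid.
#' @export
validateSurvivalTable <- function(x) {
  need <- c("sample", "time", "event")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("survival table missing column(s): ",
                         paste(miss, collapse = ", "))
  .checkIds(as.character(x$sample), "survival sample ids")
  if (any(!is.finite(x$time) | x$time <= 0))
    stop("survival times must be positive and finite")
  if (!all(x$event %in% c(0, 1))) stop("event indicator must be 0 or 1")
  invisible(x)
}

# ---- S4 classes -------------------------------------------------------------

#' OmicsBundle: matched multi-omics layers over a shared sample set
#'
#' Container for matched molecular layers of one cohort. Continuous layers
#' (mRNA expression, lncRNA expression, methylation betas) are genes/probes x
#' samples matrices; the mutation layer is binary genes x samples; segments
#' and clinical data are data.frames keyed by sample. Every present layer has
#' exactly the bundle's samples, in the same order.
#'
#' @slot expression numeric matrix, log2-scale expression (genes x samples).
#' @slot lncrna optional numeric matrix of lncRNA expression, or NULL.
#' @slot methylation optional beta matrix (probes x samples), or NULL.
#' @slot mutations optional binary matrix (genes x samples), or NULL.
#' @slot segments optional segment data.frame, or NULL.
#' @slot clinical optional survival data.frame, or NULL.
#' @slot scaleTag character, "log2" or "linear", scale of `expression`.
#'
#' @export
setClass("OmicsBundle",
  representation(expression = "matrix", lncrna = "ANY", methylation = "ANY",
                 mutations = "ANY", segments = "ANY", clinical = "ANY",
                 scaleTag = "character"),
  prototype(lncrna = NULL, methylation = NULL, mutations = NULL,
            segments = NULL, clinical = NULL, scaleTag = "log2"))

setValidity("OmicsBundle", function(object) {
  ids <- colnames(object@expression)
  chk <- try(validateExpressionMatrix(object@expression), silent = TRUE)
  if (inherits(chk, "try-error")) return(conditionMessage(attr(chk, "condition")))
  for (nm in c("lncrna", "methylation", "mutations")) {
    m <- slot(object, nm)
    if (is.null(m)) next
    if (!identical(colnames(m), ids))
      return(paste0(nm, " samples differ from bundle samples"))
    chk <- try(switch(nm,
      lncrna      = validateExpressionMatrix(m, "lncrna"),
      methylation = validateBetaMatrix(m),
      mutations   = validateMutationMatrix(m)), silent = TRUE)
    if (inherits(chk, "try-error")) return(conditionMessage(attr(chk, "condition")))
  }
  if (!is.null(object@segments)) {
    chk <- try(validateSegmentTable(object@segments), silent = TRUE)
    if (inherits(chk, "try-error")) return(conditionMessage(attr(chk, "condition")))
    if (!all(object@segments$sample %in% ids))
      return("segments contain samples outside the bundle")
  }
  if (!is.null(object@clinical)) {
    chk <- try(validateSurvivalTable(object@clinical), silent = TRUE)
    if (inherits(chk, "try-error")) return(conditionMessage(attr(chk, "condition")))
    if (!identical(as.character(object@clinical$sample), ids))
      return("clinical samples differ from bundle samples (order matters)")
  }
  if (!object@scaleTag %in% c("log2", "linear"))
    return("scaleTag must be 'log2' or 'linear'")
  TRUE
})

#' PartitionEnsemble: per-algorithm partitions and their consensus
#'
#' @slot algorithms character, names of the algorithms that succeeded.
#' @slot partitions integer matrix samples x algorithms of cluster labels.
#' @slot consensus numeric n x n matrix; entry ij is the fraction of
#'   algorithms that co-assign samples i and j.
#' @slot labels named integer vector of final subtype labels (1..k, numbered
#'   by descending subtype size).
#' @slot k integer, number of subtypes requested.
#' @slot silhouette numeric, mean silhouette width on 1 - consensus.
#' @slot silhouetteSamples named numeric vector of per-sample widths.
#'
#' @export
setClass("PartitionEnsemble",
  representation(algorithms = "character", partitions = "matrix",
                 consensus = "matrix", labels = "integer", k = "integer",
                 silhouette = "numeric", silhouetteSamples = "numeric"))

setValidity("PartitionEnsemble", function(object) {
  M <- object@consensus
  if (nrow(M) != ncol(M)) return("consensus must be square")
  if (max(abs(M - t(M))) > 1e-12) return("consensus must be symmetric")
  if (any(M < -1e-12 | M > 1 + 1e-12)) return("consensus entries must be in [0,1]")
  if (max(abs(diag(M) - 1)) > 1e-12) return("consensus diagonal must be 1")
  if (length(object@labels) != nrow(M)) return("labels length != consensus dim")
  if (length(unique(object@labels)) != object@k)
    return("final labels must take exactly k values")
  TRUE
})

#' SignatureSet: named gene sets with optional per-gene weights
#'
#' @slot signatures named list of character vectors (gene ids).
#' @slot weights named list of numeric vectors (same lengths), or empty.
#' @slot description named character vector (GMT description field).
#'
#' @export
setClass("SignatureSet",
  representation(signatures = "list", weights = "list",
                 description = "character"),
  prototype(weights = list(), description = character()))

setValidity("SignatureSet", function(object) {
  if (is.null(names(object@signatures)) || any(names(object@signatures) == ""))
    return("signatures must be named")
  if (any(duplicated(names(object@signatures)))) return("duplicate signature names")
  if (any(lengths(object@signatures) == 0L)) return("empty signature")
  for (nm in names(object@weights)) {
    if (length(object@weights[[nm]]) != length(object@signatures[[nm]]))
      return(paste0("weights length mismatch for ", nm))
  }
  TRUE
})

#' SubtypeTemplates: per-subtype marker gene lists
#'
#' @slot templates named list (one entry per subtype) of ordered gene vectors.
#' @slot weights named list of numeric vectors (log2 fold changes), same shape.
#' @slot provenance list recording thresholds and derivation parameters.
#'
#' @export
setClass("SubtypeTemplates",
  representation(templates = "list", weights = "list", provenance = "list"),
  prototype(provenance = list()))

setValidity("SubtypeTemplates", function(object) {
  g <- unlist(object@templates, use.names = FALSE)
  if (any(duplicated(g))) return("template gene lists must be pairwise disjoint")
  if (!identical(names(object@templates), names(object@weights)))
    return("templates and weights must share names")
  TRUE
})

#' PamPanel: nearest-shrunken-centroid scores and the reduced gene panel
#'
#' @slot scores numeric matrix genes x subtypes of standardized centroid scores.
#' @slot thresholds named numeric vector, per-subtype selection thresholds.
#' @slot selected named list of genes selected per subtype.
#' @slot panel character, the union panel.
#'
#' @export
setClass("PamPanel",
  representation(scores = "matrix", thresholds = "numeric",
                 selected = "list", panel = "character"))

#' NtpResult: nearest-template predictions for one cohort
#'
#' @slot table data.frame with one row per sample: assigned `subtype`, one
#'   `dist.<subtype>` column per template (cosine distance), resampling `p`,
#'   Benjamini-Hochberg `fdr`, and logical `confident`.
#' @slot coverage numeric, fraction of template genes measured in the cohort.
#'
#' @export
setClass("NtpResult",
  representation(table = "data.frame", coverage = "numeric"))

#' KSelectionReport: evidence for the choice of cluster number
#'
#' @slot kRange integer vector of evaluated k (gap additionally includes k=1).
#' @slot cpi named numeric, partition-stability index per k.
#' @slot gap data.frame with columns k, gap, se.
#' @slot silhouette named numeric, mean consensus silhouette per k (optional).
#' @slot chosenK integer.
#' @slot ruleUsed character description of the decision rule.
#'
#' @export
setClass("KSelectionReport",
  representation(kRange = "integer", cpi = "numeric", gap = "data.frame",
                 silhouette = "numeric", chosenK = "integer",
                 ruleUsed = "character"),
  prototype(silhouette = numeric()))
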