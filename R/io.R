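# Readers and writers for the plain-text formats the pipeline touches:
# expression TSV / GCT 1.2, methylation beta TSV, MAF(-lite) mutation tables,
# SEG copy-number segments, GMT gene sets, clinical TSV. All dialects are
# tab-delimited UTF-8 with '.' decimal separator.

.readMatrixTsv <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2L) stop("malformed header in ", path,
                          ": need id column + >=1 sample column (line 1)")
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop("non-numeric cell in ", what, " at row ", bad[1L] + 1L,
             ", column '", names(vals)[j], "' of ", path)
      vals[[j]] <- vn
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

.collapseDuplicateRows <- function(m, what) {
  if (!anyDuplicated(rownames(m))) return(m)
  dup <- unique(rownames(m)[duplicated(rownames(m))])
  warning(length(dup), " duplicate ", what,
          " id(s) collapsed by per-sample maximum (e.g. ",
          paste(head(dup, 3), collapse = ", "), ")", call. = FALSE)
  grp <- rownames(m)
  keep <- !duplicated(grp)
  res <- m[keep, , drop = FALSE]
  for (g in dup) {
    res[g, ] <- apply(m[grp == g, , drop = FALSE], 2L, max)
  }
  res
}

#' Read a gene expression matrix (TSV or GCT 1.2)
#'
#' TSV: first column gene ids, header row sample ids. GCT: the standard
#' "#1.2" + dimensions header is honored and the Description column dropped.
#' Duplicate gene rows are collapsed by per-sample maximum (with a warning).
#'
#' @param path file path.
#' @param format "tsv" or "gct".
#' @param scaleTag "log2" (default; log2(TPM+1)-like) or "linear", recorded on
#'   the returned matrix as attribute `scale_tag`.
#' @return numeric genes x samples matrix with `scale_tag` attribute.
#' @export
readExpression <- function(path, format = c("tsv", "gct"), scaleTag = "log2") {
  format <- match.arg(format)
  if (format == "gct") {
    ln <- readLines(path, n = 2L)
    if (length(ln) < 2L || !startsWith(ln[1L], "#1.2"))
      stop("malformed GCT header in ", path, ": line 1 must be '#1.2'")
    dims <- suppressWarnings(as.integer(strsplit(ln[2L], "\t")[[1L]][1:2]))
    if (any(is.na(dims)))
      stop("malformed GCT header in ", path, ": line 2 must give dimensions")
    df <- read.delim(path, skip = 2L, header = TRUE, sep = "\t",
                     check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(df) != dims[1L])
      stop("GCT declares ", dims[1L], " rows but has ", nrow(df))
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -(1:2), drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric cell in GCT body of ", path)
    rownames(m) <- ids
  } else {
    m <- .readMatrixTsv(path, "expression")
  }
  m <- .collapseDuplicateRows(m, "gene")
  validateExpressionMatrix(m)
  attr(m, "scale_tag") <- match.arg(scaleTag, c("log2", "linear"))
  m
}

#' Read a methylation beta matrix (TSV)
#'
#' @param path file path; first column probe ids, header row sample ids.
#' @return probes x samples matrix of beta values in \[0, 1\].
#' @export
readBeta <- function(path) {
  m <- .readMatrixTsv(path, "methylation")
  m <- .collapseDuplicateRows(m, "probe")
  validateBetaMatrix(m)
  m
}

#' Read a MAF(-lite) somatic mutation table into a binary gene x sample matrix
#'
#' Only three columns are required (Hugo_Symbol, Tumor_Sample_Barcode,
#' Variant_Classification); full MAF files work, extra columns are ignored.
#' Variants classified "Silent" are excluded by default.
#'
#' @param path file path.
#' @param excludeSilent drop rows with Variant_Classification == "Silent".
#' @return binary genes x samples matrix (1 = at least one somatic variant).
#' @export
readMafLite <- function(path, excludeSilent = TRUE) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#", quote = "")
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("MAF missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (excludeSilent) df <- df[df$Variant_Classification != "Silent", , drop = FALSE]
  genes <- sort(unique(df$Hugo_Symbol))
  samples <- sort(unique(df$Tumor_Sample_Barcode))
  m <- matrix(0, length(genes), length(samples),
              dimnames = list(genes, samples))
  if (nrow(df)) m[cbind(match(df$Hugo_Symbol, genes),
                        match(df$Tumor_Sample_Barcode, samples))] <- 1
  if (nrow(m)) validateMutationMatrix(m)
  m
}

#' Read a SEG copy-number segment file
#'
#' Standard 6-column SEG (sample, chromosome, start, end, num_mark, seg_mean);
#' 5-column files without num_mark are accepted. Coordinates are 1-based
#' inclusive.
#'
#' @param path file path.
#' @return data.frame with columns sample, chromosome, start, end, log2ratio.
#' @export
readSegments <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) == 6L) df <- df[, c(1:4, 6L)]
  if (ncol(df) != 5L) stop("SEG file must have 5 or 6 columns, got ", ncol(df))
  names(df) <- c("sample", "chromosome", "start", "end", "log2ratio")
  df$sample <- as.character(df$sample)
  df$chromosome <- as.character(df$chromosome)
  bad <- which(df$start > df$end)
  if (length(bad)) stop("SEG start > end at line ", bad[1L] + 1L, " of ", path)
  validateSegmentTable(df)
  df
}

#' Read a GMT gene-set file
#'
#' Each line: set name, description, then gene ids. The description is
#' preserved but unused downstream.
#'
#' @param path file path.
#' @return a [SignatureSet-class] object.
#' @export
readGmt <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short)) stop("GMT line ", short[1L],
                          " has fewer than 3 fields (name, description, genes)")
  nms <- vapply(parts, `[[`, "", 1L)
  desc <- vapply(parts, `[[`, "", 2L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- nms
  names(desc) <- nms
  new("SignatureSet", signatures = sets, description = desc)
}

#' Read a clinical/survival table (TSV)
#'
#' Requires columns sample, time (months), event (0/1); optional group and
#' risk_score columns are carried through.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
readClinical <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  df$sample <- as.character(df$sample)
  validateSurvivalTable(df)
  df
}

# ---- writers ----------------------------------------------------------------

#' Write a matrix as TSV (id column + sample header)
#' @param m matrix with dimnames.
#' @param path output path.
#' @param idColumn name of the first column.
#' @return `path`, invisibly.
#' @export
writeMatrixTsv <- function(m, path, idColumn = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- idColumn
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix in GCT 1.2 format
#' @param m genes x samples matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGct <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
  df <- data.frame(Name = rownames(m), Description = "na", m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a SignatureSet as GMT
#' @param x a `SignatureSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(x, path) {
  desc <- x@description
  ln <- vapply(names(geneSets(x)), function(nm) {
    d <- if (nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, geneSets(x)[[nm]]), collapse = "\t")
  }, "")
  writeLines(ln, path)
  invisible(path)
}

#' Write a segment table as 6-column SEG
#' @param seg data.frame (sample, chromosome, start, end, log2ratio).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSegments <- function(seg, path) {
  out <- data.frame(ID = seg$sample, chrom = seg$chromosome,
                    loc.start = seg$start, loc.end = seg$end,
                    num.mark = NA_integer_, seg.mean = seg$log2ratio)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- bundle construction ----------------------------------------------------

#' Assemble matched layers into an OmicsBundle
#'
#' Intersects the sample sets of all provided layers, orders the shared
#' samples lexicographically, reorders every layer to match, and reports how
#' many samples each layer lost.
#'
#' @param expression genes x samples expression matrix (required).
#' @param lncrna,methylation,mutations optional layer matrices.
#' @param segments optional segment data.frame (rows outside the shared set
#'   are dropped).
#' @param clinical optional survival data.frame.
#' @param scaleTag scale of `expression` ("log2" or "linear").
#' @return an [OmicsBundle-class].
#' @export
alignBundle <- function(expression, lncrna = NULL, methylation = NULL,
                        mutations = NULL, segments = NULL, clinical = NULL,
                        scaleTag = "log2") {
  layers <- list(expression = colnames(expression))
  if (!is.null(lncrna)) layers$lncrna <- colnames(lncrna)
  if (!is.null(methylation)) layers$methylation <- colnames(methylation)
  if (!is.null(mutations)) layers$mutations <- colnames(mutations)
  if (!is.null(clinical)) layers$clinical <- as.character(clinical$sample)
  shared <- Reduce(intersect, layers)
  if (!length(shared))
    stop("no shared samples across layers; per-layer counts: ",
         paste(names(layers), lengths(layers), sep = "=", collapse = ", "))
  shared <- sort(shared)
  dropped <- vapply(layers, function(s) length(setdiff(s, shared)), 1L)
  if (any(dropped > 0L))
    message("alignBundle: dropped samples per layer: ",
            paste(names(dropped), dropped, sep = "=", collapse = ", "))
  sub <- function(m) if (is.null(m)) NULL else m[, shared, drop = FALSE]
  cl <- NULL
  if (!is.null(clinical)) {
    cl <- clinical[match(shared, clinical$sample), , drop = FALSE]
    rownames(cl) <- NULL
  }
  sg <- NULL
  if (!is.null(segments)) {
    sg <- segments[segments$sample %in% shared, , drop = FALSE]
    rownames(sg) <- NULL
  }
  new("OmicsBundle", expression = sub(expression), lncrna = sub(lncrna),
      methylation = sub(methylation), mutations = sub(mutations),
      segments = sg, clinical = cl, scaleTag = scaleTag)
}
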