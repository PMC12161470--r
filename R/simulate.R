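# Seeded generator of matched multi-omics cohorts with planted subtype
# structure. The defaults emulate the statistical shape of a 90-sample
# non-APL AML discovery cohort: three subtypes, 50 marker mRNAs per subtype
# on a log2 expression scale, globally hypermethylated CpG background with
# per-subtype demethylation blocks, sparse binary mutations with
# subtype-enriched genes, a more copy-number-unstable subtype 1, and
# exponential survival ordered worst-to-best across subtypes 1..3 (median
# 18 / 27 / 45 months).

.withSeed <- function(seed, expr) {
  # evaluate expr under a local RNG state so the generator never perturbs
  # (or depends on) the caller's random stream
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.subSeed <- function(seed, offset) (as.integer(seed) * 97L + offset) %% 2147483629L

#' Configuration of a simulated multi-omics cohort
#'
#' All arguments have defaults describing the reference study conditions;
#' `simulateCohort()` consumes the returned object.
#'
#' @param nSamples number of samples.
#' @param kTrue number of planted subtypes.
#' @param subtypeProps subtype proportions (must sum to 1); default equal.
#' @param nGenes,nLnc,nProbes,nMutGenes feature counts of the mRNA, lncRNA,
#'   methylation and mutation layers.
#' @param nMarkersPerSubtype marker mRNAs planted per subtype (disjoint sets).
#' @param nLncMarkersPerSubtype marker lncRNAs planted per subtype.
#' @param effectSize mean log2 shift added to a subtype's marker genes in its
#'   own samples. This is also the master switch for all planted structure:
#'   at 0, the methylation blocks, mutation enrichment and the extra
#'   copy-number instability of subtype 1 are disabled too, giving a fully
#'   null cohort.
#' @param noiseSd residual SD of log2 expression.
#' @param demethBlockSize number of CpG probes per subtype losing methylation
#'   in that subtype (beta ~ Beta(2,8) instead of the Beta(8,2) background).
#' @param nMutEnrichedPerSubtype mutation genes enriched per subtype.
#' @param mutRateBackground,mutRateEnriched Bernoulli rates of the binary
#'   mutation calls outside/inside a subtype's enriched genes.
#' @param hazardBySubtype exponential event rates per subtype; the default
#'   log(2)/c(18, 27, 45) gives median overall survival of 18, 27 and 45
#'   months for subtypes 1..3.
#' @param censorRate expected fraction of administratively censored samples.
#' @param seed master seed; every layer draws from a named substream.
#' @return a validated list of class `SimConfig`.
#' @export
simConfig <- function(nSamples = 90L, kTrue = 3L,
                      subtypeProps = rep(1 / kTrue, kTrue),
                      nGenes = 1500L, nLnc = 800L, nProbes = 1500L,
                      nMutGenes = 80L, nMarkersPerSubtype = 50L,
                      nLncMarkersPerSubtype = 30L,
                      effectSize = 2.0, noiseSd = 1.0,
                      demethBlockSize = 50L, nMutEnrichedPerSubtype = 5L,
                      mutRateBackground = 0.02, mutRateEnriched = 0.30,
                      hazardBySubtype = log(2) / c(18, 27, 45)[seq_len(kTrue)],
                      censorRate = 0.3, seed = 1L) {
  cfg <- list(nSamples = as.integer(nSamples), kTrue = as.integer(kTrue),
              subtypeProps = subtypeProps, nGenes = as.integer(nGenes),
              nLnc = as.integer(nLnc), nProbes = as.integer(nProbes),
              nMutGenes = as.integer(nMutGenes),
              nMarkersPerSubtype = as.integer(nMarkersPerSubtype),
              nLncMarkersPerSubtype = as.integer(nLncMarkersPerSubtype),
              effectSize = effectSize, noiseSd = noiseSd,
              demethBlockSize = as.integer(demethBlockSize),
              nMutEnrichedPerSubtype = as.integer(nMutEnrichedPerSubtype),
              mutRateBackground = mutRateBackground,
              mutRateEnriched = mutRateEnriched,
              hazardBySubtype = hazardBySubtype, censorRate = censorRate,
              seed = as.integer(seed))
  with(cfg, {
    if (abs(sum(subtypeProps) - 1) > 1e-8) stop("subtypeProps must sum to 1")
    if (length(subtypeProps) != kTrue) stop("subtypeProps length must equal kTrue")
    if (any(c(nSamples, kTrue, nGenes, nProbes, nMutGenes) <= 0L))
      stop("all counts must be positive")
    if (nMarkersPerSubtype * kTrue > nGenes)
      stop("nMarkersPerSubtype x kTrue exceeds nGenes")
    if (nLncMarkersPerSubtype * kTrue > nLnc)
      stop("nLncMarkersPerSubtype x kTrue exceeds nLnc")
    if (demethBlockSize * kTrue > nProbes)
      stop("demethBlockSize x kTrue exceeds nProbes")
    if (nMutEnrichedPerSubtype * kTrue > nMutGenes)
      stop("nMutEnrichedPerSubtype x kTrue exceeds nMutGenes")
    if (any(c(mutRateBackground, mutRateEnriched) <= 0) ||
        any(c(mutRateBackground, mutRateEnriched) >= 1))
      stop("mutation rates must be in (0,1)")
    if (censorRate < 0 || censorRate >= 1) stop("censorRate must be in [0,1)")
    if (length(hazardBySubtype) != kTrue || any(hazardBySubtype <= 0))
      stop("hazardBySubtype must be kTrue positive rates")
  })
  class(cfg) <- "SimConfig"
  cfg
}

.markerIdx <- function(k, perSub) {
  # disjoint marker blocks at the head of the feature list
  lapply(seq_len(k), function(s) seq_len(perSub) + (s - 1L) * perSub)
}

.simExprLayer <- function(n, p, labels, markers, effect, noiseSd, prefix) {
  m <- matrix(rnorm(p * n, 0, noiseSd), p, n,
              dimnames = list(sprintf("%s%04d", prefix, seq_len(p)),
                              names(labels)))
  for (s in seq_along(markers))
    m[markers[[s]], labels == s] <- m[markers[[s]], labels == s] + effect
  m
}

#' Simulate a matched multi-omics cohort with planted subtypes
#'
#' @param config a [simConfig()] object.
#' @return list with elements `bundle` (an [OmicsBundle-class] including
#'   segments and clinical survival), `labels` (named integer vector of true
#'   subtypes), and `markers` (per-layer lists of planted feature ids by
#'   subtype).
#' @export
simulateCohort <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  cfg <- config
  n <- cfg$nSamples; k <- cfg$kTrue
  samples <- sprintf("S%03d", seq_len(n))

  labels <- .withSeed(.subSeed(cfg$seed, 1L), {
    counts <- floor(cfg$subtypeProps * n)
    rem <- n - sum(counts)
    if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
    sample(rep(seq_len(k), counts))
  })
  names(labels) <- samples

  mIdx <- .markerIdx(k, cfg$nMarkersPerSubtype)
  expr <- .withSeed(.subSeed(cfg$seed, 2L),
    .simExprLayer(n, cfg$nGenes, labels, mIdx, cfg$effectSize, cfg$noiseSd, "GENE"))
  lIdx <- .markerIdx(k, cfg$nLncMarkersPerSubtype)
  lnc <- .withSeed(.subSeed(cfg$seed, 3L),
    .simExprLayer(n, cfg$nLnc, labels, lIdx, cfg$effectSize, cfg$noiseSd, "LNC"))

  # methylation: hypermethylated Beta(8,2) background; per-subtype blocks of
  # probes drop to Beta(2,8) in that subtype's samples (demethylators)
  bIdx <- .markerIdx(k, cfg$demethBlockSize)
  meth <- .withSeed(.subSeed(cfg$seed, 4L), {
    m <- matrix(rbeta(cfg$nProbes * n, 8, 2), cfg$nProbes, n,
                dimnames = list(sprintf("cg%06d", seq_len(cfg$nProbes)), samples))
    if (cfg$effectSize > 0) {
      for (s in seq_len(k)) {
        sel <- labels == s
        m[bIdx[[s]], sel] <- rbeta(length(bIdx[[s]]) * sum(sel), 2, 8)
      }
    }
    m
  })

  # mutations: sparse Bernoulli background, per-subtype enriched gene sets
  gIdx <- .markerIdx(k, cfg$nMutEnrichedPerSubtype)
  mut <- .withSeed(.subSeed(cfg$seed, 5L), {
    m <- matrix(rbinom(cfg$nMutGenes * n, 1, cfg$mutRateBackground),
                cfg$nMutGenes, n,
                dimnames = list(sprintf("MUT%03d", seq_len(cfg$nMutGenes)), samples))
    if (cfg$effectSize > 0) {
      for (s in seq_len(k)) {
        sel <- labels == s
        m[gIdx[[s]], sel] <- rbinom(length(gIdx[[s]]) * sum(sel), 1,
                                    cfg$mutRateEnriched)
      }
    }
    m
  })

  # copy-number segments: 10 chromosomes x 10 bins of 10 Mb; subtype 1 is
  # copy-number unstable (more bins at |log2| >= 0.3, loss-biased)
  seg <- .withSeed(.subSeed(cfg$seed, 6L), {
    nChr <- 10L; nBin <- 10L; binLen <- 1e7
    altRate <- if (cfg$effectSize > 0) ifelse(labels == 1L, 0.15, 0.04)
               else rep(0.04, n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      nb <- nChr * nBin
      lr <- rnorm(nb, 0, 0.05)
      lr <- pmin(pmax(lr, -0.29), 0.29)          # neutral bins stay sub-threshold
      alt <- runif(nb) < altRate[i]
      sign <- ifelse(runif(nb) < ifelse(labels[i] == 1L, 0.6, 0.5), -1, 1)
      lr[alt] <- sign[alt] * runif(sum(alt), 0.35, 0.9)
      rows[[i]] <- data.frame(
        sample = samples[i],
        chromosome = paste0("chr", rep(seq_len(nChr), each = nBin)),
        start = rep((seq_len(nBin) - 1L) * binLen + 1, nChr),
        end = rep(seq_len(nBin) * binLen, nChr),
        log2ratio = lr, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })

  # survival: exponential event times by subtype hazard; with probability
  # censorRate a subject is administratively censored at U(0, T)
  clin <- .withSeed(.subSeed(cfg$seed, 7L), {
    t0 <- rexp(n, cfg$hazardBySubtype[labels])
    cens <- runif(n) < cfg$censorRate
    tim <- ifelse(cens, runif(n, 0, 1) * t0, t0)
    data.frame(sample = samples, time = pmax(tim, 1e-3),
               event = as.integer(!cens),
               group = paste0("subtype", labels), stringsAsFactors = FALSE)
  })

  bundle <- alignBundle(expression = expr, lncrna = lnc, methylation = meth,
                        mutations = mut, segments = seg, clinical = clin)
  markers <- list(
    mrna = lapply(mIdx, function(i) rownames(expr)[i]),
    lncrna = lapply(lIdx, function(i) rownames(lnc)[i]),
    methylation = lapply(bIdx, function(i) rownames(meth)[i]),
    mutations = lapply(gIdx, function(i) rownames(mut)[i]))
  list(bundle = bundle, labels = labels[sampleIDs(bundle)], markers = markers)
}

#' Simulate a normal (reference) methylation cohort
#'
#' Probes eligible for demethylation calling (the planted blocks) are strongly
#' methylated in the reference (Beta(12,2), so beta > 0.8 with high
#' probability); all other probes are uninformative (Beta(2,2)).
#'
#' @param config a [simConfig()] object (defines probe ids and blocks).
#' @param nNormal number of reference samples.
#' @return probes x nNormal beta matrix matching the cohort's probe ids.
#' @export
simulateNormalReference <- function(config = simConfig(), nNormal = 20L) {
  stopifnot(inherits(config, "SimConfig"))
  cfg <- config
  if (cfg$nProbes == 0L)
    return(matrix(numeric(0), 0, nNormal,
                  dimnames = list(character(0),
                                  sprintf("N%03d", seq_len(nNormal)))))
  elig <- unlist(.markerIdx(cfg$kTrue, cfg$demethBlockSize))
  .withSeed(.subSeed(cfg$seed, 8L), {
    m <- matrix(rbeta(cfg$nProbes * nNormal, 2, 2), cfg$nProbes, nNormal,
                dimnames = list(sprintf("cg%06d", seq_len(cfg$nProbes)),
                                sprintf("N%03d", seq_len(nNormal))))
    m[elig, ] <- rbeta(length(elig) * nNormal, 12, 2)
    m
  })
}

#' Write a simulated cohort to disk in the package's exchange formats
#'
#' Writes expression/lncRNA/methylation TSVs, a MAF-lite mutation table, a
#' SEG file, a clinical TSV, plus truth files (labels and planted markers).
#'
#' @param sim result of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  b <- sim$bundle
  writeMatrixTsv(omicsLayer(b, "expression"), file.path(dir, "expression.tsv"), "gene")
  writeMatrixTsv(omicsLayer(b, "lncrna"), file.path(dir, "lncrna.tsv"), "gene")
  writeMatrixTsv(omicsLayer(b, "methylation"), file.path(dir, "methylation.tsv"), "probe")
  mut <- omicsLayer(b, "mutations")
  idx <- which(mut == 1, arr.ind = TRUE)
  maf <- data.frame(Hugo_Symbol = rownames(mut)[idx[, 1L]],
                    Tumor_Sample_Barcode = colnames(mut)[idx[, 2L]],
                    Variant_Classification = "Missense_Mutation")
  write.table(maf, file.path(dir, "mutations.maf"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeSegments(segmentTable(b), file.path(dir, "segments.seg"))
  write.table(clinicalTable(b), file.path(dir, "clinical.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = names(sim$labels), subtype = sim$labels),
              file.path(dir, "true_labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  mk <- sim$markers
  mkdf <- do.call(rbind, lapply(names(mk), function(layer)
    do.call(rbind, lapply(seq_along(mk[[layer]]), function(s)
      data.frame(layer = layer, subtype = s, feature = mk[[layer]][[s]])))))
  write.table(mkdf, file.path(dir, "true_markers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
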