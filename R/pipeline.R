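# End-to-end orchestration: discovery (feature selection -> k selection ->
# consensus ensemble -> templates -> panel -> profiling -> survival) and
# classification of new cohorts with existing templates. Configs are plain
# YAML; every artifact is a text file; a manifest records input hashes, the
# seed and the package version so a rerun with the same config and seed is
# bit-identical.

.readRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config
}

.loadBundleFromConfig <- function(cfg) {
  inp <- cfg$inputs
  if (is.null(inp$expression)) stop("config must name an expression input")
  expr <- readExpression(inp$expression)
  lnc <- if (!is.null(inp$lncrna)) readExpression(inp$lncrna) else NULL
  meth <- if (!is.null(inp$methylation)) readBeta(inp$methylation) else NULL
  mut <- if (!is.null(inp$mutations)) readMafLite(inp$mutations) else NULL
  seg <- if (!is.null(inp$segments)) readSegments(inp$segments) else NULL
  cl <- if (!is.null(inp$clinical)) readClinical(inp$clinical) else NULL
  alignBundle(expression = expr, lncrna = lnc, methylation = meth,
              mutations = mut, segments = seg, clinical = cl)
}

.writeManifest <- function(outDir, cfg, seed, extra = list()) {
  paths <- unlist(cfg$inputs)
  hashes <- if (length(paths)) as.list(tools::md5sum(paths)) else list()
  manifest <- c(list(package = "MOSubtype",
                     version = as.character(packageVersion("MOSubtype")),
                     seed = seed, inputs = hashes, config = cfg), extra)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the discovery workflow on one cohort
#'
#' Stages: feature selection, cluster-number selection (unless `k` is fixed
#' in the config), the consensus ensemble, subtype templates, the PAM panel,
#' genome-burden profiling (when segments are present) and survival
#' separation (when clinical data are present). All artifacts are written to
#' `outDir` as TSV/GMT/JSON.
#'
#' @param config a YAML path or list. Recognized keys: `inputs` (expression,
#'   lncrna, methylation, mutations, segments, clinical, normal_reference
#'   paths), `features` (layers, n_expr, n_lnc, n_meth, mut_min_frac),
#'   `k` or `k_range`, `algorithms`, `templates` (top_n, fdr_max, lfc_min),
#'   `panel` (thresholds), `seed`.
#' @param outDir output directory.
#' @param bundle optionally, a pre-built [OmicsBundle-class] (skips reading
#'   the input files).
#' @return invisibly, a list with the main artifacts (selection report,
#'   kReport, ensemble, templates, panel, burden, survival).
#' @export
runDiscovery <- function(config, outDir, bundle = NULL) {
  cfg <- .readRunConfig(config)
  seed <- as.integer(cfg$seed %||% 1L)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(bundle)) bundle <- .loadBundleFromConfig(cfg)

  fs <- cfg$features %||% list()
  layers <- fs$layers %||% c("expression", "lncrna", "methylation",
                             "mutations")
  layers <- intersect(layers,
                      c("expression", "lncrna", "methylation", "mutations"))
  normal <- if (!is.null(cfg$inputs$normal_reference))
    readBeta(cfg$inputs$normal_reference) else NULL
  ci <- buildClusterInput(bundle, layers = layers,
                          nExpr = fs$n_expr %||% 1000L,
                          nLnc = fs$n_lnc %||% 1000L,
                          nMeth = fs$n_meth %||% 1000L,
                          mutMinFrac = fs$mut_min_frac %||% 0.03,
                          normalReference = normal)
  write.table(ci$report, file.path(outDir, "selection_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  kReport <- NULL
  if (!is.null(cfg$k)) {
    k <- as.integer(cfg$k)
  } else {
    kr <- cfg$k_range %||% c(2L, 5L)
    kReport <- kSelection(ci$bundle, kMin = min(kr), kMax = max(kr),
                          seed = .subSeed(seed, 21L))
    k <- chosenK(kReport)
    kjson <- list(kRange = kReport@kRange, cpi = as.list(kReport@cpi),
                  gap = kReport@gap, chosenK = k, rule = kReport@ruleUsed)
    jsonlite::write_json(kjson, file.path(outDir, "k_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  algorithms <- cfg$algorithms %||% c("snf", "monti", "coca", "intnmf",
                                      "lra", "nemo")
  ens <- consensusEnsemble(ci$bundle, k, algorithms = algorithms,
                           seed = .subSeed(seed, 22L))
  labs <- subtypeLabels(ens)
  write.table(data.frame(sample = names(labs), subtype = labs),
              file.path(outDir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeMatrixTsv(consensusMatrix(ens), file.path(outDir, "consensus_matrix.tsv"),
                 "sample")
  write.table(data.frame(sample = rownames(algorithmPartitions(ens)),
                         algorithmPartitions(ens)),
              file.path(outDir, "algorithm_labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  sil <- data.frame(sample = names(ens@silhouetteSamples),
                    silhouette = ens@silhouetteSamples)
  write.table(sil, file.path(outDir, "silhouette.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  tp <- cfg$templates %||% list()
  templates <- deriveTemplates(omicsLayer(bundle, "expression"), labs,
                               topN = tp$top_n %||% 50L,
                               fdrMax = tp$fdr_max %||% 0.05,
                               lfcMin = tp$lfc_min %||% 1.0)
  writeGmt(new("SignatureSet", signatures = templateGenes(templates),
               description = setNames(rep("subtype template",
                                          length(templateGenes(templates))),
                                      names(templateGenes(templates)))),
           file.path(outDir, "templates.gmt"))
  wdf <- do.call(rbind, lapply(names(templateWeights(templates)), function(nm)
    data.frame(subtype = nm, gene = names(templateWeights(templates)[[nm]]),
               log2fc = unname(templateWeights(templates)[[nm]]))))
  write.table(wdf, file.path(outDir, "template_weights.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  panel <- NULL
  thr <- cfg$panel$thresholds
  if (!is.null(thr)) {
    sc <- pamScores(omicsLayer(bundle, "expression"), labs)
    panel <- reducePanel(sc, unlist(thr))
    pdf <- do.call(rbind, lapply(names(panel@selected), function(nm) {
      g <- panel@selected[[nm]]
      if (!length(g)) return(NULL)
      data.frame(subtype = nm, gene = g, score = sc[g, nm])
    }))
    write.table(pdf, file.path(outDir, "pam_panel.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  burden <- NULL
  if (!is.null(segmentTable(bundle))) {
    burden <- genomeBurden(segmentTable(bundle))
    burden$subtype <- labs[burden$sample]
    write.table(burden, file.path(outDir, "genome_burden.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  survRep <- NULL
  if (!is.null(clinicalTable(bundle))) {
    cl <- clinicalTable(bundle)
    grp <- paste0("subtype", labs[cl$sample])
    lr <- logrank(cl, grp, pairwise = TRUE)
    med <- medianSurvival(cl, grp)
    survRep <- list(logrank = lr[c("chisq", "df", "p")],
                    pairwise = lr$pairwise, medianOS = as.list(med))
    jsonlite::write_json(survRep, file.path(outDir, "survival_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  .writeManifest(outDir, cfg, seed,
                 list(k = k, algorithms = as.list(ens@algorithms)))
  invisible(list(selection = ci$report, kReport = kReport, ensemble = ens,
                 templates = templates, panel = panel, burden = burden,
                 survival = survRep))
}

#' Classify a new cohort with existing subtype templates
#'
#' Reads the cohort expression and a templates GMT (plus optional weights),
#' runs [ntpClassify()], and, when clinical data are supplied, the survival
#' separation of the predicted subtypes.
#'
#' @param config YAML path or list with keys: `inputs` (expression, optional
#'   clinical), `templates` (path to a GMT), `ntp` (n_resamples, fdr_max,
#'   weighting), `seed`.
#' @param outDir output directory.
#' @param expr,templates optionally pass the objects directly.
#' @return invisibly, a list with `ntp` (an [NtpResult-class]) and `survival`.
#' @export
runClassify <- function(config, outDir, expr = NULL, templates = NULL) {
  cfg <- .readRunConfig(config)
  seed <- as.integer(cfg$seed %||% 1L)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(expr)) {
    if (is.null(cfg$inputs$expression)) stop("config must name an expression input")
    expr <- readExpression(cfg$inputs$expression)
  }
  if (ncol(expr) == 0L) stop("cohort is empty")
  if (is.null(templates)) {
    if (is.null(cfg$templates)) stop("config must name a templates GMT")
    sig <- readGmt(cfg$templates)
    templates <- new("SubtypeTemplates", templates = geneSets(sig),
                     weights = lapply(geneSets(sig), function(g)
                       setNames(rep(1, length(g)), g)),
                     provenance = list(source = cfg$templates))
  }
  ntpCfg <- cfg$ntp %||% list()
  res <- ntpClassify(expr, templates,
                     nResamples = ntpCfg$n_resamples %||% 1000L,
                     fdrMax = ntpCfg$fdr_max %||% 0.05,
                     weighting = ntpCfg$weighting %||% "binary",
                     seed = .subSeed(seed, 31L))
  write.table(ntpTable(res), file.path(outDir, "ntp_results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  survRep <- NULL
  if (!is.null(cfg$inputs$clinical)) {
    cl <- readClinical(cfg$inputs$clinical)
    common <- intersect(cl$sample, ntpTable(res)$sample)
    cl <- cl[match(common, cl$sample), ]
    grp <- subtypeLabels(res)[common]
    if (length(unique(grp)) >= 2L) {
      lr <- logrank(cl, grp, pairwise = TRUE)
      survRep <- list(logrank = lr[c("chisq", "df", "p")],
                      pairwise = lr$pairwise,
                      medianOS = as.list(medianSurvival(cl, grp)))
      jsonlite::write_json(survRep, file.path(outDir, "survival_report.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
  }
  .writeManifest(outDir, cfg, seed, list(coverage = res@coverage))
  invisible(list(ntp = res, survival = survRep))
}
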