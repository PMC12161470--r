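# Survival separation and model-comparison statistics: Kaplan-Meier curves,
# log-rank tests (overall and pairwise with BH adjustment), Harrell's
# concordance index, and a paired-bootstrap comparison of two risk scores.
# The product-limit, log-rank and concordance computations are delegated to
# the survival package.

#' @importFrom survival Surv survfit survdiff concordance
NULL

.survCheck <- function(table) {
  validateSurvivalTable(table)
  table
}

#' Kaplan-Meier curves per group
#'
#' @param table survival data.frame (sample, time, event, optional group).
#' @param group grouping vector; defaults to the table's `group` column, or a
#'   single group if absent.
#' @return named list, one entry per group: data.frame (time, surv, nRisk,
#'   nEvent) plus attributes `median` (NA when never reached) and `n`.
#' @export
kmFit <- function(table, group = NULL) {
  .survCheck(table)
  if (is.null(group)) group <- table$group %||% rep("all", nrow(table))
  stopifnot(length(group) == nrow(table))
  out <- list()
  for (g in sort(unique(group))) {
    sel <- group == g
    fit <- survival::survfit(survival::Surv(table$time[sel],
                                            table$event[sel]) ~ 1)
    curve <- data.frame(time = fit$time, surv = fit$surv,
                        nRisk = fit$n.risk, nEvent = fit$n.event)
    med <- unname(summary(fit)$table["median"])
    attr(curve, "median") <- med
    attr(curve, "n") <- sum(sel)
    out[[as.character(g)]] <- curve
  }
  out
}

#' Median survival per group
#'
#' @param table survival data.frame.
#' @param group grouping vector (defaults as in [kmFit()]).
#' @return named numeric vector of medians (NA when the curve never reaches
#'   0.5).
#' @export
medianSurvival <- function(table, group = NULL) {
  curves <- kmFit(table, group)
  vapply(curves, function(cv) as.numeric(attr(cv, "median")), 1)
}

#' Log-rank test between survival groups
#'
#' Overall g-group test (df = g - 1) and, optionally, all pairwise tests with
#' Benjamini-Hochberg adjustment. Empty groups are dropped with a warning.
#'
#' @param table survival data.frame.
#' @param group grouping vector (defaults as in [kmFit()]).
#' @param pairwise also run all pairwise tests.
#' @return list with `chisq`, `df`, `p`, and (if requested) `pairwise`
#'   (data.frame: groupA, groupB, chisq, p, fdr).
#' @export
logrank <- function(table, group = NULL, pairwise = FALSE) {
  .survCheck(table)
  if (is.null(group)) group <- table$group %||% stop("no grouping available")
  group <- as.character(group)
  keep <- !is.na(group)
  if (any(!keep)) { warning("dropping samples with missing group"); }
  tb <- table[keep, ]; group <- group[keep]
  gl <- sort(unique(group))
  if (length(gl) < 2L) stop("need >= 2 non-empty groups")
  sd1 <- survival::survdiff(survival::Surv(tb$time, tb$event) ~ group)
  df <- length(gl) - 1L
  res <- list(chisq = unname(sd1$chisq), df = df,
              p = stats::pchisq(sd1$chisq, df, lower.tail = FALSE))
  if (pairwise) {
    pairs <- utils::combn(gl, 2L)
    pw <- apply(pairs, 2L, function(pr) {
      sel <- group %in% pr
      s <- survival::survdiff(survival::Surv(tb$time[sel], tb$event[sel]) ~
                                group[sel])
      c(chisq = unname(s$chisq),
        p = stats::pchisq(s$chisq, 1, lower.tail = FALSE))
    })
    res$pairwise <- data.frame(groupA = pairs[1L, ], groupB = pairs[2L, ],
                               chisq = pw["chisq", ], p = pw["p", ],
                               fdr = p.adjust(pw["p", ], "BH"),
                               stringsAsFactors = FALSE)
  }
  res
}

#' Harrell's concordance index
#'
#' C over usable (censoring-aware) pairs; higher risk must mean worse
#' expected outcome. Risk ties count 0.5.
#'
#' @param table survival data.frame.
#' @param risk numeric or ordinal risk per sample (higher = worse).
#' @return C in \[0, 1\].
#' @export
concordanceIndex <- function(table, risk) {
  .survCheck(table)
  stopifnot(length(risk) == nrow(table))
  risk <- as.numeric(risk)
  fit <- survival::concordance(survival::Surv(table$time, table$event) ~ risk,
                               reverse = TRUE)
  if (sum(fit$count[1:3]) == 0) stop("no usable pairs (all pairs tied/censored)")
  unname(fit$concordance)
}

#' Paired bootstrap comparison of two risk scores
#'
#' Resamples the cohort with replacement, recomputes both concordance
#' indices on each resample, and reports the observed difference with a
#' two-sided bootstrap p-value for delta C = 0.
#'
#' @param table survival data.frame.
#' @param riskA,riskB risk vectors over the same samples (higher = worse).
#' @param nBoot bootstrap resamples.
#' @param seed RNG seed.
#' @return list: cA, cB, deltaC, p, nBootUsed.
#' @export
compareCindex <- function(table, riskA, riskB, nBoot = 1000L, seed = 1L) {
  .survCheck(table)
  stopifnot(length(riskA) == nrow(table), length(riskB) == nrow(table))
  cA <- concordanceIndex(table, riskA)
  cB <- concordanceIndex(table, riskB)
  n <- nrow(table)
  deltas <- .withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      idx <- sample(n, replace = TRUE)
      tb <- table[idx, ]
      tb$sample <- paste0("b", seq_len(n))   # resampled ids must stay unique
      dA <- try(concordanceIndex(tb, riskA[idx]), silent = TRUE)
      dB <- try(concordanceIndex(tb, riskB[idx]), silent = TRUE)
      if (inherits(dA, "try-error") || inherits(dB, "try-error"))
        return(NA_real_)
      dA - dB
    }, 1)
  })
  deltas <- deltas[!is.na(deltas)]
  if (length(deltas) < nBoot / 2) stop("bootstrap degenerate: too few usable resamples")
  pLow <- mean(deltas <= 0); pHigh <- mean(deltas >= 0)
  list(cA = cA, cB = cB, deltaC = cA - cB,
       p = min(1, 2 * min(pLow, pHigh)), nBootUsed = length(deltas))
}
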