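# Guide-level statistics for sorted-bin screens and the surrogate
# per-target enrichment score. All scores live in knockdown space:
# for a high-vs-neg (or high-vs-low) comparison, knocking down an
# activator depletes its guides from the High bin, so activators score
# negative. Writers flip the sign once into the activator-positive
# orientation.

.parse_comparison <- function(comparison) {
  parts <- strsplit(comparison, "_vs_", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !all(parts %in% .POPULATIONS))
    stop("comparison must be '<population>_vs_<population>', got '",
         comparison, "'")
  parts
}

#' Normalize guide counts to pseudo-CPM
#'
#' Per sample, abundance = (count + 0.5) / sum(count + 0.5) * 1e6. The
#' 0.5 pseudocount keeps zero-count guides finite without dominating
#' ranks; every column sums to 1e6 exactly.
#'
#' @param x a [ScreenCounts-class] or a count matrix.
#' @return numeric matrix of abundances with the same dimnames.
#' @export
normalizeCounts <- function(x) {
  m <- if (is(x, "SummarizedExperiment")) assay(x, "counts") else as.matrix(x)
  zero <- colSums(m) == 0
  if (any(zero))
    .stopf("all-zero count column(s): %s",
           paste(colnames(m)[zero], collapse = ", "))
  m <- m + 0.5
  sweep(m, 2, colSums(m), "/") * 1e6
}

#' Per-guide log2 fold change between sorted populations
#'
#' For each replicate of each screen, computes
#' log2(abundance in numerator population / abundance in denominator
#' population), e.g. the GFP-High over GFP-Low guide ratio. The
#' pseudocount is applied upstream in [normalizeCounts()].
#'
#' @param normalized abundance matrix from [normalizeCounts()].
#' @param comparison string `"<num>_vs_<den>"`, e.g. `"high_vs_low"`.
#' @param sheet the [SampleSheet-class] describing the columns.
#' @return data.frame with columns `guide_id`, `screen_id`, `replicate`,
#'   `comparison`, `log2fc`.
#' @export
guideLog2fc <- function(normalized, comparison, sheet) {
  pops <- .parse_comparison(comparison)
  s <- samples(sheet)
  s <- s[s$sample_id %in% colnames(normalized), , drop = FALSE]
  out <- list()
  for (scr in unique(s$screen_id)) {
    reps <- sort(unique(s$replicate[s$screen_id == scr &
                                    s$population %in% pops]))
    for (r in reps) {
      ids <- vapply(pops, function(p) {
        hit <- s$sample_id[s$screen_id == scr & s$population == p &
                           s$replicate == r]
        if (!length(hit))
          .stopf("missing population sample: (%s, %s, replicate %d)",
                 scr, p, r)
        hit
      }, character(1))
      out[[paste(scr, r)]] <- data.frame(
        guide_id = rownames(normalized), screen_id = scr, replicate = r,
        comparison = comparison,
        log2fc = log2(normalized[, ids[1]] / normalized[, ids[2]]),
        row.names = NULL)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Z-score guide log2 fold changes
#'
#' Standardizes log2fc over all guides of each (screen, replicate,
#' comparison) stratum using the sample sd (divisor n - 1); as a config
#' switch, the mean and sd can be taken from nontargeting guides only.
#'
#' @param stats data.frame from [guideLog2fc()].
#' @param library optional [GuideLibrary-class]; required when
#'   `nontargeting_only = TRUE` or `robust = TRUE`.
#' @param nontargeting_only standardize using nontargeting guides'
#'   moments instead of all guides.
#' @param robust center on the per-stratum median over all guides
#'   (robust to a minority of true-effect guides) and scale by the
#'   nontargeting-guide sd. Used by the interaction pipeline, where a
#'   handful of strong hits would otherwise shift every null guide's z.
#' @return the input with a `z` column added.
#' @export
zscoreGuides <- function(stats, library = NULL, nontargeting_only = FALSE,
                         robust = FALSE) {
  if (nontargeting_only && robust)
    stop("choose one of nontargeting_only and robust")
  if ((nontargeting_only || robust) && is.null(library))
    stop("library required for nontargeting-referenced standardization")
  nt_ids <- if (nontargeting_only || robust)
    guides(library)$guide_id[guides(library)$target_class == "nontargeting"]
  key <- paste(stats$screen_id, stats$replicate, stats$comparison)
  stats$z <- NA_real_
  for (k in unique(key)) {
    i <- key == k
    if (sum(i) < 3) .stopf("fewer than 3 guides in stratum %s", k)
    ref <- if (nontargeting_only || robust) i & stats$guide_id %in% nt_ids
           else i
    s <- stats::sd(stats$log2fc[ref])
    if (!is.finite(s) || s == 0)
      .stopf("zero log2fc standard deviation in stratum %s (degenerate screen)", k)
    ctr <- if (robust) stats::median(stats$log2fc[i])
           else mean(stats$log2fc[ref])
    stats$z[i] <- (stats$log2fc[i] - ctr) / s
  }
  stats
}

#' Surrogate target-level enrichment score
#'
#' Collapses guide z scores to a per-target score (mean z over the
#' target's guides and replicates) and tests each target's guide-z
#' values, pooled over replicates, against the nontargeting guide-z
#' values with a two-sided Wilcoxon rank-sum test. BH correction is
#' applied across targets within each comparison. The score stands in
#' for a screen effect size ("beta score") and only feeds downstream
#' rankings and classes; it is validated by recovery on simulated
#' screens. Sign convention: negative score in `high_vs_neg` (knockdown
#' depleted from High) means activator.
#'
#' @param stats data.frame from [zscoreGuides()].
#' @param library a [GuideLibrary-class] with nontargeting guides.
#' @param alpha FDR threshold for regulator classification.
#' @return data.frame with columns `target_id`, `comparison`, `score`,
#'   `p`, `fdr`, `regulator_class`, `n_guides`.
#' @export
surrogateTargetScore <- function(stats, library, alpha = 0.05) {
  lib <- guides(library)
  nt_guides <- lib$guide_id[lib$target_class == "nontargeting"]
  if (!length(nt_guides))
    stop("library has no nontargeting guides; surrogate scoring needs them")
  stats <- stats[stats$guide_id %in% lib$guide_id, , drop = FALSE]
  empty <- data.frame(target_id = character(), comparison = character(),
                      score = numeric(), p = numeric(), fdr = numeric(),
                      regulator_class = character(), n_guides = integer())
  if (!nrow(stats)) return(empty)
  tgt_of <- setNames(lib$target_id, lib$guide_id)
  out <- list()
  for (cmp in unique(stats$comparison)) {
    sc <- stats[stats$comparison == cmp, , drop = FALSE]
    nt_z <- sc$z[sc$guide_id %in% nt_guides]
    targets <- setdiff(unique(tgt_of[sc$guide_id]),
                       unique(lib$target_id[lib$target_class == "nontargeting"]))
    rows <- lapply(targets, function(tg) {
      gz <- sc$z[tgt_of[sc$guide_id] == tg]
      ng <- length(unique(sc$guide_id[tgt_of[sc$guide_id] == tg]))
      if (ng < 2) {
        .warnf("target %s has < 2 guides; excluded", tg)
        return(NULL)
      }
      p <- stats::wilcox.test(gz, nt_z, alternative = "two.sided",
                              exact = FALSE)$p.value
      data.frame(target_id = tg, comparison = cmp, score = mean(gz), p = p,
                 n_guides = ng)
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows)) next
    rows$fdr <- stats::p.adjust(rows$p, "BH")
    rows$regulator_class <- ifelse(rows$fdr > alpha, "ns",
                                   ifelse(rows$score < 0, "activator",
                                          "repressor"))
    out[[cmp]] <- rows[, c("target_id", "comparison", "score", "p", "fdr",
                           "regulator_class", "n_guides")]
  }
  if (!length(out)) return(empty)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Run the guide-level screen pipeline in one call
#'
#' Convenience wrapper: [normalizeCounts()] then [guideLog2fc()] then
#' [zscoreGuides()].
#'
#' @param x a [ScreenCounts-class].
#' @param comparison comparison string, e.g. `"high_vs_low"`.
#' @inheritParams zscoreGuides
#' @return guide-statistics data.frame with `log2fc` and `z`.
#' @export
screenGuideStats <- function(x, comparison, library = screenLibrary(x),
                             nontargeting_only = FALSE, robust = FALSE) {
  zscoreGuides(guideLog2fc(normalizeCounts(x), comparison, screenSheet(x)),
               library = library, nontargeting_only = nontargeting_only,
               robust = robust)
}
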