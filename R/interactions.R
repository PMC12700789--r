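# The core statistic: noRE-normalized TF-RE interaction scores. Guide z
# scores from each RE reporter screen are normalized by subtracting the
# matched (guide, replicate) z from the noRE control screen, cancelling
# minimal-promoter and trans-acting confounders; per TF, the per-guide
# values are tested against zero with a one-sample t-test and BH
# corrected within the RE screen.

#' noRE-normalize guide z scores
#'
#' Subtracts the noRE control screen's z from the reporter screen's z,
#' matched by (guide, replicate): z* = z[guide, rep, RE] - z[guide, rep,
#' noRE]. Any per-(guide, replicate) confounder common to all reporters
#' cancels exactly. Guides present in only one screen are dropped with a
#' warning; more than 10% dropped is an error.
#'
#' @param z_re guide-statistics data.frame (with `z`) for one RE screen.
#' @param z_nore guide-statistics data.frame for the noRE screen.
#' @return data.frame with columns `guide_id`, `replicate`, `z_star`.
#' @export
noreNormalize <- function(z_re, z_nore) {
  key_re <- paste(z_re$guide_id, z_re$replicate)
  key_no <- paste(z_nore$guide_id, z_nore$replicate)
  common <- intersect(key_re, key_no)
  dropped <- length(unique(c(key_re, key_no))) - length(common)
  if (dropped > 0) {
    frac <- dropped / length(unique(c(key_re, key_no)))
    if (frac > 0.1)
      .stopf("%.0f%% of (guide, replicate) pairs unmatched between screens",
             100 * frac)
    .warnf("%d (guide, replicate) pair(s) present in one screen only; dropped",
           dropped)
  }
  i_re <- match(common, key_re); i_no <- match(common, key_no)
  data.frame(guide_id = z_re$guide_id[i_re],
             replicate = z_re$replicate[i_re],
             z_star = z_re$z[i_re] - z_nore$z[i_no])
}

# Shared per-TF one-sample t machinery for interactionTest and the noRE
# responder screen. `values` holds one column of per-guide means.
.per_tf_ttest <- function(vals_df, library, alpha, re_id, value_col = "z_star",
                          pool_replicates = FALSE) {
  lib <- guides(library)
  tgt_of <- setNames(lib$target_id, lib$guide_id)
  tfs <- unique(lib$target_id[lib$target_class != "nontargeting"])
  tfs <- intersect(tfs, unique(tgt_of[vals_df$guide_id]))
  rows <- lapply(tfs, function(tf) {
    sub <- vals_df[tgt_of[vals_df$guide_id] == tf, , drop = FALSE]
    # t-test unit: per-guide mean over replicates (replicates of one
    # guide are not independent); a pooled guide x replicate variant is
    # available as a config switch.
    vals <- if (pool_replicates) sub[[value_col]]
            else tapply(sub[[value_col]], sub$guide_id, mean)
    n <- length(unique(sub$guide_id))
    if (n < 3) {
      message("TF ", tf, " has < 3 matched guides in ", re_id,
              "; emitted with p = NA")
      return(data.frame(tf_id = tf, re_id = re_id,
                        interaction_score = mean(vals), t_stat = NA_real_,
                        p = NA_real_, n_guides = n))
    }
    score <- mean(vals)
    if (stats::sd(vals) == 0) {
      # all values identical: t undefined at 0, infinite otherwise
      t_stat <- if (score == 0) NA_real_ else sign(score) * Inf
      p <- if (score == 0) NA_real_ else 0
    } else {
      tt <- stats::t.test(vals, mu = 0, alternative = "two.sided")
      t_stat <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(tf_id = tf, re_id = re_id, interaction_score = score,
               t_stat = t_stat, p = p, n_guides = n)
  })
  rec <- do.call(rbind, rows)
  rec$fdr <- NA_real_
  ok <- !is.na(rec$p)
  rec$fdr[ok] <- stats::p.adjust(rec$p[ok], "BH")
  rec$significant <- !is.na(rec$fdr) & rec$fdr <= alpha
  rec$direction <- ifelse(rec$interaction_score < 0, "activating", "repressive")
  rec
}

#' One-sample interaction test for one RE screen
#'
#' Per TF: the noRE-normalized values are collapsed to one value per
#' guide (mean over replicates); the interaction score is the mean of
#' those per-guide values, tested against zero with a two-sided
#' one-sample t-test (df = n_guides - 1) and BH-corrected across all TFs
#' within the RE screen. TFs with fewer than 3 matched guides are
#' emitted with p = NA and never called significant. Scores are in
#' knockdown space (activating interaction < 0).
#'
#' @param z_star data.frame from [noreNormalize()].
#' @param library a [GuideLibrary-class].
#' @param re_id RE identifier for the output records.
#' @param alpha FDR threshold (default 0.2).
#' @param pool_replicates test pooled guide-by-replicate values instead
#'   of per-guide means (config switch; df then n_values - 1).
#' @return data.frame of interaction records for this RE.
#' @export
interactionTest <- function(z_star, library, re_id = "RE", alpha = 0.2,
                            pool_replicates = FALSE) {
  .per_tf_ttest(z_star, library, alpha, re_id,
                pool_replicates = pool_replicates)
}

#' Identify TFs that affect the noRE control reporter
#'
#' Applies the per-TF one-sample test to the raw (un-normalized) noRE
#' guide z scores; TFs significant at the FDR threshold act on the
#' minimal promoter or in trans and must be removed from every RE grid.
#'
#' @param z_nore guide-statistics data.frame (with `z`) for the noRE
#'   screen.
#' @param library a [GuideLibrary-class].
#' @param alpha FDR threshold (default 0.2).
#' @return data.frame with columns `tf_id`, `nore_fdr`.
#' @export
excludeNoreResponders <- function(z_nore, library, alpha = 0.2) {
  vals <- data.frame(guide_id = z_nore$guide_id, replicate = z_nore$replicate,
                     z_star = z_nore$z)
  rec <- .per_tf_ttest(vals, library, alpha, "noRE")
  data.frame(tf_id = rec$tf_id[rec$significant],
             nore_fdr = rec$fdr[rec$significant])
}

#' Build the full TF-by-RE interaction matrix
#'
#' Runs the complete interaction pipeline on a panel of guide-statistics
#' tables: excludes noRE responders, noRE-normalizes every RE screen,
#' tests each TF and assembles the retained grid. BH correction is
#' applied within each RE screen (each an independently sorted
#' experiment); `global_bh = TRUE` pools all screens instead.
#'
#' @param panel_z named list of guide-statistics data.frames (with `z`),
#'   one per reporter, including the noRE control.
#' @param library a [GuideLibrary-class].
#' @param nore_id name of the noRE element of `panel_z`.
#' @param alpha FDR threshold (default 0.2).
#' @param global_bh pool BH correction across all RE screens.
#' @param pool_replicates see [interactionTest()].
#' @return An [InteractionMatrix-class].
#' @export
buildInteractionMatrix <- function(panel_z, library, nore_id = "noRE",
                                   alpha = 0.2, global_bh = FALSE,
                                   pool_replicates = FALSE) {
  if (!nore_id %in% names(panel_z))
    stop("noRE screen '", nore_id, "' not in panel")
  excl <- excludeNoreResponders(panel_z[[nore_id]], library, alpha)
  keep_lib <- GuideLibrary(
    guides(library)[!guides(library)$target_id %in% excl$tf_id, , drop = FALSE])
  res <- list()
  for (re in setdiff(names(panel_z), nore_id)) {
    zs <- noreNormalize(panel_z[[re]], panel_z[[nore_id]])
    res[[re]] <- interactionTest(zs, keep_lib, re_id = re, alpha = alpha,
                                 pool_replicates = pool_replicates)
  }
  rec <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  if (global_bh) {
    ok <- !is.na(rec$p)
    rec$fdr[ok] <- stats::p.adjust(rec$p[ok], "BH")
    rec$significant <- !is.na(rec$fdr) & rec$fdr <= alpha
  }
  new("InteractionMatrix", records = rec, exclusions = excl, alpha = alpha)
}

#' Interaction matrix straight from a reporter-screen panel
#'
#' End-to-end convenience wrapper: computes guide statistics for every
#' reporter screen in the panel (GFP-High over GFP-Low log2 ratios,
#' standardized per replicate) and runs [buildInteractionMatrix()]. By
#' default the standardization is the robust variant (median center over
#' all guides, nontargeting-guide sd): in screens with a minority of
#' strong true effects the plain mean/sd would shift and stretch every
#' null guide's z, inflating false interaction calls.
#'
#' @param panel named list of [ScreenCounts-class], one per reporter,
#'   including the `"noRE"` control.
#' @param library a [GuideLibrary-class].
#' @param comparison comparison string (default `"high_vs_low"`).
#' @param robust see [zscoreGuides()].
#' @inheritParams buildInteractionMatrix
#' @return An [InteractionMatrix-class].
#' @export
reporterPanelInteractions <- function(panel, library,
                                      comparison = "high_vs_low",
                                      nore_id = "noRE", alpha = 0.2,
                                      robust = TRUE, global_bh = FALSE,
                                      pool_replicates = FALSE) {
  panel_z <- lapply(panel, screenGuideStats, comparison = comparison,
                    library = library, robust = robust)
  buildInteractionMatrix(panel_z, library, nore_id = nore_id, alpha = alpha,
                         global_bh = global_bh,
                         pool_replicates = pool_replicates)
}

#' PCA and k-means grouping of reporter screens
#'
#' Aggregates guide-level log2 fold changes to target-level means, runs
#' PCA over the (reporter, replicate) observations and k-means
#' (k-means++ initialization, 50 restarts, fixed seed) on the leading
#' components explaining at least `var_explained` of the variance.
#'
#' @param panel_lfc data.frame with columns `reporter_id`, `replicate`,
#'   `guide_id`, `log2fc` covering all reporters.
#' @param library a [GuideLibrary-class] used to average guides per
#'   target.
#' @param k number of clusters.
#' @param seed integer seed for the k-means restarts.
#' @param var_explained minimum cumulative variance of the retained
#'   components (default 0.8).
#' @return data.frame with one row per (reporter, replicate): principal
#'   coordinates `PC1..`, and `cluster`.
#' @export
reporterGrouping <- function(panel_lfc, library, k, seed = 1,
                             var_explained = 0.8) {
  tgt_of <- setNames(guides(library)$target_id, guides(library)$guide_id)
  panel_lfc <- panel_lfc[panel_lfc$guide_id %in% names(tgt_of), , drop = FALSE]
  obs_key <- paste(panel_lfc$reporter_id, panel_lfc$replicate, sep = "|")
  obs_levels <- unique(obs_key)
  if (k > length(obs_levels))
    .stopf("k = %d exceeds the %d (reporter, replicate) observations",
           k, length(obs_levels))
  tgt <- tgt_of[panel_lfc$guide_id]
  m <- tapply(panel_lfc$log2fc, list(tgt, obs_key), mean)
  m <- m[, obs_levels, drop = FALSE]
  if (anyNA(m)) stop("incomplete target coverage across observations")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  n_pc <- max(1, which(cum >= var_explained)[1], na.rm = TRUE)
  n_pc <- min(n_pc, ncol(pc$x))
  coords <- pc$x[, seq_len(n_pc), drop = FALSE]
  cl <- .with_seed(seed, .kmeanspp(coords, k, nstart = 50))
  parts <- do.call(rbind, strsplit(obs_levels, "|", fixed = TRUE))
  data.frame(reporter_id = parts[, 1], replicate = as.integer(parts[, 2]),
             coords, cluster = unname(cl$cluster), row.names = NULL,
             check.names = FALSE)
}
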