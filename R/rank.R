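# Rank-integration statistics: cumulative interaction-score curves over
# a screen-derived TF ranking, tested against scrambled rankings, and a
# weighted Kolmogorov-Smirnov (GSEA-style) enrichment of expression
# groups in the same ranking.

#' Rank targets by screen score
#'
#' Orders targets from strongest activator to strongest repressor. Input
#' scores are in knockdown space (activator negative); the ranking score
#' is the activator-positive flip, sorted descending with lexicographic
#' tie-breaking on target id so the order is deterministic.
#'
#' @param scores data.frame from [surrogateTargetScore()] (columns
#'   `target_id`, `score`, optionally `comparison`), or a named numeric
#'   vector of knockdown-space scores.
#' @return data.frame with columns `target_id`, `ranking_score`,
#'   `comparison`, ordered activator-first.
#' @export
rankTargets <- function(scores) {
  if (is.numeric(scores))
    scores <- data.frame(target_id = names(scores), score = unname(scores),
                         comparison = NA_character_)
  if (anyDuplicated(scores$target_id))
    .stopf("duplicate target(s) in ranking: %s",
           paste(unique(scores$target_id[duplicated(scores$target_id)]),
                 collapse = ", "))
  rs <- -scores$score
  ord <- order(-rs, scores$target_id)
  data.frame(target_id = scores$target_id[ord], ranking_score = rs[ord],
             comparison = if ("comparison" %in% names(scores))
               scores$comparison[ord] else NA_character_,
             row.names = NULL)
}

#' Cumulative interaction-score curve along a ranking
#'
#' Walking the ranking from strongest activator down, accumulates the
#' interaction scores: `cumulative[i]` is the sum of the scores of the
#' first i targets. The summary statistic is the mean of the cumulative
#' array; its final value equals the total score sum for every
#' permutation of the ranking. Targets missing a score are dropped from
#' both (logged).
#'
#' @param ranking data.frame from [rankTargets()].
#' @param scores_for_re named numeric, interaction score per target for
#'   one RE (activator-positive orientation, as serialized).
#' @return list with `target_id`, `cumulative`, `observed_mean`.
#' @export
cumulativeCurve <- function(ranking, scores_for_re) {
  keep <- ranking$target_id %in% names(scores_for_re)
  if (!any(keep)) stop("no ranked target has an interaction score")
  if (!all(keep))
    message(sum(!keep), " ranked target(s) lack scores; dropped")
  ids <- ranking$target_id[keep]
  cum <- cumsum(unname(scores_for_re[ids]))
  list(target_id = ids, cumulative = cum, observed_mean = mean(cum))
}

#' Scrambled-ranking null for the cumulative curve
#'
#' Scrambles the ranking (permutation without replacement) `n_boot`
#' times, recomputing the mean cumulative score each time. The
#' one-sided empirical p (activator-enrichment direction, with the
#' +1/(B+1) correction so p is never 0) asks whether the observed mean
#' exceeds the scrambled means; per-position 95th and 99th percentile
#' envelopes of the null curves are returned for plotting.
#'
#' @inheritParams cumulativeCurve
#' @param n_boot number of scrambles (default 10000).
#' @param seed integer seed.
#' @param alternative `"greater"` (default, activator enrichment) or
#'   `"two.sided"`.
#' @return list of class `"CumulativeResult"`: `positions`,
#'   `cumulative`, `observed_mean`, `empirical_p`, `n_boot`, `seed`,
#'   `envelope_95`, `envelope_99`.
#' @export
bootstrapRankingNull <- function(ranking, scores_for_re, n_boot = 10000,
                                 seed = 1, alternative = c("greater",
                                                           "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_boot < 1) stop("n_boot must be >= 1")
  obs <- cumulativeCurve(ranking, scores_for_re)
  s <- unname(scores_for_re[obs$target_id])
  n <- length(s)
  if (n < 5) stop("need >= 5 targets with scores")
  .with_seed(seed, {
    null_curves <- vapply(seq_len(n_boot),
                          function(b) cumsum(s[sample.int(n)]),
                          numeric(n))  # n x n_boot
    stopifnot(all(abs(null_curves[n, ] - sum(s)) < 1e-8))
    null_means <- colMeans(null_curves)
    p <- if (alternative == "greater")
      (1 + sum(null_means >= obs$observed_mean)) / (n_boot + 1)
    else
      (1 + sum(abs(null_means - mean(null_means)) >=
                 abs(obs$observed_mean - mean(null_means)))) / (n_boot + 1)
    structure(list(positions = seq_len(n), target_id = obs$target_id,
                   cumulative = obs$cumulative,
                   observed_mean = obs$observed_mean, empirical_p = p,
                   n_boot = n_boot, seed = seed,
                   envelope_95 = apply(null_curves, 1, stats::quantile, 0.95),
                   envelope_99 = apply(null_curves, 1, stats::quantile, 0.99)),
              class = "CumulativeResult")
  })
}

#' @export
print.CumulativeResult <- function(x, ...) {
  cat("CumulativeResult:", length(x$positions), "targets; observed mean =",
      signif(x$observed_mean, 4), "; empirical p =", signif(x$empirical_p, 4),
      sprintf("(n_boot = %d, seed = %d)\n", x$n_boot, x$seed))
  invisible(x)
}

# Weighted KS running sum over a ranking. Hit steps are proportional to
# |ranking_score|^weight (uniform if the weights vanish); miss steps are
# uniform. Returns the signed extremum.
.running_sum_es <- function(in_set, weights, weight_exponent) {
  w <- abs(weights)^weight_exponent
  hit_w <- w * in_set
  if (sum(hit_w) == 0) hit_w <- as.numeric(in_set)
  n_miss <- sum(!in_set)
  steps <- ifelse(in_set, hit_w / sum(hit_w), -1 / n_miss)
  rs <- cumsum(steps)
  rs[which.max(abs(rs))]
}

#' GSEA-style enrichment of a target set in a ranking
#'
#' Standard weighted Kolmogorov-Smirnov running-sum enrichment score:
#' walking down the ranking, set members increment the sum proportional
#' to |ranking_score|^weight_exponent and non-members decrement it
#' uniformly; the score is the signed extremum (in [-1, 1]).
#' Significance is assessed by gene-set permutation (random sets of the
#' same size), one-sided in the direction of the observed score with the
#' +1/(B+1) correction.
#'
#' @param ranking data.frame from [rankTargets()].
#' @param gene_set character vector of target ids; must intersect the
#'   ranking and not cover it entirely.
#' @param weight_exponent weighting exponent (0 = classical KS).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @param set_id label recorded in the result.
#' @return list of class `"EnrichmentResult"`: `set_id`, `es`, `p`,
#'   `n_perm`, `seed`.
#' @export
gseaES <- function(ranking, gene_set, weight_exponent = 1, n_perm = 1000,
                   seed = 1, set_id = "set") {
  ids <- ranking$target_id
  in_set <- ids %in% gene_set
  if (!any(in_set)) stop("gene set does not intersect the ranking")
  if (all(in_set)) stop("gene set covers the entire ranking")
  es <- .running_sum_es(in_set, ranking$ranking_score, weight_exponent)
  .with_seed(seed, {
    k <- sum(in_set); n <- length(ids)
    null_es <- vapply(seq_len(n_perm), function(b) {
      perm <- logical(n); perm[sample.int(n, k)] <- TRUE
      .running_sum_es(perm, ranking$ranking_score, weight_exponent)
    }, numeric(1))
    p <- if (es >= 0) (1 + sum(null_es >= es)) / (n_perm + 1)
         else (1 + sum(null_es <= es)) / (n_perm + 1)
    structure(list(set_id = set_id, es = es, p = p, n_perm = n_perm,
                   seed = seed), class = "EnrichmentResult")
  })
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat("EnrichmentResult <", x$set_id, ">: ES =", signif(x$es, 4),
      ", p =", signif(x$p, 4), sprintf("(n_perm = %d)\n", x$n_perm))
  invisible(x)
}
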