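# Time-course analysis: z-scored dynamics, archetype clustering with
# peak-time labelling, spline peak estimation, two-way ANOVA variance
# decomposition (differentiation vs X-chromosome number) and Fisher
# enrichment of regulator classes in expression clusters.

#' log2(CPM + 1) transform of an expression course
#'
#' @param course an [ExpressionCourse-class]. Courses already in
#'   `"log2cpm"` are returned unchanged.
#' @return An [ExpressionCourse-class] with unit `"log2cpm"`.
#' @export
log2cpm <- function(course) {
  if (identical(metadata(course)$unit, "log2cpm")) return(course)
  m <- assay(course)
  cpm <- sweep(m, 2, colSums(m), "/") * 1e6
  cd <- colData(course)
  ExpressionCourse(log2(cpm + 1), cd$timepoint_h, cd$genotype, cd$replicate,
                   unit = "log2cpm")
}

#' Z-scored expression dynamics
#'
#' For one genotype: replicate means of log2(CPM + 1) per timepoint,
#' standardized per gene across timepoints with the sample sd. Genes
#' with a constant raw profile are flagged degenerate (z = NA) and are
#' excluded from clustering.
#'
#' @param course an [ExpressionCourse-class] (counts are log2-CPM
#'   transformed internally).
#' @param genotype `"XX"` (default) or `"XO"`.
#' @return list of class `"DynamicsProfiles"`: `z` and `raw_mean`
#'   (gene-by-timepoint matrices), `timepoints`, `genotype`,
#'   `degenerate` (logical per gene).
#' @export
zscoreDynamics <- function(course, genotype = "XX") {
  course <- log2cpm(course)
  cd <- colData(course)
  sel <- cd$genotype == genotype
  if (!any(sel)) stop("genotype ", genotype, " absent from course")
  tps <- sort(unique(cd$timepoint_h[sel]))
  if (length(tps) < 3) stop("need >= 3 distinct timepoints")
  m <- assay(course)[, sel, drop = FALSE]
  tp <- cd$timepoint_h[sel]
  raw <- do.call(cbind, lapply(tps, function(t)
    rowMeans(m[, tp == t, drop = FALSE])))
  dimnames(raw) <- list(rownames(m), paste0("t", tps))
  sds <- apply(raw, 1, stats::sd)
  degenerate <- !is.finite(sds) | sds == 0
  z <- (raw - rowMeans(raw)) / sds
  z[degenerate, ] <- NA_real_
  structure(list(z = z, raw_mean = raw, timepoints = tps,
                 genotype = genotype, degenerate = degenerate),
            class = "DynamicsProfiles")
}

#' @export
print.DynamicsProfiles <- function(x, ...) {
  cat("DynamicsProfiles:", nrow(x$z), "genes x", length(x$timepoints),
      "timepoints (", x$genotype, ");", sum(x$degenerate), "degenerate\n")
  invisible(x)
}

#' Peak time of an expression profile
#'
#' Fits a natural cubic spline through (timepoint, z) and returns the
#' argmax on an hourly grid within the measured range (earliest grid
#' point on ties). Reported peaks can therefore fall between measured
#' timepoints. With fewer than 4 timepoints, the argmax of the measured
#' points is returned.
#'
#' @param z numeric profile over `timepoints`.
#' @param timepoints hours, ascending.
#' @param grid_h grid resolution in hours (default 1).
#' @return peak time in hours, or NA for a degenerate (NA/constant)
#'   profile.
#' @export
peakTime <- function(z, timepoints, grid_h = 1) {
  if (anyNA(z) || stats::sd(z) == 0) return(NA_real_)
  if (length(timepoints) < 4) return(timepoints[which.max(z)])
  grid <- seq(min(timepoints), max(timepoints), by = grid_h)
  fit <- stats::spline(timepoints, z, xout = grid, method = "natural")
  grid[which.max(fit$y)]
}

#' Cluster expression dynamics into archetypes
#'
#' k-means (k-means++ initialization, 50 restarts, fixed seed) on the
#' z-scored profiles. Cluster labels follow the centroid peak time:
#' centroids peaking at the first measured timepoint are `naive`, at the
#' last `committed`, and interior peaks are `transient_1..m` in
#' ascending peak-time order.
#'
#' @param profiles a `"DynamicsProfiles"` from [zscoreDynamics()].
#' @param k number of clusters (default 5: naive, three transients,
#'   committed).
#' @param seed integer seed.
#' @param grid_h spline grid for centroid peaks (hours).
#' @return data.frame with columns `gene`, `cluster_id`, `cluster_label`,
#'   `cluster_peak_time_h`.
#' @export
clusterDynamics <- function(profiles, k = 5, seed = 1, grid_h = 1) {
  z <- profiles$z[!profiles$degenerate, , drop = FALSE]
  if (nrow(z) < k)
    .stopf("k = %d exceeds the %d non-degenerate profiles", k, nrow(z))
  fit <- .with_seed(seed, .kmeanspp(z, k, nstart = 50))
  centroids <- fit$centers
  peaks <- apply(centroids, 1, peakTime, timepoints = profiles$timepoints,
                 grid_h = grid_h)
  first_t <- min(profiles$timepoints); last_t <- max(profiles$timepoints)
  kind <- ifelse(peaks <= first_t, "naive",
                 ifelse(peaks >= last_t, "committed", "transient"))
  labels <- character(k)
  ord <- order(peaks)
  for (kd in c("naive", "transient", "committed")) {
    idx <- ord[kind[ord] == kd]
    labels[idx] <- if (length(idx) == 1 && kd != "transient") kd
                   else paste0(kd, "_", seq_along(idx))
  }
  data.frame(gene = rownames(z), cluster_id = unname(fit$cluster),
             cluster_label = labels[fit$cluster],
             cluster_peak_time_h = peaks[fit$cluster], row.names = NULL)
}

#' Two-way ANOVA variance decomposition per gene
#'
#' Per gene, fits log2(CPM + 1) ~ timepoint (categorical) + genotype +
#' interaction and partitions variance with type II sums of squares:
#' `frac_var_time` and `frac_var_genotype` are each factor's SS over the
#' total SS. F-test p-values are BH-corrected across genes per factor;
#' the X-dosage direction (`xx_biased` / `xo_biased`) is reported only
#' for genes with genotype FDR <= `alpha`. Genes with empty
#' (timepoint, genotype) cells are skipped with a warning.
#'
#' @param course an [ExpressionCourse-class] with both genotypes.
#' @param alpha FDR threshold for calling a genotype direction.
#' @return data.frame with columns `gene`, `frac_var_time`,
#'   `frac_var_genotype`, `p_time`, `p_genotype`, `fdr_time`,
#'   `fdr_genotype`, `xx_direction`.
#' @export
varianceDecomposition <- function(course, alpha = 0.05) {
  course <- log2cpm(course)
  cd <- colData(course)
  shared <- intersect(cd$timepoint_h[cd$genotype == "XX"],
                      cd$timepoint_h[cd$genotype == "XO"])
  if (length(shared) < 3)
    stop("need both genotypes at >= 3 shared timepoints")
  sel <- cd$timepoint_h %in% shared
  m <- assay(course)[, sel, drop = FALSE]
  tp <- factor(cd$timepoint_h[sel]); gt <- factor(cd$genotype[sel],
                                                  c("XO", "XX"))
  if (any(table(tp, gt) == 0)) stop("empty (timepoint, genotype) cell")
  rows <- lapply(rownames(m), function(g) {
    y <- m[g, ]
    ss_total <- sum((y - mean(y))^2)
    if (ss_total == 0)
      return(data.frame(gene = g, frac_var_time = 0, frac_var_genotype = 0,
                        p_time = 1, p_genotype = 1))
    fit <- stats::lm(y ~ tp * gt)
    # car::Anova refuses an exactly-zero residual SS (noise-free input);
    # the sequential table coincides with type II for these balanced grids
    an <- tryCatch(car::Anova(fit, type = 2),
                   error = function(e) suppressWarnings(stats::anova(fit)))
    ss <- an[["Sum Sq"]]; names(ss) <- rownames(an)
    pv <- an[["Pr(>F)"]]; names(pv) <- rownames(an)
    ss_resid <- ss[["Residuals"]]
    # noise-free inputs give 0/0 F statistics: resolve by SS mass
    fix_p <- function(nm) {
      p <- pv[[nm]]
      if (is.finite(p)) return(p)
      if (ss_resid <= 1e-10 * ss_total)
        return(if (ss[[nm]] > 1e-10 * ss_total) 0 else 1)
      1
    }
    data.frame(gene = g,
               frac_var_time = unname(ss[["tp"]] / ss_total),
               frac_var_genotype = unname(ss[["gt"]] / ss_total),
               p_time = fix_p("tp"), p_genotype = fix_p("gt"))
  })
  out <- do.call(rbind, rows)
  out$fdr_time <- stats::p.adjust(out$p_time, "BH")
  out$fdr_genotype <- stats::p.adjust(out$p_genotype, "BH")
  mean_xx <- rowMeans(m[, gt == "XX", drop = FALSE])
  mean_xo <- rowMeans(m[, gt == "XO", drop = FALSE])
  delta <- (mean_xx - mean_xo)[out$gene]
  out$xx_direction <- ifelse(out$fdr_genotype <= alpha & delta != 0,
                             ifelse(delta > 0, "xx_biased", "xo_biased"),
                             "none")
  out
}

#' One-sided Fisher enrichment of a class within a cluster
#'
#' Tests whether `class_members` are over-represented in `cluster`
#' relative to `universe` with a one-sided (greater) Fisher exact test,
#' i.e. the hypergeometric upper tail of the 2x2 table.
#'
#' @param cluster gene ids in the cluster (subset of universe).
#' @param class_members gene ids in the class (subset of universe).
#' @param universe all gene ids.
#' @return one-sided p-value.
#' @export
fisherClassEnrichment <- function(cluster, class_members, universe) {
  if (!length(universe)) stop("empty universe")
  cluster <- unique(cluster); class_members <- unique(class_members)
  if (length(setdiff(cluster, universe)) ||
      length(setdiff(class_members, universe)))
    stop("cluster and class must be subsets of the universe")
  a <- length(intersect(cluster, class_members))
  b <- length(setdiff(cluster, class_members))
  cc <- length(setdiff(class_members, cluster))
  d <- length(universe) - a - b - cc
  stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                     alternative = "greater")$p.value
}
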