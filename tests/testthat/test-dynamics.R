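test_that("z-scored dynamics standardize per gene and flag degenerate profiles", {
  vals <- rbind(lin = c(1, 2, 3), flat = c(2, 2, 2))
  course <- ExpressionCourse(vals, timepoint_h = c(0, 24, 48),
                             genotype = rep("XX", 3), replicate = rep(1, 3),
                             unit = "log2cpm")
  prof <- zscoreDynamics(course)
  expect_equal(unname(prof$z["lin", ]), c(-1, 0, 1))
  expect_true(prof$degenerate["flat"])
  expect_true(all(abs(rowMeans(prof$z[!prof$degenerate, , drop = FALSE]))
                  < 1e-9))
  expect_lt(abs(sd(prof$z["lin", ]) - 1), 1e-9)
})

test_that("spline peak estimation matches dense evaluation of the same spline", {
  tp <- c(0, 10, 16, 24, 30, 36, 48, 56, 72, 96)
  z <- dnorm(tp, mean = 17, sd = 10)
  pk <- peakTime(z, tp, grid_h = 1)
  dense <- seq(0, 96, by = 0.01)
  oracle <- dense[which.max(spline(tp, z, xout = dense,
                                   method = "natural")$y)]
  expect_lte(abs(pk - oracle), 1)  # within the 1-h grid
  expect_gt(pk, 10); expect_lt(pk, 24)
  # monotone profile peaks at the last timepoint
  expect_equal(peakTime(seq_along(tp), tp), 96)
  # symmetric tent peaking at a measured point returns that point
  tent <- c(0, 1, 2, 3, 2, 1, 0)
  expect_equal(peakTime(tent, c(0, 8, 16, 24, 32, 40, 48)), 24)
  expect_true(is.na(peakTime(rep(1, 10), tp)))
})

test_that("archetype clustering recovers simulated groups and orders labels by peak", {
  arch <- data.frame(
    gene = sprintf("G%03d", 1:300),
    archetype = rep(c("naive", "transient", "transient", "transient",
                      "committed"), each = 60),
    peak_h = rep(c(NA, 17, 30, 48, NA), each = 60))
  sim <- simulateExpressionCourse(arch, nb_dispersion = 0.01, replicates = 3,
                                  seed = 6)
  prof <- zscoreDynamics(sim$course, "XX")
  # cluster the TF genes of interest, not the housekeeping background
  prof$z <- prof$z[arch$gene, ]
  prof$degenerate <- prof$degenerate[arch$gene]
  cl <- clusterDynamics(prof, k = 5, seed = 2)
  truth <- setNames(paste(arch$archetype, ifelse(is.na(arch$peak_h), "",
                                                 arch$peak_h)), arch$gene)
  ari <- mclust::adjustedRandIndex(cl$cluster_id, truth[cl$gene])
  expect_gte(ari, 0.9)
  # labels follow the centroid peak-time ordering rule
  lab <- unique(cl[, c("cluster_label", "cluster_peak_time_h")])
  lab <- lab[order(lab$cluster_peak_time_h), ]
  expect_identical(lab$cluster_label[1], "naive")
  expect_identical(lab$cluster_label[nrow(lab)], "committed")
  trans <- grep("^transient_", lab$cluster_label, value = TRUE)
  expect_identical(trans, paste0("transient_", seq_along(trans)))
  # identical profiles land in the same cluster
  dup <- prof$z[c("G061", "G061"), ]
  rownames(dup) <- c("d1", "d2")
  prof2 <- prof
  prof2$z <- rbind(prof$z, dup)
  prof2$degenerate <- c(prof$degenerate, d1 = FALSE, d2 = FALSE)
  cl2 <- clusterDynamics(prof2, k = 5, seed = 2)
  expect_identical(cl2$cluster_id[cl2$gene == "d1"],
                   cl2$cluster_id[cl2$gene == "d2"])
  # stability across seeds for well-separated archetypes
  cl3 <- clusterDynamics(prof, k = 5, seed = 99)
  cl3 <- cl3[cl3$gene %in% arch$gene, ]
  expect_gte(mclust::adjustedRandIndex(cl$cluster_id, cl3$cluster_id), 0.95)
})

test_that("interior-peak centroids at 17 h and 30 h are transient_1 and transient_2", {
  arch <- data.frame(gene = sprintf("G%02d", 1:40),
                     archetype = "transient",
                     peak_h = rep(c(17, 30), each = 20))
  sim <- simulateExpressionCourse(arch, nb_dispersion = 0.005,
                                  replicates = 2, seed = 3)
  prof <- zscoreDynamics(sim$course, "XX")
  prof$z <- prof$z[arch$gene, ]
  prof$degenerate <- prof$degenerate[arch$gene]
  cl <- clusterDynamics(prof, k = 2, seed = 4)
  early <- unique(cl$cluster_label[cl$gene %in% sprintf("G%02d", 1:20)])
  late <- unique(cl$cluster_label[cl$gene %in% sprintf("G%02d", 21:40)])
  expect_identical(early, "transient_1")
  expect_identical(late, "transient_2")
  expect_lt(unique(cl$cluster_peak_time_h[cl$cluster_label == "transient_1"]),
            unique(cl$cluster_peak_time_h[cl$cluster_label == "transient_2"]))
})

test_that("two-way ANOVA decomposition isolates genotype and time effects", {
  tp <- rep(c(0, 24, 48, 72), each = 2)
  obs <- expand.grid(rep = 1:2, t = c(0, 24, 48, 72), g = c("XX", "XO"),
                     stringsAsFactors = FALSE)
  geno_only <- ifelse(obs$g == "XX", 5, 3)
  time_only <- obs$t / 24 + 1
  vals <- rbind(geno = 2^geno_only, time = 2^time_only)
  course <- ExpressionCourse(vals, obs$t, obs$g, obs$rep, unit = "counts")
  # keep raw values: bypass CPM composition by using log2cpm unit directly
  course2 <- ExpressionCourse(rbind(geno = geno_only, time = time_only),
                              obs$t, obs$g, obs$rep, unit = "log2cpm")
  vd <- varianceDecomposition(course2)
  g <- vd[vd$gene == "geno", ]
  expect_lt(abs(g$frac_var_genotype - 1), 1e-6)
  expect_lt(g$frac_var_time, 1e-6)
  expect_identical(g$xx_direction, "xx_biased")
  t_ <- vd[vd$gene == "time", ]
  expect_lt(abs(t_$frac_var_time - 1), 1e-6)
  expect_identical(t_$xx_direction, "none")

  # identical XX and XO profiles: no genotype variance, no direction
  same <- ExpressionCourse(rbind(g1 = time_only + 0.1), obs$t, obs$g,
                           obs$rep, unit = "log2cpm")
  vd2 <- varianceDecomposition(same)
  expect_equal(vd2$frac_var_genotype, 0)
  expect_identical(vd2$xx_direction, "none")

  # variance fractions are invariant to adding a constant
  shifted <- ExpressionCourse(rbind(geno = geno_only + 7), obs$t, obs$g,
                              obs$rep, unit = "log2cpm")
  vd3 <- varianceDecomposition(shifted)
  expect_equal(vd3$frac_var_genotype, g$frac_var_genotype, tolerance = 1e-9)
})

test_that("simulated XX bias is recovered by the ANOVA direction", {
  arch <- data.frame(gene = sprintf("B%02d", 1:30), archetype = "transient",
                     peak_h = 30)
  bias <- setNames(rep(1, 30), arch$gene)
  sim <- simulateExpressionCourse(arch, xx_bias = bias, nb_dispersion = 0.05,
                                  replicates = 3, seed = 12)
  vd <- varianceDecomposition(sim$course)
  vd <- vd[vd$gene %in% arch$gene, ]
  expect_gte(mean(vd$xx_direction == "xx_biased"), 0.9)
})

test_that("Fisher class enrichment equals the hypergeometric upper tail", {
  universe <- sprintf("u%03d", 1:100)
  activators <- universe[1:10]
  cluster <- c(universe[1:5], universe[51:55])
  p <- fisherClassEnrichment(cluster, activators, universe)
  oracle <- sum(dhyper(5:10, 10, 90, 10))
  expect_equal(p, oracle, tolerance = 1e-12)
  expect_equal(fisherClassEnrichment(cluster, character(0), universe), 1)
  expect_equal(fisherClassEnrichment(universe, universe, universe), 1)
  expect_error(fisherClassEnrichment("a", "a", character(0)), "universe")

  # brute-force agreement across random small tables (N <= 60)
  set.seed(9)
  for (i in 1:25) {
    N <- sample(5:60, 1)
    uni <- sprintf("g%02d", 1:N)
    K <- sample(0:N, 1); n <- sample(1:N, 1)
    cls <- if (K) sample(uni, K) else character(0)
    clu <- sample(uni, n)
    a <- length(intersect(clu, cls))
    oracle <- if (K == 0) 1 else sum(dhyper(a:min(K, n), K, N - K, n))
    expect_equal(fisherClassEnrichment(clu, cls, uni), oracle,
                 tolerance = 1e-12)
  }
})
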