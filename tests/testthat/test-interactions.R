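test_that("noRE normalization is the identity on itself and cancels shared shifts", {
  lib <- random_library(seed = 1)
  set.seed(10)
  # dyadic-rational z values: the shifts below are then exact in floating
  # point, so cancellation can be asserted bit-for-bit
  dyadic <- function(n) round(rnorm(n) * 2^20) / 2^20
  z <- do.call(rbind, lapply(1:3, function(r)
    fake_guide_stats(lib, dyadic(90), replicate = r)))
  self <- noreNormalize(z, z)
  expect_true(all(self$z_star == 0))

  z_re <- z; z_re$z <- z$z + 1
  shifted <- noreNormalize(z_re, z)
  expect_true(all(shifted$z_star == 1))

  # exact confounder cancellation: any per-(guide, replicate) constant
  # added to every screen leaves z* bit-for-bit unchanged
  conf <- dyadic(nrow(z))
  z_re2 <- z; z_re2$z <- z$z + dyadic(nrow(z))
  base <- noreNormalize(z_re2, z)
  z_re3 <- z_re2; z_re3$z <- z_re2$z + conf
  z_no3 <- z; z_no3$z <- z$z + conf
  expect_identical(noreNormalize(z_re3, z_no3)$z_star, base$z_star)
})

test_that("noRE normalization drops unmatched guides, errors above 10%", {
  lib <- random_library(seed = 1)
  z <- fake_guide_stats(lib, rnorm(90))
  expect_warning(out <- noreNormalize(z[-(1:3), ], z), "dropped")
  expect_equal(nrow(out), 87)
  expect_error(suppressWarnings(noreNormalize(z[-(1:20), ], z)), "unmatched")
})

test_that("interaction t-test matches the closed-form t and handles edge cases", {
  lib <- GuideLibrary(data.frame(guide_id = paste0("g", 1:5),
                                 target_id = "TF1", target_class = "tf"))
  vals <- c(1.0, 1.2, 0.8, 1.1, 0.9)
  zs <- data.frame(guide_id = paste0("g", 1:5), replicate = 1, z_star = vals)
  rec <- interactionTest(zs, lib, re_id = "RE96")
  expect_equal(rec$interaction_score, 1.0)
  t_direct <- mean(vals) / (sd(vals) / sqrt(5))
  expect_equal(rec$t_stat, t_direct)
  expect_equal(rec$p, 2 * pt(-abs(t_direct), df = 4))
  expect_identical(rec$direction, "repressive")

  # all-zero values: score 0, not significant
  zs0 <- zs; zs0$z_star <- 0
  rec0 <- interactionTest(zs0, lib, re_id = "RE96")
  expect_equal(rec0$interaction_score, 0)
  expect_false(rec0$significant)

  # < 3 guides: emitted with p = NA, never significant
  lib2 <- GuideLibrary(data.frame(guide_id = c("a", "b"), target_id = "TF9",
                                  target_class = "tf"))
  expect_message(
    rec2 <- interactionTest(data.frame(guide_id = c("a", "b"), replicate = 1,
                                       z_star = c(5, 5)), lib2, "RE1"),
    "< 3 matched guides")
  expect_true(is.na(rec2$p))
  expect_false(rec2$significant)
})

test_that("replicates are collapsed to per-guide means before testing", {
  lib <- GuideLibrary(data.frame(guide_id = paste0("g", 1:4),
                                 target_id = "TF1", target_class = "tf"))
  zs <- data.frame(guide_id = rep(paste0("g", 1:4), 3),
                   replicate = rep(1:3, each = 4),
                   z_star = c(1, 2, 3, 4, 1, 2, 3, 4, 1, 2, 3, 4))
  rec <- interactionTest(zs, lib, "RE1")
  vals <- c(1, 2, 3, 4)  # per-guide means
  expect_equal(rec$t_stat, mean(vals) / (sd(vals) / sqrt(4)))
  rec_pooled <- interactionTest(zs, lib, "RE1", pool_replicates = TRUE)
  expect_gt(abs(rec_pooled$t_stat), abs(rec$t_stat))
})

test_that("promoter-only confounders cancel and are excluded upstream", {
  lib <- generateLibrary(30, 8, 40, seed = 2)
  tfs <- sprintf("TF%03d", 1:30)
  eff <- matrix(0, 30, 1, dimnames = list(tfs, "RE61"))
  pe <- setNames(numeric(30), tfs); pe["TF005"] <- -2
  w <- WiringMatrix(eff, pe)
  zmeans <- vapply(1:10, function(s) {
    sim <- simulateReporterPanel(lib, w, cells = 2e4, depth = 5e4,
                                 replicates = 2, seed = s)
    pz <- lapply(sim$panel, screenGuideStats, comparison = "high_vs_low")
    zs <- noreNormalize(pz$RE61, pz$noRE)
    mean(zs$z_star[grepl("^TF005_", zs$guide_id)])
  }, numeric(1))
  expect_lt(abs(mean(zmeans)), 0.2)

  sim <- simulateReporterPanel(lib, w, cells = 5e4, depth = 1e5,
                               replicates = 3, seed = 99)
  pz <- lapply(sim$panel, screenGuideStats, comparison = "high_vs_low")
  excl <- excludeNoreResponders(pz$noRE, lib)
  expect_true("TF005" %in% excl$tf_id)
  im <- buildInteractionMatrix(pz, lib)
  expect_false("TF005" %in% interactions(im)$tf_id)
  expect_true("TF005" %in% exclusions(im)$tf_id)
})

test_that("single wired pair is recovered with the right sign at FDR 0.2", {
  lib <- generateLibrary(20, 8, 30, seed = 3)
  tfs <- sprintf("TF%03d", 1:20)
  eff <- matrix(0, 20, 1, dimnames = list(tfs, "RE96"))
  eff["TF001", "RE96"] <- -3
  w <- WiringMatrix(eff)
  sim <- simulateReporterPanel(lib, w, cells = 5e4, depth = 1e5,
                               replicates = 3, seed = 21)
  pz <- lapply(sim$panel, screenGuideStats, comparison = "high_vs_low")
  im <- buildInteractionMatrix(pz, lib)
  rec <- interactions(im)
  hit <- rec[rec$tf_id == "TF001", ]
  expect_true(hit$significant)
  expect_lt(hit$interaction_score, 0)
  expect_identical(hit$direction, "activating")
})

test_that("serialization applies the activator-positive flip exactly once", {
  lib <- GuideLibrary(data.frame(guide_id = paste0("g", 1:5),
                                 target_id = "TF1", target_class = "tf"))
  zs <- data.frame(guide_id = paste0("g", 1:5), replicate = 1,
                   z_star = c(-1, -1.2, -0.8, -1.1, -0.9))
  rec <- interactionTest(zs, lib, re_id = "RE61")
  im <- new("InteractionMatrix", records = rec,
            exclusions = data.frame(tf_id = character(),
                                    nore_fdr = numeric()),
            alpha = 0.2)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeInteractions(im, path)
  out <- read.delim(path, comment.char = "#")
  expect_equal(out$interaction_score, 1.0)  # activator prints positive
  expect_identical(out$direction, "activating")
  expect_match(readLines(path)[2], "activator-positive")
  # in-memory record still in knockdown space
  expect_equal(interactions(im)$interaction_score, -1.0)
})

test_that("reporter grouping recovers designed reporter groups", {
  lib <- generateLibrary(24, 6, 30, seed = 4)
  tfs <- sprintf("TF%03d", 1:24)
  eff <- matrix(0, 24, 4,
                dimnames = list(tfs, c("RE57L", "RE57M", "RE61", "RE96")))
  eff[1:6, c("RE57L", "RE57M")] <- -2.5   # proximal group
  eff[7:12, c("RE61", "RE96")] <- 2.5     # distal group
  w <- WiringMatrix(eff)
  sim <- simulateReporterPanel(lib, w, cells = 3e4, depth = 1e5,
                               replicates = 2, seed = 31)
  lfc <- do.call(rbind, lapply(names(sim$panel), function(re) {
    g <- guideLog2fc(normalizeCounts(sim$panel[[re]]), "high_vs_low",
                     screenSheet(sim$panel[[re]]))
    data.frame(reporter_id = re, replicate = g$replicate,
               guide_id = g$guide_id, log2fc = g$log2fc)
  }))
  grp <- reporterGrouping(lfc, lib, k = 3, seed = 7)
  expect_identical(length(unique(grp$cluster)), 3L)
  truth <- c(noRE = 1, RE57L = 2, RE57M = 2, RE61 = 3, RE96 = 3)
  expect_gte(mclust::adjustedRandIndex(grp$cluster, truth[grp$reporter_id]),
             0.9)
  # replicates of one reporter co-cluster
  expect_true(all(tapply(grp$cluster, grp$reporter_id,
                         function(x) length(unique(x))) == 1))

  # k = 1 gives a single label; k too large errors
  g1 <- reporterGrouping(lfc, lib, k = 1, seed = 7)
  expect_true(all(g1$cluster == 1))
  expect_error(reporterGrouping(lfc, lib, k = 11, seed = 7), "exceeds")
})

test_that("BH monotonicity: lowering alpha never adds significant pairs", {
  lib <- generateLibrary(15, 6, 20, seed = 5)
  tfs <- sprintf("TF%03d", 1:15)
  eff <- matrix(0, 15, 2, dimnames = list(tfs, c("RE1", "RE2")))
  eff["TF002", "RE1"] <- -2; eff["TF003", "RE2"] <- 1.5
  sim <- simulateReporterPanel(lib, WiringMatrix(eff), cells = 3e4,
                               depth = 5e4, replicates = 3, seed = 17)
  pz <- lapply(sim$panel, screenGuideStats, comparison = "high_vs_low")
  im20 <- buildInteractionMatrix(pz, lib, alpha = 0.2)
  im05 <- buildInteractionMatrix(pz, lib, alpha = 0.05)
  sig20 <- with(interactions(im20), paste(tf_id, re_id)[significant])
  sig05 <- with(interactions(im05), paste(tf_id, re_id)[significant])
  expect_true(all(sig05 %in% sig20))
})
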