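make_allelic_fixture <- function(n_genes = 30, seed = 1, ...) {
  gp <- simAllelicGeneParams(n_genes, frac_escapee = 0.2, seed = seed)
  sim <- simulateAllelicSC(gp, n_cells_per_condition = 250, seed = seed, ...)
  list(gp = gp, table = sim$table, truth = sim$truth)
}

test_that("Xist normalization anchors the reference median at 1", {
  fx <- make_allelic_fixture(seed = 3)
  xn <- normalizeXist(fx$table, "dtag_500")
  cd <- colData(fx$table)
  ref_pos <- cd$condition == "dtag_500" & cd$xist_count > 0
  expect_equal(median(xn[ref_pos]), 1)
  expect_true(all(xn[cd$xist_count == 0] == 0))
  expect_error(normalizeXist(fx$table, "nope"), "no Xist-positive")

  # dose ladder medians track the condition doses
  gp <- simAllelicGeneParams(5, 0, seed = 1)
  sim <- simulateAllelicSC(gp, condition_doses = c(ref = 1, half = 0.5,
                                                   quarter = 0.25),
                           n_cells_per_condition = 500, seed = 11)
  xn2 <- normalizeXist(sim$table, "ref")
  med <- tapply(xn2, colData(sim$table)$condition, median)
  expect_lt(abs(med[["half"]] - 0.5) / 0.5, 0.15)
  expect_lt(abs(med[["quarter"]] - 0.25) / 0.25, 0.15)
})

test_that("Xi assignment follows the allelic Xist majority with thresholds", {
  xa <- c(5, 3, 1, 0, 4, 10)
  xb <- c(0, 3, 0, 5, 1, 30)
  out <- assignXi(xa, xb)
  expect_identical(out$xi_allele,
                   c("a", "unassigned", "unassigned", "b", "a", "unassigned"))
  expect_identical(out$monoallelic, c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE))
  # (3,3): fraction 0.5 < 0.8 so unassigned; (1,0): below min reads
  expect_true(all(out$xi_allele[out$monoallelic] != "unassigned"))

  # accuracy on simulated truth (Xi is allele a, skew 0.95)
  fx <- make_allelic_fixture(seed = 5)
  cd <- colData(fx$table)
  xi <- assignXi(cd$xist_allele_a, cd$xist_allele_b)
  called <- xi$xi_allele != "unassigned"
  expect_gte(mean(xi$xi_allele[called] == "a"), 0.98)
})

test_that("chrX allelic fraction is the Xi read share, excluding Xist", {
  genes <- data.frame(gene_id = c("Xist", "gA", "gB", "gC"),
                      chromosome = "chrX")
  cells <- data.frame(cell_id = c("c1", "c2", "c3"), condition = "ref",
                      total_counts = 100L, xist_count = c(10L, 10L, 0L),
                      xist_allele_a = c(8L, 8L, 0L),
                      xist_allele_b = c(0L, 0L, 0L))
  a <- matrix(c(9, 2, 1, 0,   9, 0, 0, 0,  9, 5, 5, 5), 4,
              dimnames = list(genes$gene_id, cells$cell_id))
  b <- matrix(c(1, 3, 4, 5,   1, 4, 4, 4,  1, 5, 5, 5), 4,
              dimnames = list(genes$gene_id, cells$cell_id))
  tab <- AllelicCellTable(a, b, cells, genes)
  xi <- rep("a", 3)
  fr <- chrxAllelicFraction(tab, xi, min_allelic_x_reads = 10)
  expect_equal(unname(fr["c1"]), 3 / 15)       # hand arithmetic, Xist excluded
  expect_equal(unname(fr["c2"]), 0)            # fully silenced
  expect_equal(unname(fr["c3"]), 0.5)          # balanced
  expect_true(is.na(chrxAllelicFraction(tab, xi,
                                        min_allelic_x_reads = 16)["c1"]))
  expect_true(is.na(chrxAllelicFraction(tab, c("unassigned", "a", "a"))["c1"]))

  # invariance under simultaneous allele relabeling
  tab_swapped <- AllelicCellTable(b, a, cells, genes)
  fr_sw <- chrxAllelicFraction(tab_swapped, rep("b", 3),
                               min_allelic_x_reads = 10)
  expect_equal(fr, fr_sw)
})

test_that("equal-frequency Xist bins conserve cells and balance sizes", {
  fx <- make_allelic_fixture(seed = 7)
  rec <- cellSilencingRecords(fx$table, "dtag_500")
  bins <- binByXist(fx$table, rec, n_bins = 10)
  n_binned <- sum(rec$xist_positive & rec$monoallelic)
  expect_identical(sum(bins$bins$n_cells), n_binned)
  expect_lte(diff(range(bins$bins$n_cells)), 1L)
  expect_true(all(diff(bins$bins$dose) >= 0))
  expect_error(binByXist(fx$table, rec, n_bins = 1), "n_bins")

  # 100 cells in 10 bins: exactly 10 each
  rec100 <- rec[rec$xist_positive & rec$monoallelic, ][1:100, ]
  b100 <- binByXist(fx$table, rec100, n_bins = 10)
  expect_true(all(b100$bins$n_cells == 10))
  rec101 <- rec[rec$xist_positive & rec$monoallelic, ][1:101, ]
  b101 <- binByXist(fx$table, rec101, n_bins = 10)
  expect_lte(diff(range(b101$bins$n_cells)), 1L)
})

test_that("4PL fitting recovers noiseless parameters and satisfies the midpoint identity", {
  doses <- exp(seq(log(0.05), log(2), length.out = 10))
  truth <- list(b = 2, c = 0.05, d = 0.5, ed50 = 0.4)
  y <- truth$c + (truth$d - truth$c) / (1 + (doses / truth$ed50)^truth$b)
  fit <- fit4PL(doses, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$b - truth$b), 1e-4)
  expect_lt(abs(fit$c - truth$c), 1e-4)
  expect_lt(abs(fit$d - truth$d), 1e-4)
  expect_lt(abs(fit$ed50 - truth$ed50), 1e-4)
  expect_equal(predict4PL(fit, fit$ed50), (fit$c + fit$d) / 2)
  expect_false(classifyEscapee(fit))

  # constant response: flat fit routed to the escapee side
  flat <- suppressWarnings(fit4PL(doses, rep(0.5, 10)))
  expect_false(flat$converged)
  expect_true(classifyEscapee(flat))
  # too few bins: skipped with a warning
  expect_warning(skipped <- fit4PL(doses[1:3], y[1:3]), "skipped")
  expect_false(skipped$converged)
})

test_that("escapee classification follows the span/response/convergence rule", {
  doses <- exp(seq(log(0.05), log(2), length.out = 10))
  # strongly silenced gene is not an escapee
  y_sil <- 0.02 + (0.5 - 0.02) / (1 + (doses / 0.3)^2)
  expect_false(classifyEscapee(fit4PL(doses, y_sil)))
  # high plateau at max dose is an escapee even when converged
  y_high <- 0.38 + (0.52 - 0.38) / (1 + (doses / 0.3)^2)
  fit_high <- suppressWarnings(fit4PL(doses, y_high))
  expect_true(classifyEscapee(fit_high))
})

test_that("ED50 summaries take the median of silenced converged genes", {
  fits <- data.frame(gene = c("a", "b", "c", "d", "e"),
                     b = 2, c = 0.05, d = 0.5,
                     ed50 = c(0.2, 0.4, 0.6, 5, 2),
                     rss = 0.001, n_bins = 10,
                     converged = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                     escapee = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  s <- summarizeED50(fits)
  expect_equal(s$median_ed50, 0.4)
  expect_identical(s$n_genes, 3L)
  s1 <- summarizeED50(fits[2, ])
  expect_equal(s1$median_ed50, 0.4)
  expect_identical(summarizeED50(fits)$genes_above_reference, character(0))
  expect_error(summarizeED50(fits[fits$escapee, ]), "no converged")
})

test_that("full pipeline recovers per-gene ED50 and escapee status", {
  gp <- simAllelicGeneParams(40, frac_escapee = 0.2, seed = 14)
  sim <- simulateAllelicSC(gp, n_cells_per_condition = 500,
                           allelic_depth = 4, seed = 14)
  res <- doseResponsePipeline(sim$table, "dtag_500", n_bins = 10)
  fits <- merge(res$fits, gp, by = "gene")
  sil <- fits[!fits$escapee.y, ]
  rel_err <- abs(sil$ed50.x - sil$ed50.y) / sil$ed50.y
  expect_lte(median(rel_err, na.rm = TRUE), 0.2)
  sens <- mean(fits$escapee.x[fits$escapee.y])
  spec <- mean(!fits$escapee.x[!fits$escapee.y])
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.9)
  # monotone silencing: per-gene bin responses decrease with dose
  resp <- res$bins$gene_response[sil$gene, ]
  rho <- apply(resp, 1, function(r)
    suppressWarnings(cor(res$bins$bins$dose, r, method = "spearman",
                         use = "complete.obs")))
  expect_gte(mean(rho < 0, na.rm = TRUE), 0.95)
})
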