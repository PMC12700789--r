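# Seeded generators for every pipeline input, with the ground truth
# echoed in a SimTruth object so each analysis stage can be validated by
# parameter recovery. Every generator is a pure function of
# (parameters, seed).

.sim_truth <- function(type, seed, params) {
  structure(c(list(type = type, seed = seed), params), class = "SimTruth")
}

#' @export
print.SimTruth <- function(x, ...) {
  cat("SimTruth <", x$type, "> seed =", x$seed, "\n  parameters:",
      paste(setdiff(names(x), c("type", "seed")), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize / restore a SimTruth object
#'
#' @param truth a SimTruth list.
#' @param path JSON file path.
#' @export
writeSimTruth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeSimTruth
#' @export
readSimTruth <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE), class = "SimTruth")
}

#' Generate a synthetic sgRNA library
#'
#' TF targets are named `TF001..TFn` with `guides_per_target` guides
#' each; nontargeting guides share the single target `"NT"`.
#'
#' @param n_tf number of TF targets (>= 1).
#' @param guides_per_target guides per TF target (>= 1).
#' @param n_nontargeting number of nontargeting guides (>= 1).
#' @param seed integer seed (recorded; the layout is deterministic).
#' @return A [GuideLibrary-class].
#' @examples
#' lib <- generateLibrary(10, 4, 8, seed = 1)
#' length(guideIds(lib))   # 48
#' @export
generateLibrary <- function(n_tf, guides_per_target, n_nontargeting, seed = 1) {
  stopifnot(n_tf >= 1, guides_per_target >= 1, n_nontargeting >= 1)
  tf <- sprintf("TF%03d", seq_len(n_tf))
  df <- rbind(
    data.frame(guide_id = paste0(rep(tf, each = guides_per_target), "_g",
                                 rep(seq_len(guides_per_target), n_tf)),
               target_id = rep(tf, each = guides_per_target),
               target_class = "tf"),
    data.frame(guide_id = paste0("NT_g", seq_len(n_nontargeting)),
               target_id = "NT", target_class = "nontargeting"))
  GuideLibrary(df)
}

#' Sorting-gate specification for a sorted-bin screen
#'
#' Gates are quantile intervals over the measured latent phenotype,
#' recomputed per replicate (FACS gates on the observed distribution).
#' When a `neg` gate is present, the screen is treated as a FlowFISH
#' design: a negativity threshold is set at the 99th percentile of a
#' non-expressing reference draw, the `neg` interval is taken over all
#' cells, and the remaining gates are taken over the positive
#' (above-threshold) cells only. Without `neg`, all gates are quantiles
#' over all cells (GFP-reporter design).
#'
#' @param ... named quantile intervals, e.g. `high = c(0.85, 1)`,
#'   `low = c(0, 0.15)`, `neg = c(0, 0.15)`. Names must be valid
#'   populations.
#' @return A named list of intervals with class `"gateSpec"`.
#' @export
sortingGates <- function(...) {
  g <- list(...)
  if (!length(g) || is.null(names(g)) || any(names(g) == ""))
    stop("gates must be named quantile intervals")
  bad <- setdiff(names(g), c("high", "low", "neg", "selected"))
  if (length(bad)) stop("unknown gate population(s): ", paste(bad, collapse = ", "))
  for (nm in names(g)) {
    iv <- g[[nm]]
    if (length(iv) != 2 || iv[1] < 0 || iv[2] > 1 || iv[1] >= iv[2])
      stop("gate '", nm, "' must be an interval [lo, hi) within [0, 1]")
  }
  same_base <- setdiff(names(g), "neg")
  if (length(same_base) > 1) {
    ivs <- g[same_base]
    for (i in seq_along(ivs)[-1]) for (j in seq_len(i - 1))
      if (ivs[[i]][1] < ivs[[j]][2] && ivs[[j]][1] < ivs[[i]][2])
        stop("gate intervals '", same_base[j], "' and '", same_base[i],
             "' overlap")
  }
  structure(g, class = "gateSpec")
}

# Rank-based gate selection: exactly the cells whose ranks fall in
# (floor(lo*n), floor(hi*n)] among `base`, so "top 15% of 10,000" is
# exactly 1,500 cells.
.gate_select <- function(latent, base_idx, interval) {
  n <- length(base_idx)
  r <- rank(latent[base_idx], ties.method = "first")
  lo <- floor(interval[1] * n); hi <- floor(interval[2] * n)
  base_idx[r > lo & r <= hi]
}

#' Simulate a sorted-bin CRISPRi screen
#'
#' Each cell carries one guide (uniform over the library). Its latent
#' log-phenotype is Normal(`mu0` + effect of the guide's target, sd 1);
#' knockdown effects are given in sd units. For FlowFISH-style gates a
#' negativity threshold equals the 99th percentile of a non-expressing
#' reference draw (Normal(0, 1)). Sorted-bin guide counts are
#' Dirichlet-multinomial draws of `depth` reads over the within-bin
#' guide proportions; `dispersion = 0` gives a plain multinomial. An
#' `unsorted` sample is always included.
#'
#' @param library a [GuideLibrary-class].
#' @param phenotype_effect named numeric, effect per target in sd units
#'   (targets not named get 0; nontargeting is always 0).
#' @param gates a [sortingGates()] spec.
#' @param cells cells per replicate.
#' @param depth reads per sorted bin.
#' @param dispersion Dirichlet-multinomial dispersion (0 = multinomial).
#' @param replicates number of replicates.
#' @param seed integer seed.
#' @param screen_id screen identifier used in sample ids.
#' @param mu0 latent expression offset of expressing cells over the
#'   non-expressing reference (sd units).
#' @param reporter_id optional reporter id recorded in the sample sheet.
#' @return list with elements `counts` ([ScreenCounts-class]) and
#'   `truth` (SimTruth; includes per-replicate bin cell counts).
#' @export
simulateSortedScreen <- function(library, phenotype_effect = NULL,
                                 gates = sortingGates(high = c(0.85, 1),
                                                      low = c(0, 0.15),
                                                      neg = c(0, 0.15)),
                                 cells = 1e5, depth = 2e5, dispersion = 1e-4,
                                 replicates = 1, seed = 1,
                                 screen_id = "screen", mu0 = 3,
                                 reporter_id = NA_character_) {
  if (!inherits(gates, "gateSpec")) gates <- do.call(sortingGates, as.list(gates))
  lib <- guides(library)
  eff <- setNames(numeric(length(unique(lib$target_id))), unique(lib$target_id))
  if (!is.null(phenotype_effect)) {
    unknown <- setdiff(names(phenotype_effect), names(eff))
    if (length(unknown)) stop("effects for unknown target(s): ",
                              paste(unknown, collapse = ", "))
    eff[names(phenotype_effect)] <- phenotype_effect
  }
  eff[unique(lib$target_id[lib$target_class == "nontargeting"])] <- 0
  guide_eff <- eff[lib$target_id]
  G <- nrow(lib)
  pops <- c(names(gates), "unsorted")
  .with_seed(seed, {
    count_list <- list(); bin_cells <- list()
    for (r in seq_len(replicates)) {
      guide_of_cell <- sample.int(G, cells, replace = TRUE)
      latent <- stats::rnorm(cells, mu0 + guide_eff[guide_of_cell], 1)
      if ("neg" %in% names(gates)) {
        thr <- stats::quantile(stats::rnorm(cells, 0, 1), 0.99, names = FALSE)
        pos_idx <- which(latent > thr)
      } else pos_idx <- seq_len(cells)
      sizes <- integer()
      for (pop in pops) {
        idx <- if (pop == "unsorted") seq_len(cells)
               else if (pop == "neg") .gate_select(latent, seq_len(cells), gates$neg)
               else .gate_select(latent, pos_idx, gates[[pop]])
        sizes[pop] <- length(idx)
        prop <- tabulate(guide_of_cell[idx], nbins = G)
        cnt <- .rdirmult(depth, prop / sum(prop), dispersion)
        count_list[[paste0(screen_id, "_", pop, "_r", r)]] <- cnt
      }
      bin_cells[[r]] <- sizes
    }
    m <- do.call(cbind, count_list)
    rownames(m) <- lib$guide_id
    sheet <- SampleSheet(data.frame(
      sample_id = colnames(m),
      screen_id = screen_id,
      population = rep(pops, replicates),
      replicate = rep(seq_len(replicates), each = length(pops)),
      reporter_id = reporter_id))
    truth <- .sim_truth("sorted_screen", seed, list(
      screen_id = screen_id, effects = as.list(eff), gates = unclass(gates),
      cells = cells, depth = depth, dispersion = dispersion,
      overdispersed = dispersion > 0, replicates = replicates, mu0 = mu0,
      bin_cells = bin_cells))
    list(counts = ScreenCounts(m, library, sheet), truth = truth)
  })
}

#' Simulate a panel of GFP-reporter screens
#'
#' One sorted screen per reporter, including the minimal-promoter
#' `"noRE"` control. Each TF's knockdown shifts the latent reporter
#' phenotype by `wiringEffect(wiring)[tf, re] + promoterEffect(wiring)[tf]`;
#' the noRE reporter feels the promoter effect only. Default gates are
#' the GFP-High top 10% and GFP-Low bottom 10%.
#'
#' @param library a [GuideLibrary-class] whose TF targets are the rows of
#'   `wiring`.
#' @param wiring a [WiringMatrix-class].
#' @inheritParams simulateSortedScreen
#' @return list with `panel` (named list of [ScreenCounts-class], one per
#'   reporter including `"noRE"`) and `truth`.
#' @export
simulateReporterPanel <- function(library, wiring,
                                  gates = sortingGates(high = c(0.9, 1),
                                                       low = c(0, 0.1)),
                                  cells = 1e5, depth = 2e5, dispersion = 1e-4,
                                  replicates = 3, seed = 1, mu0 = 0) {
  eff <- wiringEffect(wiring)
  pe <- promoterEffect(wiring)
  tf_targets <- unique(guides(library)$target_id[
    guides(library)$target_class != "nontargeting"])
  missing_tf <- setdiff(tf_targets, rownames(eff))
  if (length(missing_tf))
    stop("wiring does not cover target(s): ", paste(missing_tf, collapse = ", "))
  reporters <- c("noRE", colnames(eff))
  .with_seed(seed, {
    panel <- list()
    for (re in reporters) {
      shift <- if (re == "noRE") pe else eff[, re] + pe
      sub_seed <- sample.int(.Machine$integer.max, 1)
      panel[[re]] <- simulateSortedScreen(
        library, phenotype_effect = shift, gates = gates, cells = cells,
        depth = depth, dispersion = dispersion, replicates = replicates,
        seed = sub_seed, screen_id = re, mu0 = mu0, reporter_id = re)
    }
    truth <- .sim_truth("reporter_panel", seed, list(
      reporters = reporters, effect = eff, promoter_effect = as.list(pe),
      gates = unclass(gates), cells = cells, depth = depth,
      dispersion = dispersion, overdispersed = dispersion > 0,
      replicates = replicates, mu0 = mu0))
    list(panel = lapply(panel, `[[`, "counts"), truth = truth)
  })
}

# Smooth archetype mean curves on [0, max(t)], scaled to (0, 1].
.archetype_curve <- function(archetype, peak_h, t) {
  T <- max(t)
  switch(archetype,
         naive = exp(-3 * t / T),
         committed = 1 / (1 + exp(-(t - T / 2) / (T / 10))),
         transient = exp(-(t - peak_h)^2 / (2 * 12^2)),
         stop("unknown archetype: ", archetype))
}

#' Simulate an expression time course
#'
#' Genes follow one of three smooth archetypes over differentiation:
#' `naive` (monotone decreasing), `committed` (monotone increasing) or
#' `transient` (unimodal with an interior peak at `peak_h`). XX samples
#' carry an additional per-gene log2 offset (`xx_bias`); XO samples do
#' not. Counts are negative binomial around the archetype mean;
#' `nb_dispersion = 0` returns the noise-free means.
#'
#' @param archetypes data.frame with columns `gene`, `archetype`
#'   (`"naive"`, `"transient"`, `"committed"`) and `peak_h` (required
#'   for transient genes; must lie strictly inside the timepoint range).
#' @param xx_bias named numeric per gene, log2 XX/XO offset (default 0).
#' @param timepoints hours, ascending; defaults to the 0-96 h design.
#' @param replicates replicates per (timepoint, genotype).
#' @param nb_dispersion negative-binomial dispersion (1/size); 0 = none.
#' @param base_mean mean expression scale (counts).
#' @param background_genes number of flat housekeeping genes (`BG...`)
#'   added at `background_mean`; they emulate the stable transcriptome
#'   majority so CPM normalization is compositionally stable, and are
#'   degenerate (constant) in the noise-free limit.
#' @param background_mean mean expression of background genes.
#' @param seed integer seed.
#' @return list with `course` ([ExpressionCourse-class], genotypes XX and
#'   XO) and `truth`.
#' @export
simulateExpressionCourse <- function(archetypes, xx_bias = NULL,
                                     timepoints = c(0, 10, 16, 24, 30, 36,
                                                    48, 56, 72, 96),
                                     replicates = 3, nb_dispersion = 0.05,
                                     base_mean = 100, background_genes = 50,
                                     background_mean = 10 * base_mean,
                                     seed = 1) {
  stopifnot(is.data.frame(archetypes),
            all(c("gene", "archetype") %in% names(archetypes)))
  timepoints <- sort(timepoints)
  if (is.null(archetypes$peak_h)) archetypes$peak_h <- NA_real_
  tr <- archetypes$archetype == "transient"
  if (any(tr & (is.na(archetypes$peak_h) |
                archetypes$peak_h <= min(timepoints) |
                archetypes$peak_h >= max(timepoints))))
    stop("transient peak_h must lie strictly inside the timepoint range")
  bias <- setNames(numeric(nrow(archetypes)), archetypes$gene)
  if (!is.null(xx_bias)) bias[names(xx_bias)] <- xx_bias
  genes <- archetypes$gene
  obs <- expand.grid(replicate = seq_len(replicates), timepoint_h = timepoints,
                     genotype = c("XX", "XO"), stringsAsFactors = FALSE)
  mu <- matrix(NA_real_, length(genes), nrow(obs),
               dimnames = list(genes, NULL))
  for (i in seq_along(genes)) {
    s <- .archetype_curve(archetypes$archetype[i], archetypes$peak_h[i],
                          obs$timepoint_h)
    m <- base_mean * (0.05 + 0.95 * s)
    m[obs$genotype == "XX"] <- m[obs$genotype == "XX"] * 2^bias[i]
    mu[i, ] <- m
  }
  if (background_genes > 0) {
    bg <- matrix(background_mean, background_genes, nrow(obs),
                 dimnames = list(sprintf("BG%03d", seq_len(background_genes)),
                                 NULL))
    mu <- rbind(mu, bg)
  }
  .with_seed(seed, {
    vals <- if (nb_dispersion > 0)
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion),
             nrow(mu), dimnames = dimnames(mu))
    else mu
    course <- ExpressionCourse(vals, timepoint_h = obs$timepoint_h,
                               genotype = obs$genotype,
                               replicate = obs$replicate, unit = "counts")
    truth <- .sim_truth("expression_course", seed, list(
      archetype = setNames(as.list(archetypes$archetype), genes),
      peak_h = setNames(as.list(archetypes$peak_h), genes),
      xx_bias = as.list(bias), timepoints = timepoints,
      replicates = replicates, nb_dispersion = nb_dispersion,
      base_mean = base_mean, background_genes = background_genes,
      background_mean = background_mean))
    list(course = course, truth = truth)
  })
}

#' Draw per-gene dose-response parameters for the allelic simulator
#'
#' Silenced genes get ED50 log-uniform in `ed50_range`, slope uniform in
#' `slope_range`, upper asymptote near the biallelic 0.5 and a low lower
#' asymptote. Escapees get upper = lower = 0.5 (no dose response).
#'
#' @param n_genes number of chrX genes.
#' @param frac_escapee fraction simulated as escapees.
#' @param ed50_range,slope_range parameter ranges for silenced genes.
#' @param seed integer seed.
#' @return data.frame with columns `gene`, `ed50`, `slope`, `upper`,
#'   `lower`, `escapee`.
#' @export
simAllelicGeneParams <- function(n_genes = 40, frac_escapee = 0.2,
                                 ed50_range = c(0.1, 2),
                                 slope_range = c(1.5, 3.5), seed = 1) {
  .with_seed(seed, {
    n_esc <- round(n_genes * frac_escapee)
    esc <- rep(c(FALSE, TRUE), c(n_genes - n_esc, n_esc))
    df <- data.frame(
      gene = sprintf("Xgene%03d", seq_len(n_genes)),
      ed50 = exp(stats::runif(n_genes, log(ed50_range[1]), log(ed50_range[2]))),
      slope = stats::runif(n_genes, slope_range[1], slope_range[2]),
      upper = stats::runif(n_genes, 0.45, 0.55),
      lower = stats::runif(n_genes, 0.01, 0.08),
      escapee = esc)
    df$upper[esc] <- 0.5
    df$lower[esc] <- 0.5
    df
  })
}

# Four-parameter log-logistic silencing law: allelic fraction as a
# function of relative Xist dose.
.fourpl <- function(x, b, c, d, e) c + (d - c) / (1 + (x / e)^b)

#' Simulate allele-resolved single-cell counts under Xist titration
#'
#' Each condition has a relative Xist dose; a cell's true dose is the
#' condition dose times lognormal noise. Xist counts are negative
#' binomial with a dose-scaled mean; the inactive X is allele `a` and
#' most allelic Xist reads come from it. Per gene, the Xi-allelic
#' fraction follows the four-parameter log-logistic law
#' `lower + (upper - lower) / (1 + (dose/ed50)^slope)` of the cell's
#' true dose, and Xi-allele counts are binomial draws from the gene's
#' allelic reads. Escapees (`upper = lower = 0.5`) show no response.
#'
#' @param gene_params data.frame as from [simAllelicGeneParams()].
#' @param condition_doses named numeric, relative Xist dose per
#'   condition; the reference (no-knockdown) condition should be 1.
#' @param n_cells_per_condition cells per condition.
#' @param allelic_depth mean allelic reads per gene per cell (Poisson).
#' @param xist_mean_ref mean Xist count at dose 1.
#' @param xist_dispersion NB dispersion of Xist counts (1/size).
#' @param dose_sdlog lognormal sd of per-cell dose around the condition
#'   dose.
#' @param xist_skew probability that an allelic Xist read maps to the Xi.
#' @param total_counts_mean mean total UMI per cell (Poisson).
#' @param dtag_nM optional named numeric, dTAG concentration per
#'   condition (metadata only).
#' @param seed integer seed.
#' @return list with `table` ([AllelicCellTable-class]) and `truth`
#'   (SimTruth; includes per-cell true doses and the gene parameters).
#' @export
simulateAllelicSC <- function(gene_params,
                              condition_doses = c(dtag_500 = 1, dtag_50 = 0.7,
                                                  dtag_15 = 0.5, dtag_5 = 0.35,
                                                  dtag_2 = 0.2, dtag_0 = 0.1),
                              n_cells_per_condition = 500,
                              allelic_depth = 3, xist_mean_ref = 50,
                              xist_dispersion = 0.1, dose_sdlog = 0.25,
                              xist_skew = 0.95, total_counts_mean = 5000,
                              dtag_nM = NULL, seed = 1) {
  stopifnot(all(gene_params$ed50 > 0),
            all(gene_params$lower >= 0), all(gene_params$upper <= 1),
            all(gene_params$lower <= gene_params$upper))
  conds <- names(condition_doses)
  if (is.null(conds)) stop("condition_doses must be named")
  n_cond <- length(conds)
  n_total <- n_cond * n_cells_per_condition
  G <- nrow(gene_params)
  .with_seed(seed, {
    condition <- rep(conds, each = n_cells_per_condition)
    dose <- condition_doses[condition] *
      stats::rlnorm(n_total, 0, dose_sdlog)
    total_counts <- stats::rpois(n_total, total_counts_mean)
    xist_count <- as.integer(stats::rnbinom(n_total, mu = xist_mean_ref * dose,
                                            size = 1 / xist_dispersion))
    n_allelic_xist <- stats::rbinom(n_total, xist_count, 0.5)
    xist_allele_a <- stats::rbinom(n_total, n_allelic_xist, xist_skew)
    xist_allele_b <- n_allelic_xist - xist_allele_a
    a <- matrix(0L, G, n_total); b <- matrix(0L, G, n_total)
    for (i in seq_len(G)) {
      n_reads <- stats::rpois(n_total, allelic_depth)
      p <- .fourpl(dose, gene_params$slope[i], gene_params$lower[i],
                   gene_params$upper[i], gene_params$ed50[i])
      a[i, ] <- stats::rbinom(n_total, n_reads, p)
      b[i, ] <- n_reads - a[i, ]
    }
    cells <- data.frame(
      cell_id = sprintf("cell%05d", seq_len(n_total)),
      condition = condition,
      dtag_nM = if (is.null(dtag_nM)) NA_real_ else unname(dtag_nM[condition]),
      line = "synthetic",
      total_counts = total_counts,
      xist_count = xist_count,
      xist_allele_a = xist_allele_a,
      xist_allele_b = xist_allele_b)
    genes <- data.frame(gene_id = gene_params$gene, chromosome = "chrX",
                        position_bp = seq_len(G) * 100000L)
    dimnames(a) <- dimnames(b) <- list(genes$gene_id, cells$cell_id)
    table <- AllelicCellTable(as(Matrix::Matrix(a, sparse = TRUE), "CsparseMatrix"),
                              as(Matrix::Matrix(b, sparse = TRUE), "CsparseMatrix"),
                              cells, genes)
    truth <- .sim_truth("allelic_sc", seed, list(
      gene_params = gene_params, condition_doses = as.list(condition_doses),
      n_cells_per_condition = n_cells_per_condition,
      allelic_depth = allelic_depth, xist_mean_ref = xist_mean_ref,
      xist_dispersion = xist_dispersion, dose_sdlog = dose_sdlog,
      xist_skew = xist_skew, true_dose = unname(dose)))
    list(table = table, truth = truth)
  })
}
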