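# Allele-specific single-cell pipeline: Xist-positive calling, Xi
# assignment from allelic Xist reads (Xist coats the inactive X),
# chromosome-wide allelic fraction, equal-frequency Xist-dose binning
# and per-gene four-parameter log-logistic dose-response fits (ED50).

#' Normalize per-cell Xist expression to the reference condition
#'
#' Xist counts per 10k total counts, divided by the median over
#' Xist-positive cells of the reference (no-knockdown) condition, so the
#' reference median is 1 by construction.
#'
#' @param x an [AllelicCellTable-class].
#' @param reference_condition condition label of the no-knockdown
#'   reference (e.g. the highest-dTAG condition).
#' @return numeric vector of relative Xist levels, one per cell.
#' @export
normalizeXist <- function(x, reference_condition) {
  cd <- colData(x)
  cp10k <- cd$xist_count / cd$total_counts * 1e4
  ref <- cd$condition == reference_condition & cd$xist_count > 0
  if (!any(ref))
    .stopf("reference condition '%s' has no Xist-positive cells",
           reference_condition)
  setNames(cp10k / stats::median(cp10k[ref]), colnames(x))
}

#' Assign the inactive X from allelic Xist reads
#'
#' Xist RNA coats the Xi, so the Xi is the allele carrying the majority
#' of allelic Xist reads. Cells need at least `min_allelic_xist` allelic
#' Xist reads; `monoallelic` requires the majority fraction to reach
#' `monoallelic_fraction`, otherwise the cell is `unassigned`.
#'
#' @param xist_allele_a,xist_allele_b allelic Xist read counts (vectors).
#' @param min_allelic_xist minimum allelic Xist reads (default 2).
#' @param monoallelic_fraction majority fraction required (default 0.8).
#' @return data.frame with columns `xi_allele` (`"a"`, `"b"`,
#'   `"unassigned"`) and `monoallelic`.
#' @export
assignXi <- function(xist_allele_a, xist_allele_b, min_allelic_xist = 2,
                     monoallelic_fraction = 0.8) {
  tot <- xist_allele_a + xist_allele_b
  frac_major <- pmax(xist_allele_a, xist_allele_b) / tot
  ok <- tot >= min_allelic_xist & is.finite(frac_major) &
    frac_major >= monoallelic_fraction & xist_allele_a != xist_allele_b
  xi <- ifelse(ok, ifelse(xist_allele_a > xist_allele_b, "a", "b"),
               "unassigned")
  data.frame(xi_allele = xi, monoallelic = ok)
}

#' Chromosome-wide Xi allelic fraction per cell
#'
#' Fraction of allele-resolved chrX reads arising from the Xi: the sum
#' over chrX genes of Xi-allele counts divided by the sum of both-allele
#' counts. 0.5 means no silencing, 0 complete silencing. Xist itself is
#' expressed from the Xi and is excluded (as are any genes listed in
#' `exclude`, e.g. known escapees). NA when the Xi is unassigned or the
#' denominator is below `min_allelic_x_reads`.
#'
#' @param x an [AllelicCellTable-class].
#' @param xi_allele per-cell Xi labels from [assignXi()].
#' @param min_allelic_x_reads minimum informative reads (default 10).
#' @param exclude gene ids to exclude (default `"Xist"` if present).
#' @return numeric vector, one fraction (or NA) per cell.
#' @export
chrxAllelicFraction <- function(x, xi_allele, min_allelic_x_reads = 10,
                                exclude = "Xist") {
  keep <- rowData(x)$chromosome == "chrX" & !(rownames(x) %in% exclude)
  a <- Matrix::colSums(assay(x, "allele_a")[keep, , drop = FALSE])
  b <- Matrix::colSums(assay(x, "allele_b")[keep, , drop = FALSE])
  xi_counts <- ifelse(xi_allele == "a", a, ifelse(xi_allele == "b", b, NA))
  tot <- a + b
  out <- xi_counts / tot
  out[is.na(xi_counts) | tot < min_allelic_x_reads] <- NA_real_
  setNames(out, colnames(x))
}

#' Per-cell silencing records
#'
#' Assembles the per-cell table driving the dose-response analysis:
#' normalized Xist level, Xist-positive flag (> 0 counts), Xi
#' assignment, and the chrX allelic fraction.
#'
#' @param x an [AllelicCellTable-class].
#' @inheritParams normalizeXist
#' @inheritParams assignXi
#' @inheritParams chrxAllelicFraction
#' @return data.frame with one row per cell: `cell_id`, `condition`,
#'   `xist_count`, `xist_norm`, `xist_positive`, `xi_allele`,
#'   `monoallelic`, `n_allelic_x_reads`, `chrx_allelic_fraction`.
#' @export
cellSilencingRecords <- function(x, reference_condition,
                                 min_allelic_xist = 2,
                                 monoallelic_fraction = 0.8,
                                 min_allelic_x_reads = 10,
                                 exclude = "Xist") {
  cd <- colData(x)
  xi <- assignXi(cd$xist_allele_a, cd$xist_allele_b, min_allelic_xist,
                 monoallelic_fraction)
  keep <- rowData(x)$chromosome == "chrX" & !(rownames(x) %in% exclude)
  n_allelic <- Matrix::colSums(assay(x, "allele_a")[keep, , drop = FALSE]) +
    Matrix::colSums(assay(x, "allele_b")[keep, , drop = FALSE])
  data.frame(cell_id = colnames(x),
             condition = cd$condition,
             xist_count = cd$xist_count,
             xist_norm = unname(normalizeXist(x, reference_condition)),
             xist_positive = cd$xist_count > 0,
             xi_allele = xi$xi_allele,
             monoallelic = xi$monoallelic,
             n_allelic_x_reads = as.integer(unname(n_allelic)),
             chrx_allelic_fraction =
               unname(chrxAllelicFraction(x, xi$xi_allele,
                                          min_allelic_x_reads, exclude)),
             row.names = NULL)
}

#' Group monoallelic Xist-positive cells into Xist-dose bins
#'
#' Equal-frequency bins on the normalized Xist level (member counts
#' differ by at most 1). The bin dose is the median `xist_norm` of its
#' members; per gene, the bin response is the mean Xi-allelic fraction
#' over member cells with at least one allelic read for that gene.
#'
#' @param x an [AllelicCellTable-class].
#' @param records per-cell records from [cellSilencingRecords()],
#'   already restricted by the caller or filtered here to monoallelic
#'   Xist-positive cells.
#' @param n_bins number of bins (default 10; must be >= 2).
#' @return list of class `"DoseBins"`: `bins` (data.frame `bin_index`,
#'   `lo`, `hi`, `dose`, `n_cells`), `gene_response` and `gene_n`
#'   (gene-by-bin matrices), `cell_bins` (named bin index per binned
#'   cell).
#' @export
binByXist <- function(x, records, n_bins = 10) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  rec <- records[records$xist_positive & records$monoallelic, , drop = FALSE]
  n <- nrow(rec)
  if (n < n_bins) .stopf("only %d monoallelic Xist+ cells for %d bins", n, n_bins)
  ord <- order(rec$xist_norm, rec$cell_id)
  # equal-frequency assignment: sizes differ by <= 1
  bin_of <- integer(n)
  bin_of[ord] <- rep(seq_len(n_bins), diff(floor(seq(0, n, length.out = n_bins + 1))))
  a <- assay(x, "allele_a")[, rec$cell_id, drop = FALSE]
  b <- assay(x, "allele_b")[, rec$cell_id, drop = FALSE]
  xi_a <- rec$xi_allele == "a"
  xi_counts <- a
  if (any(!xi_a)) xi_counts[, !xi_a] <- b[, !xi_a, drop = FALSE]
  tot <- a + b
  frac <- as.matrix(xi_counts) / as.matrix(tot)  # NaN where no allelic reads
  gene_response <- matrix(NA_real_, nrow(x), n_bins,
                          dimnames = list(rownames(x), NULL))
  gene_n <- matrix(0L, nrow(x), n_bins, dimnames = list(rownames(x), NULL))
  bins <- data.frame(bin_index = seq_len(n_bins), lo = NA_real_, hi = NA_real_,
                     dose = NA_real_, n_cells = NA_integer_)
  for (bi in seq_len(n_bins)) {
    members <- bin_of == bi
    bins$n_cells[bi] <- sum(members)
    bins$lo[bi] <- min(rec$xist_norm[members])
    bins$hi[bi] <- max(rec$xist_norm[members])
    bins$dose[bi] <- stats::median(rec$xist_norm[members])
    fr <- frac[, members, drop = FALSE]
    inf <- !is.na(fr)
    gene_n[, bi] <- rowSums(inf)
    gene_response[, bi] <- ifelse(gene_n[, bi] > 0,
                                  rowSums(fr, na.rm = TRUE) / gene_n[, bi],
                                  NA_real_)
  }
  structure(list(bins = bins, gene_response = gene_response, gene_n = gene_n,
                 cell_bins = setNames(bin_of, rec$cell_id)),
            class = "DoseBins")
}

#' @export
print.DoseBins <- function(x, ...) {
  cat("DoseBins:", nrow(x$bins), "equal-frequency Xist-dose bins over",
      sum(x$bins$n_cells), "cells; dose range",
      signif(min(x$bins$dose), 3), "-", signif(max(x$bins$dose), 3), "\n")
  invisible(x)
}

#' Fit a four-parameter log-logistic dose-response curve
#'
#' Least-squares fit of `f(x) = c + (d - c) / (1 + (x/ed50)^b)` with
#' slope b > 0 (response decreases with dose from upper asymptote d to
#' lower asymptote c), box bounds c, d in [0, 0.6] (tolerating mapping
#' bias above the theoretical biallelic 0.5) and ed50 in (1e-3, 1e2).
#' Five starts over log-spaced ED50 values; the best RSS wins. ED50 is
#' the fitted midpoint parameter: `f(ed50) = (c + d)/2` exactly by
#' construction. The fit is flagged non-converged when the optimizer
#' fails, the asymptotes invert, or the 4PL does not beat a constant fit
#' by at least 5% RSS.
#'
#' @param doses bin doses (relative Xist level).
#' @param responses bin responses (mean Xi-allelic fraction); NA pairs
#'   are dropped.
#' @param lower_bounds,upper_bounds named bounds for `b`, `c`, `d`,
#'   `ed50`.
#' @param min_bins minimum informative bins (default 5).
#' @return list of class `"DoseResponseFit"`: `b`, `c`, `d`, `ed50`,
#'   `rss`, `converged`, `n_bins`, `max_dose`, `response_at_max_dose`.
#' @export
fit4PL <- function(doses, responses,
                   lower_bounds = c(b = 0.01, c = 0, d = 0, ed50 = 1e-3),
                   upper_bounds = c(b = 50, c = 0.6, d = 0.6, ed50 = 1e2),
                   min_bins = 5) {
  ok <- is.finite(doses) & is.finite(responses)
  x <- doses[ok]; y <- responses[ok]
  out <- list(b = NA_real_, c = NA_real_, d = NA_real_, ed50 = NA_real_,
              rss = NA_real_, converged = FALSE, n_bins = length(x),
              max_dose = if (length(x)) max(x) else NA_real_,
              response_at_max_dose = NA_real_)
  if (length(x) < min_bins) {
    .warnf("fit skipped: %d informative bins < %d", length(x), min_bins)
    return(structure(out, class = "DoseResponseFit"))
  }
  rss_const <- sum((y - mean(y))^2)
  best <- NULL
  starts_e <- exp(seq(log(max(min(x), 1e-3)), log(max(x)), length.out = 5))
  for (e0 in starts_e) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ c + (d - c) / (1 + (x / ed50)^b),
        start = list(b = 2,
                     c = max(min(y), lower_bounds[["c"]]),
                     d = min(max(y), upper_bounds[["d"]]),
                     ed50 = e0),
        lower = lower_bounds[c("b", "c", "d", "ed50")],
        upper = upper_bounds[c("b", "c", "d", "ed50")],
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(coef = stats::coef(fit), rss = rss)
  }
  if (is.null(best)) return(structure(out, class = "DoseResponseFit"))
  cf <- best$coef
  out$b <- unname(cf[["b"]]); out$c <- unname(cf[["c"]])
  out$d <- unname(cf[["d"]]); out$ed50 <- unname(cf[["ed50"]])
  out$rss <- best$rss
  out$response_at_max_dose <- .fourpl(out$max_dose, out$b, out$c, out$d,
                                      out$ed50)
  out$converged <- out$c <= out$d && out$ed50 > 0 &&
    best$rss <= 0.95 * rss_const
  structure(out, class = "DoseResponseFit")
}

#' @export
print.DoseResponseFit <- function(x, ...) {
  cat(sprintf(
    "DoseResponseFit: ed50 = %.3g, b = %.3g, c = %.3g, d = %.3g (rss %.3g, %s)\n",
    x$ed50, x$b, x$c, x$d, x$rss,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Predict a 4PL response
#'
#' @param fit a `"DoseResponseFit"`.
#' @param dose relative Xist level(s).
#' @return predicted Xi-allelic fraction(s).
#' @export
predict4PL <- function(fit, dose) .fourpl(dose, fit$b, fit$c, fit$d, fit$ed50)

#' Classify a gene as an escapee
#'
#' A gene escapes Xist-mediated silencing when its dose-response is
#' flat or stays high: escapee iff the fitted span (d - c) is below
#' `min_span`, the fitted response at the maximum observed dose exceeds
#' `max_dose_response_threshold`, or the fit did not converge.
#'
#' @param fit a `"DoseResponseFit"`.
#' @param max_dose_response_threshold allelic fraction above which the
#'   gene is not considered silenced at full dose (default 0.35).
#' @param min_span minimum asymptote span for a real response
#'   (default 0.1).
#' @param max_dose the maximum observed dose at which the fitted curve
#'   is evaluated; defaults to the largest dose that entered the fit.
#'   The pipeline passes the highest normalized Xist level among binned
#'   cells, so slowly silencing genes (large ED50) are judged over the
#'   full observed range rather than at the top bin's median.
#' @return logical escapee flag.
#' @export
classifyEscapee <- function(fit, max_dose_response_threshold = 0.35,
                            min_span = 0.1, max_dose = fit$max_dose) {
  if (!fit$converged) return(TRUE)
  (fit$d - fit$c) < min_span ||
    predict4PL(fit, max_dose) > max_dose_response_threshold
}

#' Fit dose-response curves for all genes
#'
#' Runs [fit4PL()] on each gene's per-bin responses and classifies
#' escapees.
#'
#' @param bins a `"DoseBins"` from [binByXist()].
#' @param min_informative_cells per-bin minimum informative cells for a
#'   gene's bin to enter the fit (default 1).
#' @inheritParams classifyEscapee
#' @inheritParams fit4PL
#' @return data.frame with one row per gene: `gene`, `b`, `c`, `d`,
#'   `ed50`, `rss`, `n_bins`, `converged`, `escapee`.
#' @export
fitDoseResponses <- function(bins, min_informative_cells = 1,
                             max_dose_response_threshold = 0.35,
                             min_span = 0.1, min_bins = 5) {
  genes <- rownames(bins$gene_response)
  max_observed <- max(bins$bins$hi)
  rows <- lapply(genes, function(g) {
    resp <- bins$gene_response[g, ]
    resp[bins$gene_n[g, ] < min_informative_cells] <- NA_real_
    fit <- suppressWarnings(fit4PL(bins$bins$dose, resp, min_bins = min_bins))
    data.frame(gene = g, b = fit$b, c = fit$c, d = fit$d, ed50 = fit$ed50,
               rss = fit$rss, n_bins = fit$n_bins, converged = fit$converged,
               escapee = classifyEscapee(fit, max_dose_response_threshold,
                                         min_span, max_dose = max_observed))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Summarize ED50 values over silenced genes
#'
#' Median ED50 over converged, non-escapee genes; genes with ED50 > 1
#' need supra-reference Xist levels for half-silencing and are flagged.
#'
#' @param fits data.frame from [fitDoseResponses()].
#' @return list: `median_ed50`, `n_genes`, `genes_above_reference`
#'   (ids with ED50 > 1), `table` (the non-escapee fit rows).
#' @export
summarizeED50 <- function(fits) {
  keep <- fits$converged & !fits$escapee
  if (!any(keep)) stop("no converged non-escapee fits")
  tab <- fits[keep, , drop = FALSE]
  list(median_ed50 = stats::median(tab$ed50), n_genes = nrow(tab),
       genes_above_reference = tab$gene[tab$ed50 > 1], table = tab)
}

#' Full allelic dose-response pipeline
#'
#' [cellSilencingRecords()] then [binByXist()] then [fitDoseResponses()]
#' then [summarizeED50()].
#'
#' @param x an [AllelicCellTable-class].
#' @inheritParams cellSilencingRecords
#' @inheritParams binByXist
#' @inheritParams fitDoseResponses
#' @return list: `records`, `bins`, `fits`, `summary`.
#' @export
doseResponsePipeline <- function(x, reference_condition, n_bins = 10,
                                 min_allelic_xist = 2,
                                 monoallelic_fraction = 0.8,
                                 min_allelic_x_reads = 10,
                                 exclude = "Xist",
                                 max_dose_response_threshold = 0.35,
                                 min_span = 0.1, min_bins = 5) {
  records <- cellSilencingRecords(x, reference_condition, min_allelic_xist,
                                  monoallelic_fraction, min_allelic_x_reads,
                                  exclude)
  bins <- binByXist(x, records, n_bins)
  fits <- fitDoseResponses(bins,
                           max_dose_response_threshold =
                             max_dose_response_threshold,
                           min_span = min_span, min_bins = min_bins)
  list(records = records, bins = bins, fits = fits,
       summary = summarizeED50(fits))
}
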