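#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

.TARGET_CLASSES <- c("tf", "control", "nontargeting")
.POPULATIONS <- c("high", "low", "neg", "unsorted", "selected")

#' GuideLibrary: an sgRNA library table
#'
#' Maps each guide to its target and records whether the target is a
#' transcription factor, a non-TF control, or a nontargeting control.
#' Nontargeting guides serve as the null reference for the surrogate
#' target-level test.
#'
#' @slot guides data.frame with columns `guide_id`, `target_id`,
#'   `target_class` (one of `"tf"`, `"control"`, `"nontargeting"`).
#' @export
setClass("GuideLibrary", slots = c(guides = "data.frame"))

setValidity("GuideLibrary", function(object) {
  g <- object@guides
  need <- c("guide_id", "target_id", "target_class")
  if (!all(need %in% names(g)))
    return(paste("missing column(s):", paste(setdiff(need, names(g)), collapse = ", ")))
  dup <- unique(g$guide_id[duplicated(g$guide_id)])
  if (length(dup))
    return(paste("duplicate guide_id:", paste(dup, collapse = ", ")))
  bad <- setdiff(unique(g$target_class), .TARGET_CLASSES)
  if (length(bad))
    return(paste("unknown target_class:", paste(bad, collapse = ", ")))
  TRUE
})

#' Construct a GuideLibrary
#'
#' @param guides data.frame with columns `guide_id`, `target_id`,
#'   `target_class`.
#' @return A [GuideLibrary-class] object.
#' @examples
#' lib <- GuideLibrary(data.frame(
#'   guide_id = c("g1", "g2", "g3"),
#'   target_id = c("Oct4", "Oct4", "NT"),
#'   target_class = c("tf", "tf", "nontargeting")))
#' guideIds(lib)
#' @export
GuideLibrary <- function(guides) {
  guides <- as.data.frame(guides, stringsAsFactors = FALSE)
  for (col in intersect(names(guides), c("guide_id", "target_id", "target_class")))
    guides[[col]] <- as.character(guides[[col]])
  rownames(guides) <- NULL
  new("GuideLibrary", guides = guides)
}

#' SampleSheet: sample annotation for sorted-bin screens
#'
#' One row per sequenced sample, identifying the screen, the sorted
#' population (`high`/`low`/`neg`/`unsorted`/`selected`), the replicate
#' and, for reporter screens, the reporter cassette (`"noRE"` is reserved
#' for the minimal-promoter control reporter).
#'
#' @slot samples data.frame with columns `sample_id`, `screen_id`,
#'   `population`, `replicate` and optionally `reporter_id`.
#' @export
setClass("SampleSheet", slots = c(samples = "data.frame"))

setValidity("SampleSheet", function(object) {
  s <- object@samples
  need <- c("sample_id", "screen_id", "population", "replicate")
  if (!all(need %in% names(s)))
    return(paste("missing column(s):", paste(setdiff(need, names(s)), collapse = ", ")))
  if (anyDuplicated(s$sample_id))
    return(paste("duplicate sample_id:",
                 paste(unique(s$sample_id[duplicated(s$sample_id)]), collapse = ", ")))
  bad <- setdiff(unique(s$population), .POPULATIONS)
  if (length(bad))
    return(paste("unknown population:", paste(bad, collapse = ", ")))
  if (any(s$replicate < 1) || any(s$replicate != round(s$replicate)))
    return("replicate must be an integer >= 1")
  key <- paste(s$screen_id, s$population, s$replicate)
  if (anyDuplicated(key))
    return(paste("duplicate (screen_id, population, replicate):",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  TRUE
})

#' Construct a SampleSheet
#'
#' @param samples data.frame with columns `sample_id`, `screen_id`,
#'   `population`, `replicate` and optionally `reporter_id`.
#' @return A [SampleSheet-class] object.
#' @export
SampleSheet <- function(samples) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  samples$replicate <- as.integer(samples$replicate)
  if (is.null(samples$reporter_id)) samples$reporter_id <- NA_character_
  rownames(samples) <- NULL
  new("SampleSheet", samples = samples)
}

#' ScreenCounts: guide-by-sample read counts
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' integer `counts` assay; `rowData` carries the [GuideLibrary-class]
#' columns and `colData` the [SampleSheet-class] columns. Rows follow
#' library order and columns sheet order by construction.
#'
#' @export
setClass("ScreenCounts", contains = "SummarizedExperiment")

setValidity("ScreenCounts", function(object) {
  m <- assay(object, "counts")
  if (any(m < 0)) return("negative counts")
  if (any(m != round(m))) return("non-integer counts")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    return("guide ids must be unique rownames")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    return("sample ids must be unique colnames")
  TRUE
})

#' Construct a ScreenCounts object
#'
#' @param counts integer matrix, guides in rows, samples in columns.
#' @param library a [GuideLibrary-class]; rows are reordered to its order.
#' @param sheet a [SampleSheet-class]; columns are restricted and ordered
#'   to its samples.
#' @return A [ScreenCounts-class] object.
#' @export
ScreenCounts <- function(counts, library, sheet) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("non-integer or negative counts in matrix")
  storage.mode(counts) <- "integer"
  lib <- guides(library)
  sam <- samples(sheet)
  missing_g <- setdiff(lib$guide_id, rownames(counts))
  if (length(missing_g))
    stop("guides missing from count matrix: ", paste(missing_g, collapse = ", "))
  keep <- intersect(sam$sample_id, colnames(counts))
  if (!length(keep)) stop("no sheet samples present in count matrix")
  counts <- counts[lib$guide_id, keep, drop = FALSE]
  sam <- sam[match(keep, sam$sample_id), , drop = FALSE]
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(lib[, c("target_id", "target_class")], row.names = lib$guide_id),
    colData = DataFrame(sam[, setdiff(names(sam), "sample_id")], row.names = sam$sample_id))
  new("ScreenCounts", se)
}

#' ExpressionCourse: gene expression over a differentiation time course
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass whose `colData`
#' records `timepoint_h`, `genotype` (`"XX"` or `"XO"`) and `replicate`;
#' the expression unit (`"counts"` or `"log2cpm"`) is stored in
#' `metadata(x)$unit`.
#'
#' @export
setClass("ExpressionCourse", contains = "SummarizedExperiment")

setValidity("ExpressionCourse", function(object) {
  cd <- colData(object)
  need <- c("timepoint_h", "genotype", "replicate")
  if (!all(need %in% names(cd)))
    return(paste("colData must contain", paste(need, collapse = ", ")))
  if (!all(cd$genotype %in% c("XX", "XO")))
    return("genotype must be XX or XO")
  if (any(assay(object) < 0)) return("expression values must be nonnegative")
  TRUE
})

#' Construct an ExpressionCourse
#'
#' @param values numeric matrix, genes in rows, observations in columns.
#' @param timepoint_h,genotype,replicate per-column annotations.
#' @param unit expression unit, `"counts"` (default) or `"log2cpm"`.
#' @return An [ExpressionCourse-class] object.
#' @export
ExpressionCourse <- function(values, timepoint_h, genotype, replicate,
                             unit = "counts") {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0(genotype, "_", timepoint_h, "h_r", replicate)
  se <- SummarizedExperiment(
    assays = list(values = values),
    colData = DataFrame(timepoint_h = as.numeric(timepoint_h),
                        genotype = as.character(genotype),
                        replicate = as.integer(replicate),
                        row.names = colnames(values)))
  metadata(se)$unit <- unit
  new("ExpressionCourse", se)
}

#' AllelicCellTable: allele-resolved single-cell counts
#'
#' A [SingleCellExperiment::SingleCellExperiment] subclass with two count
#' assays, `allele_a` and `allele_b`, holding allele-resolved reads per
#' (gene, cell). `colData` carries per-cell metadata (`condition`,
#' `dtag_nM`, `line`, `total_counts`) and the per-cell Xist read counts
#' (`xist_count`, `xist_allele_a`, `xist_allele_b`); `rowData` carries
#' `chromosome` and optional `position_bp`. Allelic assignment loses
#' reads, so `xist_allele_a + xist_allele_b <= xist_count` is not
#' enforced.
#'
#' @export
setClass("AllelicCellTable", contains = "SingleCellExperiment")

setValidity("AllelicCellTable", function(object) {
  if (!all(c("allele_a", "allele_b") %in% SummarizedExperiment::assayNames(object)))
    return("assays allele_a and allele_b required")
  cd <- colData(object)
  need <- c("condition", "total_counts", "xist_count", "xist_allele_a", "xist_allele_b")
  if (!all(need %in% names(cd)))
    return(paste("colData must contain", paste(need, collapse = ", ")))
  if (!"chromosome" %in% names(rowData(object)))
    return("rowData must contain chromosome")
  if (any(assay(object, "allele_a") < 0) || any(assay(object, "allele_b") < 0))
    return("allelic counts must be nonnegative")
  if (any(cd$xist_count < 0) || any(cd$xist_allele_a < 0) || any(cd$xist_allele_b < 0))
    return("Xist counts must be nonnegative")
  TRUE
})

#' Construct an AllelicCellTable
#'
#' @param allele_a,allele_b gene-by-cell count matrices (dense or sparse)
#'   for the two alleles.
#' @param cells data.frame of per-cell metadata; must contain `cell_id`,
#'   `condition`, `total_counts`, `xist_count`, `xist_allele_a`,
#'   `xist_allele_b` (optionally `dtag_nM`, `line`).
#' @param genes data.frame of per-gene metadata; must contain `gene_id`
#'   and `chromosome` (optionally `position_bp`).
#' @return An [AllelicCellTable-class] object.
#' @export
AllelicCellTable <- function(allele_a, allele_b, cells, genes) {
  if (!identical(dim(allele_a), dim(allele_b)))
    stop("allele_a and allele_b layers have mismatched dimensions: ",
         paste(dim(allele_a), collapse = "x"), " vs ",
         paste(dim(allele_b), collapse = "x"))
  if (nrow(allele_a) != nrow(genes) || ncol(allele_a) != nrow(cells))
    stop("layer dimensions do not match gene/cell annotations")
  cells <- as.data.frame(cells); genes <- as.data.frame(genes)
  if (is.null(cells$dtag_nM)) cells$dtag_nM <- NA_real_
  if (is.null(cells$line)) cells$line <- NA_character_
  if (is.null(genes$position_bp)) genes$position_bp <- NA_integer_
  sce <- SingleCellExperiment(
    assays = list(allele_a = allele_a, allele_b = allele_b),
    colData = DataFrame(cells[, setdiff(names(cells), "cell_id")],
                        row.names = cells$cell_id),
    rowData = DataFrame(genes[, setdiff(names(genes), "gene_id")],
                        row.names = genes$gene_id))
  new("AllelicCellTable", sce)
}

#' WiringMatrix: ground-truth TF-by-RE interaction effects
#'
#' Signed effects, in standard deviations of the latent reporter
#' phenotype, that knockdown of each TF exerts on each regulatory-element
#' reporter; `promoterEffect` acts on every reporter including the noRE
#' control (a minimal-promoter confounder). Zero means no interaction.
#'
#' @slot effect numeric matrix, TFs in rows, REs in columns (never
#'   `"noRE"`).
#' @slot promoter_effect named numeric vector, one value per TF.
#' @export
setClass("WiringMatrix",
         slots = c(effect = "matrix", promoter_effect = "numeric"))

setValidity("WiringMatrix", function(object) {
  if (!all(is.finite(object@effect))) return("effects must be finite")
  if (!all(is.finite(object@promoter_effect))) return("promoter effects must be finite")
  if ("noRE" %in% colnames(object@effect)) return("'noRE' cannot be a wired RE")
  if (!identical(sort(rownames(object@effect)), sort(names(object@promoter_effect))))
    return("promoter_effect names must match effect rownames")
  TRUE
})

#' Construct a WiringMatrix
#'
#' @param effect numeric TF-by-RE matrix with dimnames.
#' @param promoter_effect named numeric vector per TF; defaults to zero.
#' @return A [WiringMatrix-class] object.
#' @export
WiringMatrix <- function(effect, promoter_effect = NULL) {
  effect <- as.matrix(effect)
  if (is.null(promoter_effect))
    promoter_effect <- setNames(numeric(nrow(effect)), rownames(effect))
  new("WiringMatrix", effect = effect,
      promoter_effect = promoter_effect[rownames(effect)])
}

#' InteractionMatrix: noRE-normalized TF-RE interaction calls
#'
#' The complete grid of interaction records over retained TFs and REs,
#' plus the list of TFs excluded as noRE responders (factors that
#' significantly affect the minimal-promoter control reporter and would
#' confound every RE screen).
#'
#' @slot records data.frame with one row per (tf_id, re_id) pair:
#'   `interaction_score`, `t_stat`, `p`, `fdr`, `n_guides`, `significant`,
#'   `direction`. Scores are in knockdown space (activator < 0);
#'   serialization flips the sign once so activators print positive.
#' @slot exclusions data.frame of excluded TFs with their noRE fdr.
#' @slot alpha FDR threshold used for significance calls.
#' @export
setClass("InteractionMatrix",
         slots = c(records = "data.frame", exclusions = "data.frame",
                   alpha = "numeric"))

setValidity("InteractionMatrix", function(object) {
  r <- object@records
  if (nrow(r)) {
    if ("noRE" %in% r$re_id) return("'noRE' cannot appear as an re_id")
    if (any(r$tf_id %in% object@exclusions$tf_id))
      return("excluded TFs must not appear in the grid")
    ok <- !is.na(r$fdr)
    if (any(r$significant[ok] != (r$fdr[ok] <= object@alpha)))
      return("significant flag inconsistent with fdr threshold")
  }
  TRUE
})
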