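# Readers and writers for the pipeline's canonical on-disk dialect:
# UTF-8 TSV with a header, unquoted identifiers, and a schema-version
# comment line "#rewire-format=1" as the first line. Sparse allelic
# layers use MatrixMarket coordinate files (1-based on disk, 0-based
# never exposed) with TSV sidecars.

.FORMAT_TAG <- "#rewire-format=1"

.write_tsv <- function(df, path, extra_comments = character()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(.FORMAT_TAG, extra_comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", comment.char = "#", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
}

.require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    .stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
}

#' Read and write sgRNA library tables
#'
#' TSV with header columns `guide_id`, `target_id`, `target_class`.
#'
#' @param path file path.
#' @return `readGuideLibrary` returns a [GuideLibrary-class];
#'   `writeGuideLibrary` invisibly returns `path`.
#' @export
readGuideLibrary <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("guide_id", "target_id", "target_class"), path)
  GuideLibrary(df)
}

#' @rdname readGuideLibrary
#' @param library a [GuideLibrary-class].
#' @export
writeGuideLibrary <- function(library, path) {
  .write_tsv(guides(library), path)
}

#' Read and write sample sheets
#'
#' TSV with header columns `sample_id`, `screen_id`, `population`,
#' `replicate` and optionally `reporter_id`.
#'
#' @param path file path.
#' @return `readSampleSheet` returns a [SampleSheet-class].
#' @export
readSampleSheet <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("sample_id", "screen_id", "population", "replicate"), path)
  df$replicate <- as.integer(df$replicate)
  SampleSheet(df)
}

#' @rdname readSampleSheet
#' @param sheet a [SampleSheet-class].
#' @export
writeSampleSheet <- function(sheet, path) {
  s <- samples(sheet)
  if (all(is.na(s$reporter_id))) s$reporter_id <- NULL
  .write_tsv(s, path)
}

#' Read a guide-by-sample count table
#'
#' MAGeCK-style TSV: first column `guide_id`, remaining columns sample
#' ids. Rows are reordered to library order; columns are restricted to
#' the sheet (file columns absent from the sheet are dropped with a
#' warning); guides present in the library but absent from the file are
#' zero-filled with a warning.
#'
#' @param path file path.
#' @param library a [GuideLibrary-class] fixing guide order.
#' @param sheet a [SampleSheet-class] restricting and annotating samples.
#' @return A [ScreenCounts-class] object.
#' @export
readCounts <- function(path, library, sheet) {
  df <- .read_tsv(path)
  .require_columns(df, "guide_id", path)
  mat_cols <- setdiff(names(df), "guide_id")
  vals <- suppressWarnings(
    vapply(df[mat_cols], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1) vals <- matrix(vals, 1, dimnames = list(NULL, mat_cols))
  bad <- which(is.na(vals) | vals != round(vals), arr.ind = TRUE)
  if (nrow(bad))
    .stopf("%s: non-integer count '%s' at (%s, %s)", path,
           df[[mat_cols[bad[1, 2]]]][bad[1, 1]],
           df$guide_id[bad[1, 1]], mat_cols[bad[1, 2]])
  rownames(vals) <- df$guide_id
  extra <- setdiff(colnames(vals), samples(sheet)$sample_id)
  if (length(extra)) {
    .warnf("%s: dropping sample(s) absent from sheet: %s", path,
           paste(extra, collapse = ", "))
    vals <- vals[, setdiff(colnames(vals), extra), drop = FALSE]
  }
  missing_g <- setdiff(guideIds(library), rownames(vals))
  if (length(missing_g)) {
    .warnf("%s: %d library guide(s) absent from file, zero-filled: %s", path,
           length(missing_g), paste(missing_g, collapse = ", "))
    fill <- matrix(0L, length(missing_g), ncol(vals),
                   dimnames = list(missing_g, colnames(vals)))
    vals <- rbind(vals, fill)
  }
  ScreenCounts(vals, library, sheet)
}

#' @rdname readCounts
#' @param x a [ScreenCounts-class].
#' @export
writeCounts <- function(x, path) {
  m <- assay(x, "counts")
  df <- data.frame(guide_id = rownames(m), m, check.names = FALSE)
  .write_tsv(df, path)
}

#' Read and write expression time courses
#'
#' Long-format TSV with columns `gene`, `timepoint_h`, `genotype`,
#' `replicate`, `value`; the expression unit is recorded in a `#unit=`
#' comment. Column (observation) order is preserved through a round trip.
#'
#' @param path file path.
#' @return `readExpressionCourse` returns an [ExpressionCourse-class].
#' @export
readExpressionCourse <- function(path) {
  header <- readLines(path, n = 5)
  unit <- sub("^#unit=", "", grep("^#unit=", header, value = TRUE))
  if (!length(unit)) unit <- "counts"
  df <- .read_tsv(path)
  .require_columns(df, c("gene", "timepoint_h", "genotype", "replicate", "value"), path)
  obs <- paste(df$genotype, df$timepoint_h, df$replicate, sep = "|")
  obs_levels <- unique(obs)
  genes <- unique(df$gene)
  m <- matrix(NA_real_, length(genes), length(obs_levels),
              dimnames = list(genes, obs_levels))
  m[cbind(match(df$gene, genes), match(obs, obs_levels))] <- as.numeric(df$value)
  parts <- do.call(rbind, strsplit(obs_levels, "|", fixed = TRUE))
  colnames(m) <- paste0(parts[, 1], "_", parts[, 2], "h_r", parts[, 3])
  ExpressionCourse(m, timepoint_h = as.numeric(parts[, 2]),
                   genotype = parts[, 1], replicate = as.integer(parts[, 3]),
                   unit = unit)
}

#' @rdname readExpressionCourse
#' @param course an [ExpressionCourse-class].
#' @export
writeExpressionCourse <- function(course, path) {
  cd <- colData(course)
  m <- assay(course)
  df <- data.frame(
    gene = rep(rownames(m), times = ncol(m)),
    timepoint_h = rep(cd$timepoint_h, each = nrow(m)),
    genotype = rep(cd$genotype, each = nrow(m)),
    replicate = rep(cd$replicate, each = nrow(m)),
    value = as.vector(m))
  .write_tsv(df, path, paste0("#unit=", metadata(course)$unit))
}

#' Read and write allele-resolved single-cell bundles
#'
#' A directory holding `allele_a.mtx` and `allele_b.mtx` (MatrixMarket
#' coordinate, genes x cells, 1-based on disk), `genes.tsv`, `cells.tsv`
#' and `xist.tsv` sidecars.
#'
#' @param dir directory path.
#' @return `readAllelic` returns an [AllelicCellTable-class].
#' @export
readAllelic <- function(dir) {
  a <- as(Matrix::readMM(file.path(dir, "allele_a.mtx")), "CsparseMatrix")
  b <- as(Matrix::readMM(file.path(dir, "allele_b.mtx")), "CsparseMatrix")
  if (!identical(dim(a), dim(b)))
    .stopf("%s: allele layers have mismatched dimensions (%s vs %s)", dir,
           paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  genes <- .read_tsv(file.path(dir, "genes.tsv"))
  cells <- .read_tsv(file.path(dir, "cells.tsv"))
  xist <- .read_tsv(file.path(dir, "xist.tsv"))
  .require_columns(genes, c("gene_id", "chromosome"), "genes.tsv")
  .require_columns(cells, c("cell_id", "condition", "total_counts"), "cells.tsv")
  .require_columns(xist, c("cell_id", "xist_count", "xist_allele_a", "xist_allele_b"),
                   "xist.tsv")
  if (nrow(genes) != nrow(a) || nrow(cells) != ncol(a))
    .stopf("%s: sidecar row counts do not match layer dimensions", dir)
  cells <- merge(cells, xist, by = "cell_id", sort = FALSE)
  for (col in c("total_counts", "xist_count", "xist_allele_a", "xist_allele_b"))
    cells[[col]] <- as.integer(cells[[col]])
  if (!is.null(cells$dtag_nM)) cells$dtag_nM <- as.numeric(cells$dtag_nM)
  if (!is.null(genes$position_bp)) genes$position_bp <- as.integer(genes$position_bp)
  dimnames(a) <- dimnames(b) <- list(genes$gene_id, cells$cell_id)
  AllelicCellTable(a, b, cells, genes)
}

#' @rdname readAllelic
#' @param x an [AllelicCellTable-class].
#' @export
writeAllelic <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(as(as(assay(x, "allele_a"), "dMatrix"), "CsparseMatrix"),
                  file.path(dir, "allele_a.mtx"))
  Matrix::writeMM(as(as(assay(x, "allele_b"), "dMatrix"), "CsparseMatrix"),
                  file.path(dir, "allele_b.mtx"))
  rd <- as.data.frame(rowData(x))
  .write_tsv(cbind(gene_id = rownames(x), rd), file.path(dir, "genes.tsv"))
  cd <- as.data.frame(colData(x))
  xist_cols <- c("xist_count", "xist_allele_a", "xist_allele_b")
  .write_tsv(cbind(cell_id = colnames(x), cd[, setdiff(names(cd), xist_cols)]),
             file.path(dir, "cells.tsv"))
  .write_tsv(cbind(cell_id = colnames(x), cd[, xist_cols]),
             file.path(dir, "xist.tsv"))
  invisible(dir)
}

#' Write target-level screen scores
#'
#' Serializes a [surrogateTargetScore()] table with a header comment
#' recording the sign convention (negative score in `high_vs_neg` means
#' the target is an activator: its knockdown depletes guides from the
#' High bin).
#'
#' @param scores data.frame from [surrogateTargetScore()].
#' @param path file path.
#' @export
writeTargetScores <- function(scores, path) {
  .write_tsv(scores, path,
             "#sign-convention: knockdown space; negative score in high_vs_neg => activator")
}

#' Write an interaction matrix
#'
#' Emits the TF-by-RE grid with the single, final sign flip into the
#' heat-map orientation (activators positive); in-memory scores stay in
#' knockdown space. Also writes the exclusion list.
#'
#' @param x an [InteractionMatrix-class].
#' @param path path for the grid TSV.
#' @param exclusions_path optional path for the exclusion-list TSV.
#' @export
writeInteractions <- function(x, path, exclusions_path = NULL) {
  rec <- interactions(x)
  rec$interaction_score <- -rec$interaction_score
  rec$t_stat <- -rec$t_stat
  .write_tsv(rec, path,
             "#sign-convention: activator-positive orientation (single flip applied at serialization)")
  if (!is.null(exclusions_path)) .write_tsv(exclusions(x), exclusions_path)
  invisible(path)
}
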