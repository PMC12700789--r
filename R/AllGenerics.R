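#' @rdname GuideLibrary-class
#' @param x a GuideLibrary (or, for `samples`, a SampleSheet).
#' @export
setGeneric("guides", function(x) standardGeneric("guides"))

#' @rdname GuideLibrary-class
#' @export
setGeneric("guideIds", function(x) standardGeneric("guideIds"))

#' @rdname GuideLibrary-class
#' @export
setGeneric("targetIds", function(x) standardGeneric("targetIds"))

#' @rdname SampleSheet-class
#' @param x a SampleSheet.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname WiringMatrix-class
#' @param x a WiringMatrix.
#' @export
setGeneric("wiringEffect", function(x) standardGeneric("wiringEffect"))

#' @rdname WiringMatrix-class
#' @export
setGeneric("promoterEffect", function(x) standardGeneric("promoterEffect"))

#' @rdname InteractionMatrix-class
#' @param x an InteractionMatrix.
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))

#' @rdname InteractionMatrix-class
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))

setMethod("guides", "GuideLibrary", function(x) x@guides)
setMethod("guideIds", "GuideLibrary", function(x) x@guides$guide_id)
setMethod("targetIds", "GuideLibrary", function(x) unique(x@guides$target_id))
setMethod("samples", "SampleSheet", function(x) x@samples)
setMethod("wiringEffect", "WiringMatrix", function(x) x@effect)
setMethod("promoterEffect", "WiringMatrix", function(x) x@promoter_effect)
setMethod("interactions", "InteractionMatrix", function(x) x@records)
setMethod("exclusions", "InteractionMatrix", function(x) x@exclusions)

#' Reconstruct the GuideLibrary of a ScreenCounts object
#'
#' @param x a [ScreenCounts-class].
#' @return The [GuideLibrary-class] stored in `rowData`.
#' @export
screenLibrary <- function(x) {
  rd <- rowData(x)
  GuideLibrary(data.frame(guide_id = rownames(x),
                          target_id = rd$target_id,
                          target_class = rd$target_class))
}

#' Reconstruct the SampleSheet of a ScreenCounts object
#'
#' @param x a [ScreenCounts-class].
#' @return The [SampleSheet-class] stored in `colData`.
#' @export
screenSheet <- function(x) {
  cd <- as.data.frame(colData(x))
  SampleSheet(cbind(sample_id = colnames(x), cd))
}

setMethod("show", "GuideLibrary", function(object) {
  g <- object@guides
  cat("GuideLibrary:", nrow(g), "guides,", length(unique(g$target_id)),
      "targets (", sum(g$target_class == "nontargeting"), "nontargeting )\n")
})

setMethod("show", "SampleSheet", function(object) {
  s <- object@samples
  cat("SampleSheet:", nrow(s), "samples,", length(unique(s$screen_id)),
      "screen(s); populations:", paste(unique(s$population), collapse = ", "), "\n")
})

setMethod("show", "WiringMatrix", function(object) {
  cat("WiringMatrix:", nrow(object@effect), "TFs x", ncol(object@effect),
      "REs;", sum(object@effect != 0), "nonzero interactions,",
      sum(object@promoter_effect != 0), "promoter effect(s)\n")
})

setMethod("show", "InteractionMatrix", function(object) {
  r <- object@records
  cat("InteractionMatrix:", length(unique(r$tf_id)), "TFs x",
      length(unique(r$re_id)), "REs; ",
      sum(r$significant, na.rm = TRUE), "significant at FDR <=", object@alpha,
      "\n  excluded noRE responders:",
      if (nrow(object@exclusions)) paste(object@exclusions$tf_id, collapse = ", ")
      else "none", "\n  sign convention: knockdown space (activator < 0);",
      "writers flip once so activators print positive\n")
})
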