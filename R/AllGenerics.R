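#' Accessors for CorrespondenceMap
#'
#' `correspondencePairs()` returns the per-subgroup best-match table,
#' `scoreMatrix()` the full pairwise match-score matrix and
#' `overlapCounts()` the shared-marker count matrix.
#'
#' @param x A [CorrespondenceMap].
#' @return A DataFrame (`correspondencePairs`) or matrix.
#' @name CorrespondenceMap-accessors
NULL

#' @rdname CorrespondenceMap-accessors
#' @export
setGeneric("correspondencePairs", function(x) standardGeneric("correspondencePairs"))

#' @rdname CorrespondenceMap-accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname CorrespondenceMap-accessors
#' @export
setGeneric("overlapCounts", function(x) standardGeneric("overlapCounts"))

#' @rdname CorrespondenceMap-accessors
#' @export
setMethod("correspondencePairs", "CorrespondenceMap", function(x) x@pairs)

#' @rdname CorrespondenceMap-accessors
#' @export
setMethod("scoreMatrix", "CorrespondenceMap", function(x) x@scores)

#' @rdname CorrespondenceMap-accessors
#' @export
setMethod("overlapCounts", "CorrespondenceMap", function(x) x@overlap)

#' @describeIn CorrespondenceMap-accessors compact display
#' @param object A [CorrespondenceMap].
#' @export
setMethod("show", "CorrespondenceMap", function(object) {
  cat("CorrespondenceMap:", nrow(object@scores), "x", ncol(object@scores),
      "subgroups,", sum(object@pairs$reciprocal_best),
      "reciprocal best hits\n")
  print(as.data.frame(object@pairs))
  invisible(NULL)
})

#' @describeIn MarkerTable compact display
#' @param object A [MarkerTable].
#' @export
setMethod("show", "MarkerTable", function(object) {
  cat("MarkerTable:", nrow(object), "markers across",
      length(unique(object$subgroup)), "of",
      length(metadata(object)$subgroups), "subgroups\n")
  callNextMethod()
})
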