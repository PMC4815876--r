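#' @name accessors
#' @title Accessors for mgindex objects
#'
#' @description Small accessor generics: `gVectors()` returns the g-vector
#' matrix of a pool (optionally only the active rows), `activeMask()` the
#' active-reflection mask, `truthLabels()` the ground-truth label table,
#' `nActive()` the number of active reflections, `basisMatrix()` the 3 x 3
#' direct basis of a hypothesis or indexed grain, `assignments()` its
#' hkl-to-reflection table, `matchedCount()` its assignment count,
#' `members()` the reflection indices of a candidate, and `grains()` the
#' grain list of an indexing result.
#'
#' @param x An mgindex object.
#' @param activeOnly Logical; return only active rows.
#' @return The accessed component.
NULL

#' @rdname accessors
#' @export
setGeneric("gVectors", function(x, activeOnly = FALSE) standardGeneric("gVectors"))
#' @rdname accessors
#' @export
setGeneric("activeMask", function(x) standardGeneric("activeMask"))
#' @rdname accessors
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))
#' @rdname accessors
#' @export
setGeneric("nActive", function(x) standardGeneric("nActive"))
#' @rdname accessors
#' @export
setGeneric("basisMatrix", function(x) standardGeneric("basisMatrix"))
#' @rdname accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))
#' @rdname accessors
#' @export
setGeneric("matchedCount", function(x) standardGeneric("matchedCount"))
#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname accessors
#' @export
setGeneric("grains", function(x) standardGeneric("grains"))

#' @rdname accessors
setMethod("gVectors", "GVectorPool", function(x, activeOnly = FALSE) {
  if (activeOnly) x@gvec[x@active, , drop = FALSE] else x@gvec
})
#' @rdname accessors
setMethod("activeMask", "GVectorPool", function(x) x@active)
#' @rdname accessors
setMethod("truthLabels", "GVectorPool", function(x) x@labels)
#' @rdname accessors
setMethod("nActive", "GVectorPool", function(x) sum(x@active))
#' @rdname accessors
setMethod("basisMatrix", "GrainHypothesis", function(x) x@basis)
#' @rdname accessors
setMethod("basisMatrix", "IndexedGrain", function(x) x@basis)
#' @rdname accessors
setMethod("assignments", "GrainHypothesis", function(x) x@assignments)
#' @rdname accessors
setMethod("assignments", "IndexedGrain", function(x) x@assignments)
#' @rdname accessors
setMethod("matchedCount", "GrainHypothesis", function(x) x@matchedCount)
#' @rdname accessors
setMethod("matchedCount", "IndexedGrain", function(x) x@matchedCount)
#' @rdname accessors
setMethod("members", "LatticeCandidate", function(x) x@members)
#' @rdname accessors
setMethod("members", "CandidateGrain", function(x) x@members)
#' @rdname accessors
setMethod("grains", "IndexingResult", function(x) x@grains)

setMethod("show", "UnitCell", function(object) {
  cat(sprintf(
    "UnitCell: a=%.4f b=%.4f c=%.4f  alpha=%.3f beta=%.3f gamma=%.3f  V=%.2f A^3\n",
    object@a, object@b, object@c, object@alpha, object@beta, object@gamma,
    cellVolume(object)))
})

setMethod("show", "PhaseSpec", function(object) {
  cat(sprintf("PhaseSpec '%s'%s\n", object@name,
              if (is.null(object@condition)) "" else " (reflection condition set)"))
  methods::show(object@cell)
})

setMethod("show", "GVectorPool", function(object) {
  cat(sprintf("GVectorPool: %d g-vectors (%d active)%s\n",
              nrow(object@gvec), sum(object@active),
              if (is.null(object@labels)) "" else ", ground-truth labels"))
  if (nrow(object@gvec)) {
    q <- sqrt(rowSums(object@gvec^2))
    cat(sprintf("  |g| range: %.4f - %.4f 1/A\n", min(q), max(q)))
  }
})

setMethod("show", "LatticeCandidate", function(object) {
  cat(sprintf("LatticeCandidate: d*=%.6f  count=%d  score=%.2f  members=%d\n",
              object@dstar, as.integer(object@rawCount), object@score,
              length(object@members)))
})

setMethod("show", "CandidateGrain", function(object) {
  cat(sprintf("CandidateGrain: %d member reflections\n", length(object@members)))
})

setMethod("show", "GrainHypothesis", function(object) {
  cat(sprintf("GrainHypothesis: %d matched reflections\n", object@matchedCount))
  methods::show(cellFromBasis(object@basis))
})

setMethod("show", "IndexedGrain", function(object) {
  cat(sprintf("IndexedGrain #%d: %d reflections\n", object@serial,
              object@matchedCount))
  methods::show(object@cell)
})

setMethod("show", "IndexingResult", function(object) {
  cat(sprintf("IndexingResult: %d grains, %d reflections unclaimed (%s)\n",
              length(object@grains), sum(object@pool@active),
              object@stopReason))
})

setMethod("show", "MeritReport", function(object) {
  cat("MeritReport\n")
  cat(sprintf("  fraction of grains identified : %.4f\n",
              object@fractionIdentified))
  cat(sprintf("  mean |dV|/V over successes    : %.3g\n",
              object@meanRelVolumeDeviation))
  cat(sprintf("  mean correct fraction         : %.4f\n",
              object@meanCorrectFraction))
  cat(sprintf("  mean false fraction           : %.3g\n",
              object@meanFalseFraction))
})
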