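#' Accessors
#'
#' Small accessor generics for the package's S4 classes.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("doseMatrix", function(x) standardGeneric("doseMatrix"))

#' @rdname accessors
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname accessors
#' @export
setGeneric("alleleFreq", function(x) standardGeneric("alleleFreq"))

#' @rdname accessors
#' @export
setGeneric("relMatrix", function(x) standardGeneric("relMatrix"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("chainSamples", function(x) standardGeneric("chainSamples"))

#' @rdname accessors
#' @export
setMethod("sampleIds", "GenotypeData", function(x) x@ids)

#' @rdname accessors
#' @export
setMethod("sampleIds", "TraitData", function(x) x@sowId)

#' @rdname accessors
#' @export
setMethod("sampleIds", "RelationshipMatrix", function(x) x@ids)

#' @rdname accessors
#' @export
setMethod("doseMatrix", "GenotypeData", function(x) {
  d <- x@dose
  dimnames(d) <- list(x@ids, x@map$marker)
  d
})

#' @rdname accessors
#' @export
setMethod("markerMap", "GenotypeData", function(x) x@map)

#' @rdname accessors
#' @export
setMethod("alleleFreq", "GenotypeData", function(x) {
  setNames(colMeans(x@dose, na.rm = TRUE) / 2, x@map$marker)
})

#' @rdname accessors
#' @export
setMethod("relMatrix", "RelationshipMatrix", function(x) {
  m <- x@mat
  dimnames(m) <- list(x@ids, x@ids)
  m
})

#' @rdname accessors
#' @export
setMethod("nSamples", "PosteriorChain", function(x) {
  cfg <- x@config
  as.integer(floor((cfg@nIter - cfg@burnIn) / cfg@thin))
})

#' @rdname accessors
#' @export
setMethod("chainSamples", "PosteriorChain", function(x) x@samples)
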