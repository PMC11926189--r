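#' Accessors for PolysomeTracer classes
#'
#' @param object,x a \linkS4class{ParticleSet}, \linkS4class{LinkGraph}
#'   or \linkS4class{PolysomeChainSet}.
#' @name accessors
NULL

#' @describeIn accessors particle table (data.frame) of a ParticleSet.
#' @export
setGeneric("particles", function(object) standardGeneric("particles"))

#' @describeIn accessors number of particles.
#' @export
setGeneric("nParticles", function(object) standardGeneric("nParticles"))

#' @describeIn accessors pixel size (A/px) recorded at load.
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @describeIn accessors label column names.
#' @export
setGeneric("labelColumns", function(object) standardGeneric("labelColumns"))

#' @describeIn accessors link table (data.frame) of a LinkGraph.
#' @export
setGeneric("links", function(object) standardGeneric("links"))

#' @describeIn accessors list of ordered member-ID vectors of the chains.
#' @export
setGeneric("chainMembers", function(object) standardGeneric("chainMembers"))

#' @describeIn accessors per-chain step distances (list of numerics, A).
#' @export
setGeneric("stepDistances", function(object) standardGeneric("stepDistances"))

#' @export
setMethod("particles", "ParticleSet", function(object) object@particles)

#' @export
setMethod("nParticles", "ParticleSet",
          function(object) nrow(object@particles))

#' @export
setMethod("pixelSize", "ParticleSet", function(object) object@pixelSize)

#' @export
setMethod("labelColumns", "ParticleSet",
          function(object) object@labelColumns)

#' @export
setMethod("links", "LinkGraph", function(object) object@links)

#' @export
setMethod("chainMembers", "PolysomeChainSet", function(object) object@chains)

#' @export
setMethod("stepDistances", "PolysomeChainSet",
          function(object) object@stepDistances)

#' @describeIn accessors chain lengths (number of ribosomes per polysome).
#' @export
chainLengths <- function(object) lengths(chainMembers(object))

#' @describeIn accessors tomogram ID of each chain.
#' @export
chainTomoIDs <- function(object) object@tomoIDs
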