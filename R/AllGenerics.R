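#' @import methods
NULL

#' @export
setGeneric("lipidClass", function(x) standardGeneric("lipidClass"))

#' @export
setGeneric("speciesName", function(x) standardGeneric("speciesName"))

#' @export
setGeneric("speciesLevel", function(x) standardGeneric("speciesLevel"))

#' @export
setGeneric("acylChains", function(x) standardGeneric("acylChains"))

#' @export
setGeneric("sumComposition", function(x) standardGeneric("sumComposition"))

#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @export
setGeneric("speciesReactions", function(x) standardGeneric("speciesReactions"))

#' @export
setGeneric("reactionId", function(x) standardGeneric("reactionId"))

#' @export
setGeneric("substrates", function(x) standardGeneric("substrates"))

#' @export
setGeneric("products", function(x) standardGeneric("products"))

#' @export
setGeneric("transferredAcyls", function(x) standardGeneric("transferredAcyls"))

#' @export
setGeneric("isHeuristic", function(x) standardGeneric("isHeuristic"))

#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @export
setGeneric("caseSamples", function(x) standardGeneric("caseSamples"))

#' @export
setGeneric("controlSamples", function(x) standardGeneric("controlSamples"))

#' @export
setGeneric("subnetworks", function(x) standardGeneric("subnetworks"))

#' @export
setGeneric("objectives", function(x) standardGeneric("objectives"))

#' @export
setGeneric("pvalues", function(x) standardGeneric("pvalues"))

#' @export
setGeneric("bestSubnetwork", function(x) standardGeneric("bestSubnetwork"))

#' @export
setGeneric("nodeScores", function(x) standardGeneric("nodeScores"))

#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @export
setGeneric("featureInfo", function(x) standardGeneric("featureInfo"))

#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @export
setGeneric("writeGraphML", function(x, path, ...) standardGeneric("writeGraphML"))
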