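#' Class posterior probabilities
#'
#' Predict three-class posterior probabilities for new samples. Rows of the
#' returned matrix are samples, columns are the classes in the fixed order
#' healthy, localized, metastatic; every row is a probability simplex.
#'
#' @param model a fitted [HierarchicalKnnModel-class] or
#'   [TwoLayerNetModel-class].
#' @param x a numeric matrix (samples x panel features), a single activity
#'   vector, or an [ActivitySet-class].
#' @return numeric matrix of posteriors with one row per sample.
#' @export
setGeneric("predictPosterior", function(model, x) standardGeneric("predictPosterior"))

#' @rdname activityAccessors
#' @export
setGeneric("activityMatrix", function(x) standardGeneric("activityMatrix"))

#' @rdname activityAccessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname panelAccessors
#' @export
setGeneric("panelProteases", function(x) standardGeneric("panelProteases"))

#' @rdname panelAccessors
#' @export
setGeneric("consensusSequences", function(x) standardGeneric("consensusSequences"))

#' @rdname panelAccessors
#' @export
setGeneric("groupMeans", function(x) standardGeneric("groupMeans"))

#' @rdname panelAccessors
#' @export
setGeneric("groupSds", function(x) standardGeneric("groupSds"))

#' @rdname ALState-accessors
#' @export
setGeneric("labeledIds", function(x) standardGeneric("labeledIds"))

#' @rdname ALState-accessors
#' @export
setGeneric("poolIds", function(x) standardGeneric("poolIds"))

#' @rdname ALState-accessors
#' @export
setGeneric("testIds", function(x) standardGeneric("testIds"))

#' @rdname ALState-accessors
#' @export
setGeneric("queryHistory", function(x) standardGeneric("queryHistory"))

#' @rdname ShapExplanation-accessors
#' @export
setGeneric("shapValues", function(x) standardGeneric("shapValues"))

#' @rdname ShapExplanation-accessors
#' @export
setGeneric("baseValue", function(x) standardGeneric("baseValue"))
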