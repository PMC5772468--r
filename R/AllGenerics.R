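#' @rdname accessors
#' @export
setGeneric("condition", function(object) standardGeneric("condition"))

#' @rdname accessors
#' @export
setGeneric("sessionTimes", function(object) standardGeneric("sessionTimes"))

#' @rdname accessors
#' @export
setGeneric("napWindows", function(object) standardGeneric("napWindows"))

#' @rdname accessors
#' @export
setGeneric("subjects", function(object) standardGeneric("subjects"))

#' @rdname accessors
#' @export
setGeneric("nSubjects", function(object) standardGeneric("nSubjects"))

#' @rdname accessors
#' @export
setGeneric("schedule", function(object, condition) standardGeneric("schedule"))

#' @rdname accessors
#' @export
setGeneric("kssRatings", function(object) standardGeneric("kssRatings"))

#' @rdname accessors
#' @export
setGeneric("pvtTrials", function(object) standardGeneric("pvtTrials"))

#' @rdname accessors
#' @export
setGeneric("napRatings", function(object) standardGeneric("napRatings"))

#' @rdname accessors
#' @export
setGeneric("hypnograms", function(object) standardGeneric("hypnograms"))

#' @rdname accessors
#' @export
setGeneric("meanKss", function(object) standardGeneric("meanKss"))

#' @rdname accessors
#' @export
setGeneric("zWeights", function(object) standardGeneric("zWeights"))

#' @rdname accessors
#' @export
setGeneric("contrastWeights", function(object) standardGeneric("contrastWeights"))

#' @rdname accessors
#' @export
setGeneric("atlas", function(object) standardGeneric("atlas"))

#' @rdname accessors
#' @export
setGeneric("atlasLabels", function(object) standardGeneric("atlasLabels"))

#' @rdname accessors
#' @export
setGeneric("affine", function(object) standardGeneric("affine"))

#' @rdname accessors
#' @export
setGeneric("betaVolume", function(object, regressor) standardGeneric("betaVolume"))

#' @rdname accessors
#' @export
setGeneric("tVolume", function(object) standardGeneric("tVolume"))

#' @rdname accessors
#' @export
setGeneric("fweVolume", function(object) standardGeneric("fweVolume"))
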