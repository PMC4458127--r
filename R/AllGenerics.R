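#' Accessors for model, index and track objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x An [InsertSizeModel-class], [MatePairIndex-class] or
#'   [ScoreTrack-class] object.
#' @return The corresponding slot value.
#' @examples
#' m <- estimateInsertModel(c(2800, 3000, 3200))
#' muHat(m)
#' sigmaHat(m)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("muHat", function(x) standardGeneric("muHat"))
#' @rdname accessors
#' @export
setGeneric("madValue", function(x) standardGeneric("madValue"))
#' @rdname accessors
#' @export
setGeneric("sigmaHat", function(x) standardGeneric("sigmaHat"))
#' @rdname accessors
#' @export
setGeneric("nPairsUsed", function(x) standardGeneric("nPairsUsed"))
#' @rdname accessors
#' @export
setGeneric("contigName", function(x) standardGeneric("contigName"))
#' @rdname accessors
#' @export
setGeneric("contigLength", function(x) standardGeneric("contigLength"))
#' @rdname accessors
#' @export
setGeneric("pairRecords", function(x) standardGeneric("pairRecords"))
#' @rdname accessors
#' @export
setGeneric("scanPositions", function(x) standardGeneric("scanPositions"))
#' @rdname accessors
#' @export
setGeneric("supportValues", function(x) standardGeneric("supportValues"))
#' @rdname accessors
#' @export
setGeneric("zScores", function(x) standardGeneric("zScores"))
#' @rdname accessors
#' @export
setGeneric("muD", function(x) standardGeneric("muD"))
#' @rdname accessors
#' @export
setGeneric("sD", function(x) standardGeneric("sD"))

#' @rdname accessors
#' @export
setMethod("muHat", "InsertSizeModel", function(x) x@muHat)
#' @rdname accessors
#' @export
setMethod("madValue", "InsertSizeModel", function(x) x@mad)
#' @rdname accessors
#' @export
setMethod("sigmaHat", "InsertSizeModel", function(x) x@sigmaHat)
#' @rdname accessors
#' @export
setMethod("nPairsUsed", "InsertSizeModel", function(x) x@nPairsUsed)

#' @rdname accessors
#' @export
setMethod("contigName", "MatePairIndex", function(x) x@contigName)
#' @rdname accessors
#' @export
setMethod("contigLength", "MatePairIndex", function(x) x@contigLength)
#' @rdname accessors
#' @export
setMethod("pairRecords", "MatePairIndex", function(x) x@pairs)

#' @rdname accessors
#' @export
setMethod("contigName", "ScoreTrack", function(x) x@contigName)
#' @rdname accessors
#' @export
setMethod("contigLength", "ScoreTrack", function(x) x@contigLength)
#' @rdname accessors
#' @export
setMethod("scanPositions", "ScoreTrack", function(x) x@positions)
#' @rdname accessors
#' @export
setMethod("supportValues", "ScoreTrack", function(x) x@support)
#' @rdname accessors
#' @export
setMethod("zScores", "ScoreTrack", function(x) x@zscores)
#' @rdname accessors
#' @export
setMethod("muD", "ScoreTrack", function(x) x@muD)
#' @rdname accessors
#' @export
setMethod("sD", "ScoreTrack", function(x) x@sD)
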