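# Accessor generics. Slot access from user code is discouraged; these are
# the supported surface.

#' @rdname WindowGrid
#' @export
setGeneric("binWindows", function(x) standardGeneric("binWindows"))

#' @rdname WindowGrid
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname WindowGrid
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("windowLabels", function(x) standardGeneric("windowLabels"))

#' @rdname accessors
#' @export
setGeneric("tissueName", function(x) standardGeneric("tissueName"))

#' @rdname accessors
#' @export
setGeneric("markNames", function(x) standardGeneric("markNames"))

#' @rdname accessors
#' @export
setGeneric("heldoutFscore", function(x) standardGeneric("heldoutFscore"))

#' @rdname accessors
#' @export
setGeneric("heldoutReport", function(x) standardGeneric("heldoutReport"))

#' @rdname accessors
#' @export
setGeneric("baseModels", function(x) standardGeneric("baseModels"))

#' @rdname accessors
#' @export
setGeneric("metaModel", function(x) standardGeneric("metaModel"))

#' @rdname accessors
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))

#' @rdname WindowGrid
#' @export
setMethod("binWindows", "WindowGrid", function(x) x@windows)

#' @rdname WindowGrid
#' @export
setMethod("binWidth", "WindowGrid", function(x) x@binWidth)

#' @rdname WindowGrid
#' @export
setMethod("chromSizes", "WindowGrid", function(x) x@chromSizes)

#' Accessors for enhancerStack objects
#'
#' Small accessor methods: `featureMatrix()` and `windowLabels()` return a
#' dataset's raw feature matrix and 0/1 label vector; `tissueName()` and
#' `markNames()` name the source tissue and feature columns;
#' `heldoutFscore()`/`heldoutReport()` expose a base classifier's held-out
#' performance; `baseModels()`/`metaModel()` unpack an [EnhancerStack];
#' `aucValue()` extracts the area under a [RocCurve].
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("featureMatrix", "EnhancerDataset",
          function(x) assay(x, "signal"))

#' @rdname accessors
#' @export
setMethod("windowLabels", "EnhancerDataset",
          function(x) as.integer(rowData(x)$label))

#' @rdname accessors
#' @export
setMethod("tissueName", "EnhancerDataset",
          function(x) S4Vectors::metadata(x)$tissue)

#' @rdname accessors
#' @export
setMethod("markNames", "EnhancerDataset", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("markNames", "BaseForest", function(x) x@markNames)

#' @rdname accessors
#' @export
setMethod("tissueName", "BaseForest", function(x) x@tissue)

#' @rdname accessors
#' @export
setMethod("heldoutFscore", "BaseForest", function(x) x@heldoutFscore)

#' @rdname accessors
#' @export
setMethod("heldoutReport", "BaseForest", function(x) x@heldoutReport)

#' @rdname accessors
#' @export
setMethod("markNames", "EnhancerStack", function(x) x@markNames)

#' @rdname accessors
#' @export
setMethod("baseModels", "EnhancerStack", function(x) x@baseModels)

#' @rdname accessors
#' @export
setMethod("metaModel", "EnhancerStack", function(x) x@metaModel)

#' @rdname accessors
#' @export
setMethod("aucValue", "RocCurve", function(x) x@auc)

#' Convert a MetricsReport to a one-row data.frame
#'
#' @param x a [MetricsReport].
#' @param ... ignored.
#' @return A one-row data.frame with the six metrics (NA = undefined).
#' @export
setMethod("as.data.frame", "MetricsReport", function(x, ...) {
  data.frame(precision = x@precision, recall = x@recall,
             specificity = x@specificity, sensitivity = x@sensitivity,
             f_score = x@fScore, accuracy = x@accuracy)
})
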