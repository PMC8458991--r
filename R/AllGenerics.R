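#' Model contract generics
#'
#' Any classifier usable with [trainCurriculum()], [evaluateAcrossLevels()]
#' and [extractActivations()] implements these three generics.
#' \code{modelPredict} returns an items-by-classes score matrix;
#' \code{modelUpdate} performs one mini-batch gradient step and returns the
#' updated model together with the batch loss and accuracy;
#' \code{modelActivations} returns an items-by-units matrix for a named
#' layer.
#'
#' @param model the classifier object.
#' @param x numeric array of images, \code{H x W x n}.
#' @param y integer vector of class labels in \code{1..n_classes}
#'   (for \code{modelUpdate}).
#' @param lr learning rate for the step.
#' @param momentum Nesterov momentum coefficient.
#' @param layer character(1), layer tag; see [availableLayers()].
#' @param ... further arguments for methods.
#'
#' @return \code{modelPredict}: numeric matrix \code{n x n_classes} of class
#'   probabilities. \code{modelUpdate}: list with elements \code{model},
#'   \code{loss}, \code{accuracy}. \code{modelActivations}: numeric matrix
#'   \code{n x units}.
#' @name model-contract
NULL

#' @rdname model-contract
#' @export
setGeneric("modelPredict", function(model, x, ...)
  standardGeneric("modelPredict"))

#' @rdname model-contract
#' @export
setGeneric("modelUpdate", function(model, x, y, lr, momentum = 0.9, ...)
  standardGeneric("modelUpdate"))

#' @rdname model-contract
#' @export
setGeneric("modelActivations", function(model, x, layer, ...)
  standardGeneric("modelActivations"))

#' @rdname model-contract
#' @export
setGeneric("availableLayers", function(model)
  standardGeneric("availableLayers"))

#' Accessors for package classes
#'
#' \code{maskValues} returns the gain grid of a [FrequencyMask-class];
#' \code{rdmValues} the dissimilarity matrix of an [RDM-class]; \code{rdmIds}
#' its stimulus identifiers; \code{layoutManifest} the position manifest of a
#' [HybridSetLayout-class].
#'
#' @param object the object to access.
#' @return The slot content as a base R object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("maskValues", function(object) standardGeneric("maskValues"))

#' @rdname accessors
#' @export
setGeneric("rdmValues", function(object) standardGeneric("rdmValues"))

#' @rdname accessors
#' @export
setGeneric("rdmIds", function(object) standardGeneric("rdmIds"))

#' @rdname accessors
#' @export
setGeneric("layoutManifest", function(object)
  standardGeneric("layoutManifest"))

#' @rdname accessors
setMethod("maskValues", "FrequencyMask", function(object) object@values)

#' @rdname accessors
setMethod("rdmValues", "RDM", function(object) {
  v <- object@values
  dimnames(v) <- list(object@ids, object@ids)
  v
})

#' @rdname accessors
setMethod("rdmIds", "RDM", function(object) object@ids)

#' @rdname accessors
setMethod("layoutManifest", "HybridSetLayout", function(object)
  object@manifest)

setMethod("show", "FilterSpec", function(object) {
  cat(sprintf(
    "FilterSpec: %.3g c/deg, order %d, %d px, %.3g deg (r = %.4g cycles/image)\n",
    object@cutoff_cpd, object@order_n, object@image_size_px,
    object@visual_angle_deg, cutoffRadius(object)))
})

setMethod("show", "FrequencyMask", function(object) {
  n <- object@spec@image_size_px
  cat(sprintf("FrequencyMask: %d x %d Butterworth gains, ", n, n))
  show(object@spec)
})

setMethod("show", "RDM", function(object) {
  cat(sprintf("RDM: %d x %d, range [%.3g, %.3g]\n",
              nrow(object@values), ncol(object@values),
              min(object@values), max(object@values)))
})

setMethod("show", "ConceptualRDM", function(object) {
  cat(sprintf("ConceptualRDM (%s model): %d x %d binary dissimilarities\n",
              object@model, nrow(object@values), ncol(object@values)))
})

setMethod("show", "HybridSetLayout", function(object) {
  cat(sprintf(
    "HybridSetLayout: 18 hybrids (9 LSF-delta + 9 HSF-delta), boundary %.3g c/deg\n",
    object@boundary_cpd))
})

setMethod("show", "RegimeSchedule", function(object) {
  cat(sprintf("RegimeSchedule '%s': 5 stages x %d epochs (total %d)\n",
              object@name, object@stage_length, object@total_epochs))
  for (i in seq_along(object@stages)) {
    s <- object@stages[[i]]
    on <- s[s > 0]
    cat(sprintf("  stage %d: %s\n", i,
                paste(sprintf("%s=%.4g", names(on), on), collapse = ", ")))
  }
})

setMethod("show", "SynthDataset", function(object) {
  d <- dim(object@images)
  cat(sprintf("SynthDataset: %d images (%d x %d), %d classes\n",
              d[3], d[1], d[2], nlevels(object@labels)))
})

setMethod("show", "SmallCNN", function(object) {
  a <- object@arch
  cat(sprintf(
    "SmallCNN: %dx%d input, conv widths %s, hidden %d, %d classes (%d parameters)\n",
    a$input_size, a$input_size, paste(a$conv_widths, collapse = "/"),
    a$hidden, a$n_classes,
    sum(vapply(object@weights, length, integer(1)))))
})
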