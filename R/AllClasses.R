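#' @import methods
NULL

#' Calibrated low-pass filter specification
#'
#' A \code{FilterSpec} ties a spatial-frequency cutoff expressed in cycles per
#' degree of visual angle (c/deg) to a concrete square image: the image side
#' length in pixels and the visual angle the image is assumed to subtend.
#' Together these calibrate the cutoff radius of the Butterworth mask in
#' cycles per image, \eqn{r = \mathrm{cutoff} \times \theta}, which is
#' independent of the pixel size.
#'
#' @slot cutoff_cpd numeric(1), cutoff spatial frequency in cycles/degree
#'   (> 0).
#' @slot order_n integer(1), Butterworth order (>= 1); default 4 throughout
#'   the package.
#' @slot image_size_px integer(1), side length of the square image (>= 2).
#' @slot visual_angle_deg numeric(1), assumed angular size of the image in
#'   degrees (> 0); default 60.
#'
#' @seealso [filterSpec()], [cutoffRadius()], [buildMask()]
#' @exportClass FilterSpec
setClass("FilterSpec",
  representation(
    cutoff_cpd = "numeric",
    order_n = "integer",
    image_size_px = "integer",
    visual_angle_deg = "numeric"
  )
)

setValidity("FilterSpec", function(object) {
  msg <- character()
  if (length(object@cutoff_cpd) != 1L || !is.finite(object@cutoff_cpd) ||
      object@cutoff_cpd <= 0)
    msg <- c(msg, "cutoff_cpd must be a single positive finite number")
  if (length(object@order_n) != 1L || is.na(object@order_n) ||
      object@order_n < 1L)
    msg <- c(msg, "order_n must be a single integer >= 1")
  if (length(object@image_size_px) != 1L || is.na(object@image_size_px) ||
      object@image_size_px < 2L)
    msg <- c(msg, "image_size_px must be a single integer >= 2")
  if (length(object@visual_angle_deg) != 1L ||
      !is.finite(object@visual_angle_deg) || object@visual_angle_deg <= 0)
    msg <- c(msg, "visual_angle_deg must be a single positive finite number")
  if (length(msg)) msg else TRUE
})

#' Frequency-domain gain mask
#'
#' Square grid of real Butterworth gains in centered (DC-at-center) frequency
#' coordinates, produced by [buildMask()]. The DC bin sits at 0-based index
#' \code{floor(N/2)} along each axis and carries gain exactly 1; gains are
#' strictly positive, at most 1, and radially non-increasing.
#'
#' @slot values numeric matrix, N x N gain grid.
#' @slot spec the [FilterSpec-class] that produced the mask.
#'
#' @exportClass FrequencyMask
setClass("FrequencyMask",
  representation(values = "matrix", spec = "FilterSpec")
)

setValidity("FrequencyMask", function(object) {
  v <- object@values
  n <- object@spec@image_size_px
  msg <- character()
  if (nrow(v) != n || ncol(v) != n)
    msg <- c(msg, "mask dimensions must equal image_size_px")
  if (any(v <= 0) || any(v > 1))
    msg <- c(msg, "mask values must lie in (0, 1]")
  dc <- floor(n / 2) + 1L
  if (abs(v[dc, dc] - 1) > 1e-12)
    msg <- c(msg, "gain at the DC position must equal 1")
  if (length(msg)) msg else TRUE
})

#' Representational dissimilarity matrix
#'
#' Symmetric, zero-diagonal stimulus-by-stimulus matrix of dissimilarities,
#' \code{1 - Spearman rank correlation} between activation (or pixel)
#' patterns, so entries lie in \code{[0, 2]}.
#'
#' @slot values numeric matrix of dissimilarities.
#' @slot ids character vector of stimulus identifiers (row/column names).
#'
#' @seealso [rdmFromActivations()], [rdmCompare()]
#' @exportClass RDM
setClass("RDM", representation(values = "matrix", ids = "character"))

setValidity("RDM", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "RDM must be square")
  if (nrow(v) != length(object@ids))
    msg <- c(msg, "ids length must match matrix dimension")
  if (max(abs(v - t(v))) > 1e-8) msg <- c(msg, "RDM must be symmetric")
  if (max(abs(diag(v))) > 1e-8) msg <- c(msg, "RDM diagonal must be zero")
  if (min(v) < -1e-8 || max(v) > 2 + 1e-8)
    msg <- c(msg, "RDM entries must lie in [0, 2]")
  if (length(msg)) msg else TRUE
})

#' Conceptual (binary model) RDM
#'
#' An [RDM-class] whose off-diagonal entries are 0 (maximally similar) or 1
#' (maximally dissimilar), encoding the hypothesis that representation tracks
#' only the low-band ("LSF") or only the high-band ("HSF") content of the
#' hybrid stimulus set.
#'
#' @slot model character(1), \code{"LSF"} or \code{"HSF"}.
#' @exportClass ConceptualRDM
setClass("ConceptualRDM", contains = "RDM",
  representation(model = "character"))

setValidity("ConceptualRDM", function(object) {
  msg <- character()
  if (!object@model %in% c("LSF", "HSF"))
    msg <- c(msg, "model must be 'LSF' or 'HSF'")
  off <- object@values[row(object@values) != col(object@values)]
  if (!all(off %in% c(0, 1)))
    msg <- c(msg, "off-diagonal entries must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Layout of the 18-image hybrid stimulus set
#'
#' Positions 1-9 are the LSF-delta images (shared high-band source, varying
#' low-band source); positions 10-18 are the HSF-delta images (shared
#' low-band source, varying high-band source). The manifest maps each
#' position to its (low-band source, high-band source) pair.
#'
#' @slot lsf_delta integer(9), positions with varying low-band content.
#' @slot hsf_delta integer(9), positions with varying high-band content.
#' @slot boundary_cpd numeric(1), low/high band boundary in cycles/degree
#'   (default 0.17).
#' @slot manifest data.frame with columns \code{position}, \code{subset},
#'   \code{low_source}, \code{high_source}.
#'
#' @seealso [buildHybridSet()], [conceptualRDM()]
#' @exportClass HybridSetLayout
setClass("HybridSetLayout",
  representation(
    lsf_delta = "integer",
    hsf_delta = "integer",
    boundary_cpd = "numeric",
    manifest = "data.frame"
  )
)

setValidity("HybridSetLayout", function(object) {
  msg <- character()
  if (length(object@lsf_delta) != 9L || length(object@hsf_delta) != 9L)
    msg <- c(msg, "layout must have exactly 9 LSF-delta and 9 HSF-delta positions")
  pos <- sort(c(object@lsf_delta, object@hsf_delta))
  if (!identical(pos, 1:18))
    msg <- c(msg, "positions must be a partition of 1..18")
  if (nrow(object@manifest) != 18L)
    msg <- c(msg, "manifest must have 18 rows")
  m <- object@manifest
  if (nrow(m) == 18L) {
    if (length(unique(m$low_source[object@hsf_delta])) != 1L)
      msg <- c(msg, "all HSF-delta positions must share one low-band source")
    if (length(unique(m$high_source[object@lsf_delta])) != 1L)
      msg <- c(msg, "all LSF-delta positions must share one high-band source")
  }
  if (object@boundary_cpd <= 0)
    msg <- c(msg, "boundary_cpd must be positive")
  if (length(msg)) msg else TRUE
})

#' Curriculum training schedule
#'
#' A named training regime over spatial-frequency levels: five stages, each a
#' set of mixing proportions over \code{SFL1..SFL4, UF}, plus a piecewise
#' learning-rate schedule whose breakpoints sit at fixed fractions (0.8, 0.9)
#' of the total epoch count.
#'
#' @slot name character(1): \code{"full"}, \code{"gradual"} or \code{"mixed"}.
#' @slot stages list of 5 named numeric vectors of proportions summing to 1.
#' @slot stage_length integer(1), epochs per stage (reference value 100).
#' @slot total_epochs integer(1); the fifth stage extends to this epoch.
#'
#' @seealso [regimeTable()], [proportionsAt()], [lrAt()]
#' @exportClass RegimeSchedule
setClass("RegimeSchedule",
  representation(
    name = "character",
    stages = "list",
    stage_length = "integer",
    total_epochs = "integer"
  )
)

setValidity("RegimeSchedule", function(object) {
  msg <- character()
  if (!object@name %in% c("full", "gradual", "mixed"))
    msg <- c(msg, "name must be one of 'full', 'gradual', 'mixed'")
  if (length(object@stages) != 5L)
    msg <- c(msg, "a schedule has exactly 5 stages")
  lv <- c("SFL1", "SFL2", "SFL3", "SFL4", "UF")
  for (s in object@stages) {
    if (!identical(names(s), lv))
      msg <- c(msg, "each stage must name proportions for SFL1..SFL4, UF")
    else if (abs(sum(s) - 1) > 1e-12 || any(s < 0))
      msg <- c(msg, "stage proportions must be non-negative and sum to 1")
  }
  if (object@stage_length < 1L)
    msg <- c(msg, "stage_length must be >= 1")
  if (object@total_epochs != 0L &&
      object@total_epochs < 4L * object@stage_length)
    msg <- c(msg, "total_epochs must cover at least stages 1-4 (or be 0 for a no-op run)")
  if (length(unique(msg))) unique(msg) else TRUE
})

#' Optimizer and run-size configuration for curriculum training
#'
#' Defaults follow the reference training setup: batch size 192, 100 steps
#' per epoch, SGD with Nesterov momentum 0.9, initial learning rate 0.5 under
#' categorical cross-entropy. Desk-scale runs override batch size, steps and
#' learning rate.
#'
#' @slot batch_size integer(1).
#' @slot steps_per_epoch integer(1).
#' @slot momentum numeric(1) in [0, 1).
#' @slot initial_lr numeric(1) > 0.
#' @slot seed integer(1), seeds all sampling and initialization.
#'
#' @seealso [trainingConfig()], [trainCurriculum()]
#' @exportClass TrainingConfig
setClass("TrainingConfig",
  representation(
    batch_size = "integer",
    steps_per_epoch = "integer",
    momentum = "numeric",
    initial_lr = "numeric",
    seed = "integer"
  )
)

setValidity("TrainingConfig", function(object) {
  msg <- character()
  if (object@batch_size < 1L) msg <- c(msg, "batch_size must be >= 1")
  if (object@steps_per_epoch < 1L) msg <- c(msg, "steps_per_epoch must be >= 1")
  if (object@momentum < 0 || object@momentum >= 1)
    msg <- c(msg, "momentum must lie in [0, 1)")
  if (object@initial_lr <= 0) msg <- c(msg, "initial_lr must be positive")
  if (length(msg)) msg else TRUE
})

#' Synthetic shape+texture dataset specification
#'
#' Parameterizes the seeded generator: each class owns a coarse blob-shape
#' prototype (low-spatial-frequency cue) and a fine oriented-sinusoid texture
#' prototype (high-spatial-frequency cue), so the category signal is carried
#' redundantly in the two frequency bands. Informativeness parameters give
#' the probability that the respective cue's family matches the image label
#' (otherwise another class's family is substituted).
#'
#' @slot n_classes integer(1).
#' @slot images_per_class integer(1).
#' @slot image_size_px integer(1), square side (default 64).
#' @slot visual_angle_deg numeric(1), default 60.
#' @slot shape_informativeness numeric(1) in [0, 1].
#' @slot texture_informativeness numeric(1) in [0, 1].
#' @slot noise_sd numeric(1), Gaussian pixel noise standard deviation.
#' @slot seed integer(1).
#' @slot shape_params data.frame, one row per class: blob center, radii,
#'   orientation.
#' @slot texture_params data.frame, one row per class: carrier frequency
#'   (cycles/image), orientation, phase.
#' @slot radius_scale numeric(1), factor applied to the SFL radii for
#'   spectral cue placement when the nominal radii exceed the Nyquist limit
#'   at \code{image_size_px}.
#'
#' @seealso [synthSpec()], [generateDataset()]
#' @exportClass SynthSpec
setClass("SynthSpec",
  representation(
    n_classes = "integer",
    images_per_class = "integer",
    image_size_px = "integer",
    visual_angle_deg = "numeric",
    shape_informativeness = "numeric",
    texture_informativeness = "numeric",
    noise_sd = "numeric",
    seed = "integer",
    shape_params = "data.frame",
    texture_params = "data.frame",
    radius_scale = "numeric"
  )
)

setValidity("SynthSpec", function(object) {
  msg <- character()
  if (object@n_classes < 2L) msg <- c(msg, "n_classes must be >= 2")
  if (object@images_per_class < 1L)
    msg <- c(msg, "images_per_class must be >= 1")
  if (object@image_size_px < 16L)
    msg <- c(msg, "image_size_px must be >= 16")
  for (f in c("shape_informativeness", "texture_informativeness")) {
    v <- slot(object, f)
    if (v < 0 || v > 1) msg <- c(msg, paste(f, "must lie in [0, 1]"))
  }
  if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be >= 0")
  nyq <- object@image_size_px / 2
  sfl4 <- 0.8 * object@visual_angle_deg * object@radius_scale
  if (nrow(object@texture_params) &&
      any(object@texture_params$carrier <= sfl4))
    msg <- c(msg, "texture carrier frequencies must exceed the scaled SFL4 radius")
  if (nrow(object@texture_params) &&
      any(object@texture_params$carrier > nyq))
    msg <- c(msg, "texture carrier frequencies must not exceed the Nyquist radius")
  if (length(msg)) msg else TRUE
})

#' Labeled synthetic image collection
#'
#' Images are held in memory as an \code{H x W x n} array of intensities in
#' \code{[0, 1]}; the manifest records, per image, the label and which shape
#' and texture families were drawn (these differ from the label when the
#' corresponding informativeness is below 1).
#'
#' @slot images numeric array, \code{H x W x n}.
#' @slot labels factor of length n.
#' @slot manifest data.frame with columns \code{id}, \code{label},
#'   \code{shape_class}, \code{texture_class}.
#' @slot spec the generating [SynthSpec-class].
#'
#' @seealso [generateDataset()]
#' @exportClass SynthDataset
setClass("SynthDataset",
  representation(
    images = "array",
    labels = "factor",
    manifest = "data.frame",
    spec = "SynthSpec"
  )
)

setValidity("SynthDataset", function(object) {
  d <- dim(object@images)
  msg <- character()
  if (length(d) != 3L) msg <- c(msg, "images must be an H x W x n array")
  if (length(d) == 3L && d[3] != length(object@labels))
    msg <- c(msg, "number of images must match number of labels")
  if (length(d) == 3L && d[3] != nrow(object@manifest))
    msg <- c(msg, "manifest rows must match number of images")
  if (length(msg)) msg else TRUE
})

#' Small convolutional classifier
#'
#' A compact reference network: three 3x3 convolution + ReLU + 2x2 average
#' pooling blocks, one hidden fully connected ReLU layer, and a softmax
#' output, trained with SGD plus Nesterov momentum under categorical
#' cross-entropy. It fulfils the model contract used by [trainCurriculum()]:
#' mini-batch updates ([modelUpdate()]), class-score prediction
#' ([modelPredict()]) and named intermediate activation extraction
#' ([modelActivations()]).
#'
#' @slot weights list of weight matrices and bias vectors.
#' @slot velocities list of momentum buffers matching \code{weights}.
#' @slot arch list describing input size, channel widths, hidden units and
#'   class count.
#'
#' @seealso [smallCNN()]
#' @exportClass SmallCNN
setClass("SmallCNN",
  representation(weights = "list", velocities = "list", arch = "list")
)
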