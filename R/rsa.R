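#' Representational dissimilarity matrix from activations
#'
#' Entry \eqn{(i, j)} is \eqn{1 - \rho_s}, one minus the Spearman rank
#' correlation (average-rank tie handling) between the activation patterns
#' of images \eqn{i} and \eqn{j}, so entries lie in \code{[0, 2]} with a
#' zero diagonal.
#'
#' @param acts numeric images-by-units activation matrix (>= 2 images,
#'   >= 2 units, finite values); row order defines the stimulus order.
#' @param ids optional character stimulus identifiers (default: rownames or
#'   \code{img1, img2, ...}).
#' @return An [RDM-class].
#' @export
rdmFromActivations <- function(acts, ids = NULL) {
  acts <- as.matrix(acts)
  if (nrow(acts) < 2L || ncol(acts) < 2L)
    stop("need at least 2 images and 2 units, got ",
         nrow(acts), " x ", ncol(acts))
  if (!all(is.finite(acts))) stop("activations must be finite")
  flat <- which(apply(acts, 1L, function(r) max(r) == min(r)))
  if (length(flat))
    stop("constant activation pattern (rank correlation undefined) for image(s): ",
         paste(flat, collapse = ", "))
  if (is.null(ids))
    ids <- if (!is.null(rownames(acts))) rownames(acts)
           else sprintf("img%d", seq_len(nrow(acts)))
  v <- 1 - stats::cor(t(acts), method = "spearman")
  diag(v) <- 0
  v[v < 0] <- 0
  v[v > 2] <- 2
  new("RDM", values = unname(v), ids = as.character(ids))
}

rdmMatrix <- function(x) {
  if (is(x, "RDM")) x@values else as.matrix(x)
}

#' Rank correlation between two RDMs
#'
#' Spearman's rho over the strictly-upper-triangle entries of both matrices
#' (the diagonal and the duplicated lower triangle are excluded).
#'
#' @param a,b [RDM-class] objects or symmetric matrices of equal size.
#' @return numeric(1), Spearman's rho.
#' @export
rdmCompare <- function(a, b) {
  ma <- rdmMatrix(a); mb <- rdmMatrix(b)
  if (!identical(dim(ma), dim(mb)))
    stop("RDM size mismatch: ", nrow(ma), " vs ", nrow(mb))
  ut <- upper.tri(ma)
  va <- ma[ut]; vb <- mb[ut]
  if (max(va) == min(va) || max(vb) == min(vb))
    stop("zero variance in an RDM's upper triangle; rank correlation undefined")
  stats::cor(va, vb, method = "spearman")
}

#' Permutation test for RDM correspondence
#'
#' Applies \code{n_perm} random relabelings of the stimuli simultaneously to
#' the rows and columns of the model RDM, recomputes its rank correlation
#' with the target after each, and reports
#' \eqn{p = \#\{\rho_{perm} > \rho_{obs}\} / n_{perm}} (strict inequality,
#' so \eqn{p} can be exactly 0). The conventional add-one estimate
#' \eqn{(\#\{\rho_{perm} \ge \rho_{obs}\} + 1)/(n_{perm} + 1)} is reported
#' alongside.
#'
#' @param model,target [RDM-class] objects (or matrices) with matching
#'   layouts, >= 3 stimuli.
#' @param n_perm number of permutations (default 1e4).
#' @return list with \code{rho} (observed), \code{p} (strict-count
#'   estimate), \code{p_conventional}, \code{n_perm}.
#' @export
permutationTestRDM <- function(model, target, n_perm = 1e4) {
  mm <- rdmMatrix(model); mt <- rdmMatrix(target)
  if (nrow(mm) < 3L) stop("need at least 3 stimuli")
  rho <- rdmCompare(mm, mt)
  n <- nrow(mm)
  exceed <- 0L
  exceed_eq <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n)
    r <- rdmCompare(mm[idx, idx], mt)
    if (r > rho) exceed <- exceed + 1L
    if (r >= rho - 1e-12) exceed_eq <- exceed_eq + 1L
  }
  list(rho = rho,
       p = exceed / n_perm,
       p_conventional = (exceed_eq + 1) / (n_perm + 1),
       n_perm = n_perm)
}

#' Bootstrap standard deviation of an RDM correlation
#'
#' Resamples stimuli (not RDM cells) with replacement, forms both resampled
#' RDMs from the precomputed entries, excludes self-pair duplicates (a
#' stimulus paired with its own copy, a structural zero) from the compared
#' triangle, and recomputes the rank correlation. Replicates with fewer than
#' 3 distinct stimuli, or with no rank variance left after exclusion, are
#' redrawn and counted.
#'
#' @param model,target [RDM-class] objects (or matrices) with matching
#'   layouts, >= 3 stimuli.
#' @param n_boot number of bootstrap replicates (default 1e4).
#' @return list with \code{sd} (standard deviation of the replicate rho
#'   distribution), \code{mean_rho}, \code{n_boot}, \code{n_redrawn}.
#' @export
bootstrapSdRDM <- function(model, target, n_boot = 1e4) {
  mm <- rdmMatrix(model); mt <- rdmMatrix(target)
  if (!identical(dim(mm), dim(mt)))
    stop("RDM size mismatch: ", nrow(mm), " vs ", nrow(mt))
  n <- nrow(mm)
  if (n < 3L) stop("need at least 3 stimuli")
  rhos <- numeric(n_boot)
  redrawn <- 0L
  max_attempts <- 100L * n_boot
  attempts <- 0L
  i <- 1L
  while (i <= n_boot) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("bootstrap failed: too many degenerate replicates")
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(idx)) < 3L) {
      redrawn <- redrawn + 1L
      next
    }
    keep <- upper.tri(mm) & outer(idx, idx, "!=")
    va <- mm[idx, idx][keep]
    vb <- mt[idx, idx][keep]
    if (length(va) < 3L || max(va) == min(va) || max(vb) == min(vb)) {
      redrawn <- redrawn + 1L
      next
    }
    rhos[i] <- stats::cor(va, vb, method = "spearman")
    i <- i + 1L
  }
  if (redrawn > 0L)
    message("bootstrapSdRDM: ", redrawn, " degenerate replicate(s) redrawn")
  list(sd = stats::sd(rhos), mean_rho = mean(rhos), n_boot = n_boot,
       n_redrawn = redrawn)
}

#' Extract an activation matrix from a model
#'
#' Forward-passes a stack of images and returns the named layer's
#' activations with one row per image, in the input order; convolutional
#' layers are returned flattened. The tags \code{"final_fc"} (the hidden
#' fully connected layer) and \code{"mid_conv"} (the middle convolution
#' block) map onto the reference model's corresponding layers.
#'
#' @param model a classifier implementing [modelActivations()].
#' @param images numeric \code{H x W x n} array.
#' @param layer layer tag; \code{"final_fc"}, \code{"mid_conv"} or any tag
#'   in [availableLayers()].
#' @return numeric images-by-units matrix.
#' @export
extractActivations <- function(model, images, layer = "final_fc") {
  tag <- switch(layer, final_fc = "hidden", mid_conv = "conv2", layer)
  modelActivations(model, images, tag)
}

#' Pixel-intensity observer activations for a stimulus set
#'
#' A training-free reference observer: each image is low- or high-pass
#' filtered at \code{boundary_cpd} and its pixel intensities are used
#' directly as the activation pattern. The low-band observer sees only
#' coarse content, the high-band observer only fine content, so their RDMs
#' should track the LSF and HSF conceptual models respectively.
#'
#' @param images numeric \code{N x N x n} array in \code{[0, 1]}.
#' @param band \code{"low"} or \code{"high"}.
#' @param boundary_cpd band boundary in cycles/degree (default 0.17).
#' @param order_n,visual_angle_deg filter calibration.
#' @return numeric images-by-pixels activation matrix.
#' @export
pixelObserver <- function(images, band = c("low", "high"),
                          boundary_cpd = 0.17, order_n = 4L,
                          visual_angle_deg = 60) {
  band <- match.arg(band)
  N <- dim(images)[1]
  n <- dim(images)[3]
  spec <- filterSpec(boundary_cpd, N, order_n, visual_angle_deg)
  acts <- matrix(0, n, N * N)
  for (i in seq_len(n)) {
    f <- if (band == "low") lowpass(images[, , i], spec, clip = FALSE)
         else highpass(images[, , i], spec, clip = FALSE)
    acts[i, ] <- as.vector(f)
  }
  acts
}
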