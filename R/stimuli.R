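#' Compose a hybrid image from a low-band and a high-band source
#'
#' Superimposes the low-pass band (below \code{boundary_cpd}) of one image
#' with the high-pass band (above \code{boundary_cpd}) of another. Because
#' the high-pass mask is the exact complement of the low-pass mask, using the
#' same image for both sources reconstructs it exactly (before clipping).
#'
#' @param low_source,high_source square numeric images of identical shape
#'   with intensities in \code{[0, 1]}.
#' @param boundary_cpd band boundary in cycles/degree (default 0.17).
#' @param order_n,visual_angle_deg filter calibration, see [filterSpec()].
#' @param clip logical, clip the composite to \code{[0, 1]} (default TRUE).
#' @return The hybrid image, same shape as the inputs.
#' @export
makeHybrid <- function(low_source, high_source, boundary_cpd = 0.17,
                       order_n = 4L, visual_angle_deg = 60, clip = TRUE) {
  if (!identical(dim(low_source), dim(high_source)))
    stop("low_source and high_source must have identical shape, got ",
         paste(dim(low_source), collapse = "x"), " vs ",
         paste(dim(high_source), collapse = "x"))
  spec <- filterSpec(boundary_cpd, nrow(low_source), order_n,
                     visual_angle_deg)
  out <- lowpass(low_source, spec, clip = FALSE) +
    highpass(high_source, spec, clip = FALSE)
  if (clip) clip01(out) else out
}

#' Build the 18-image hybrid stimulus set
#'
#' Positions 1-9 (the LSF-delta subset) share one high-band source and vary
#' the low-band source; positions 10-18 (the HSF-delta subset) share one
#' low-band source and vary the high-band source. Images are returned in
#' this fixed order.
#'
#' @param lsf_sources list of 9 images providing the varying low-band
#'   content.
#' @param hsf_sources list of 9 images providing the varying high-band
#'   content.
#' @param shared_low,shared_high the common low-band / high-band sources.
#' @param boundary_cpd band boundary in cycles/degree (default 0.17).
#' @param order_n,visual_angle_deg filter calibration.
#' @return list with elements \code{layout} (a [HybridSetLayout-class]) and
#'   \code{images} (an \code{N x N x 18} array).
#' @seealso [generateHybridSources()], [conceptualRDM()]
#' @export
buildHybridSet <- function(lsf_sources, hsf_sources, shared_low,
                           shared_high, boundary_cpd = 0.17, order_n = 4L,
                           visual_angle_deg = 60) {
  if (length(lsf_sources) != 9L || length(hsf_sources) != 9L)
    stop("expected 9 LSF-delta and 9 HSF-delta sources, got ",
         length(lsf_sources), "/", length(hsf_sources))
  all_imgs <- c(lsf_sources, hsf_sources, list(shared_low, shared_high))
  dims <- unique(lapply(all_imgs, dim))
  if (length(dims) != 1L)
    stop("all source images must share one shape")
  N <- nrow(shared_low)
  images <- array(0, dim = c(N, N, 18L))
  for (i in 1:9)
    images[, , i] <- makeHybrid(lsf_sources[[i]], shared_high,
                                boundary_cpd, order_n, visual_angle_deg)
  for (j in 1:9)
    images[, , 9L + j] <- makeHybrid(shared_low, hsf_sources[[j]],
                                     boundary_cpd, order_n,
                                     visual_angle_deg)
  manifest <- data.frame(
    position = 1:18,
    subset = rep(c("LSFdelta", "HSFdelta"), each = 9L),
    low_source = c(sprintf("lsf%d", 1:9), rep("shared_low", 9L)),
    high_source = c(rep("shared_high", 9L), sprintf("hsf%d", 1:9)),
    stringsAsFactors = FALSE)
  layout <- new("HybridSetLayout",
                lsf_delta = 1:9, hsf_delta = 10:18,
                boundary_cpd = as.numeric(boundary_cpd),
                manifest = manifest)
  list(layout = layout, images = images)
}

#' Conceptual model RDMs for the hybrid set
#'
#' The LSF model encodes the hypothesis that representation tracks only
#' low-band content: dissimilarity 0 for pairs sharing their low-band source
#' (all pairs within the HSF-delta subset) and 1 for pairs that differ in it
#' (all pairs within the LSF-delta subset). The HSF model is the mirror rule
#' on high-band sources. Cross-subset pairs score 0 whenever they happen to
#' share the relevant band source and 1 otherwise; with the standard layout
#' they share neither, so they score 1 in both models (mask them out
#' downstream if undesired).
#'
#' @param layout a [HybridSetLayout-class].
#' @param model \code{"LSF"} or \code{"HSF"}.
#' @return A [ConceptualRDM-class].
#' @export
conceptualRDM <- function(layout, model = c("LSF", "HSF")) {
  stopifnot(is(layout, "HybridSetLayout"))
  validObject(layout)
  model <- match.arg(model)
  m <- layout@manifest
  src <- if (model == "LSF") m$low_source else m$high_source
  v <- 1 - outer(src, src, "==") * 1
  diag(v) <- 0
  new("ConceptualRDM", values = v,
      ids = sprintf("hyb%02d", m$position), model = model)
}

#' Build a restricted n-way test set across frequency levels
#'
#' Mirrors the behavioral-style evaluation layout: for each class and each
#' frequency level, \code{exemplars_per_cell} filtered images, with every
#' source exemplar used exactly once across the whole set. Exemplars are
#' assigned to cells in their stored order, so the assignment is
#' deterministic.
#'
#' @param dataset a [SynthDataset-class] (or list with elements
#'   \code{images}, an \code{H x W x n} array, and \code{labels}, a factor).
#' @param levels character vector of bank levels (default
#'   \code{c("SFL1", "SFL2", "UF")}).
#' @param exemplars_per_cell images per class-by-level cell (default 10).
#' @param order_n,visual_angle_deg filter calibration.
#' @return list with \code{images} (filtered \code{H x W x n_total} array),
#'   \code{labels} (integer class indices), and \code{manifest}
#'   (data.frame with columns \code{class}, \code{level}, \code{source}).
#' @export
buildNwayTestSet <- function(dataset, levels = c("SFL1", "SFL2", "UF"),
                             exemplars_per_cell = 10L, order_n = 4L,
                             visual_angle_deg = 60) {
  if (is(dataset, "SynthDataset"))
    dataset <- list(images = dataset@images, labels = dataset@labels)
  labels <- as.factor(dataset$labels)
  bank <- sflBank()
  if (!all(levels %in% bank$label))
    stop("unknown levels: ",
         paste(setdiff(levels, bank$label), collapse = ", "))
  need <- length(levels) * exemplars_per_cell
  classes <- levels(labels)
  for (cl in classes) {
    have <- sum(labels == cl)
    if (have < need)
      stop(sprintf(
        "class '%s' has %d exemplars but %d are required (%d levels x %d)",
        cl, have, need, length(levels), exemplars_per_cell))
  }
  N <- dim(dataset$images)[1]
  n_total <- length(classes) * need
  images <- array(0, dim = c(N, N, n_total))
  rows <- vector("list", n_total)
  out_i <- 0L
  for (ci in seq_along(classes)) {
    src_idx <- which(labels == classes[ci])[seq_len(need)]
    pos <- 0L
    for (lv in levels) {
      cutoff <- bank$cutoff_cpd[bank$label == lv]
      spec <- if (is.na(cutoff)) NULL else
        filterSpec(cutoff, N, order_n, visual_angle_deg)
      for (e in seq_len(exemplars_per_cell)) {
        pos <- pos + 1L
        out_i <- out_i + 1L
        src <- src_idx[pos]
        img <- dataset$images[, , src]
        images[, , out_i] <- if (is.null(spec)) img else lowpass(img, spec)
        rows[[out_i]] <- data.frame(class = classes[ci], level = lv,
                                    source = src, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (anyDuplicated(manifest$source))
    stop("internal audit failed: a source exemplar was reused across cells")
  list(images = images,
       labels = rep(seq_along(classes), each = need),
       manifest = manifest)
}
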