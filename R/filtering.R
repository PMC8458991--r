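#' Construct a calibrated filter specification
#'
#' @param cutoff_cpd cutoff spatial frequency in cycles/degree (> 0).
#' @param image_size_px side length of the square image in pixels.
#' @param order_n Butterworth order (default 4).
#' @param visual_angle_deg assumed angular size of the image (default 60).
#'
#' @return A [FilterSpec-class] object.
#' @examples
#' sp <- filterSpec(0.1, 224)
#' cutoffRadius(sp)  # 6 cycles/image
#' @export
filterSpec <- function(cutoff_cpd, image_size_px, order_n = 4L,
                       visual_angle_deg = 60) {
  new("FilterSpec",
      cutoff_cpd = as.numeric(cutoff_cpd),
      order_n = as.integer(order_n),
      image_size_px = as.integer(image_size_px),
      visual_angle_deg = as.numeric(visual_angle_deg))
}

#' Cutoff radius in cycles per image
#'
#' Converts the cutoff from cycles/degree to cycles/image,
#' \eqn{r = \mathrm{cutoff}_{c/deg} \times \theta_{deg}}. With pixels/degree
#' \eqn{N/\theta} and pixels/cycle \eqn{N/r}, spatial frequency in c/deg is
#' their ratio \eqn{r/\theta}; inverting gives the radius, which is therefore
#' independent of the pixel size \eqn{N}. Radii above the Nyquist radius
#' \eqn{N/2} are permitted and yield near-identity filters.
#'
#' @param spec a [FilterSpec-class].
#' @return numeric(1), the cutoff radius in cycles per image.
#' @export
cutoffRadius <- function(spec) {
  stopifnot(is(spec, "FilterSpec"))
  validObject(spec)
  spec@cutoff_cpd * spec@visual_angle_deg
}

#' Butterworth low-pass gain
#'
#' Gain of the order-\eqn{n} Butterworth low-pass filter at distance \eqn{D}
#' from the DC position,
#' \deqn{g(D) = \frac{1}{1 + (\sqrt{2} - 1)\,(D/r)^{2n}},}
#' which equals 1 at DC and \eqn{2^{-1/2}} (the half-power point) at
#' \eqn{D = r} for every order.
#'
#' @param D distance(s) from the DC position in frequency-grid units (>= 0).
#' @param r cutoff radius in the same units (> 0).
#' @param n filter order (>= 1).
#' @return numeric gain(s) in (0, 1].
#' @export
butterworthGain <- function(D, r, n) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("cutoff radius 'r' must be a single positive number")
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("filter order 'n' must be >= 1")
  if (any(D < 0)) stop("distances 'D' must be non-negative")
  1 / (1 + (sqrt(2) - 1) * (D / r)^(2 * n))
}

#' Build the centered frequency-domain gain mask
#'
#' Evaluates [butterworthGain()] over the full 2-D frequency grid in centered
#' (DC-at-center) coordinates: the DC bin sits at 0-based index
#' \code{floor(N/2)} on each axis and \eqn{D} is the Euclidean distance from
#' it in grid cells.
#'
#' @param spec a [FilterSpec-class].
#' @return A [FrequencyMask-class].
#' @export
buildMask <- function(spec) {
  r <- cutoffRadius(spec)
  n <- spec@image_size_px
  off <- seq_len(n) - 1L - floor(n / 2)
  D <- sqrt(outer(off^2, off^2, "+"))
  new("FrequencyMask",
      values = butterworthGain(D, r, spec@order_n),
      spec = spec)
}

#' The canonical spatial-frequency level bank
#'
#' Four low-pass cutoff levels 0.1, 0.3, 0.5 and 0.8 cycles/degree, labeled
#' SFL1-SFL4 in increasing order, chosen to mimic the developing infant
#' contrast-sensitivity peak, plus the unfiltered level UF (no filtering,
#' cutoff \code{NA}).
#'
#' @return data.frame with columns \code{label} and \code{cutoff_cpd}.
#' @examples
#' sflBank()
#' @export
sflBank <- function() {
  data.frame(label = c("SFL1", "SFL2", "SFL3", "SFL4", "UF"),
             cutoff_cpd = c(0.1, 0.3, 0.5, 0.8, NA_real_),
             stringsAsFactors = FALSE)
}

## circular-shift index vectors moving the DC bin between corner (index 1,
## fft convention) and center (index floor(N/2)+1, mask convention)
fftshiftIdx <- function(n) ((seq_len(n) - 1L - floor(n / 2)) %% n) + 1L
ifftshiftIdx <- function(n) ((seq_len(n) - 1L + floor(n / 2)) %% n) + 1L

checkImage <- function(x, spec) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("image must be a 2-D matrix or an H x W x C array")
  if (length(d) == 3L && !(d[3] %in% c(1L, 3L)))
    stop("channel dimension must be 1 or 3, got ", d[3])
  if (d[1] != d[2])
    stop("image must be square, got ", d[1], " x ", d[2])
  if (d[1] != spec@image_size_px)
    stop("image side ", d[1], " does not match spec image_size_px ",
         spec@image_size_px)
  rng <- range(x)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop(sprintf("image intensities must lie in [0, 1], found range [%g, %g]",
                 rng[1], rng[2]))
  invisible(TRUE)
}

## multiply each channel's spectrum by an (unshifted) gain grid
applyGain <- function(x, gain_unshifted) {
  n2 <- length(gain_unshifted)
  one <- function(ch)
    Re(stats::fft(stats::fft(ch) * gain_unshifted, inverse = TRUE)) / n2
  if (is.matrix(x)) return(one(x))
  out <- x
  for (c in seq_len(dim(x)[3])) out[, , c] <- one(x[, , c])
  out
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Low-pass and high-pass filter an image
#'
#' \code{lowpass} multiplies the image's centered spectrum by the Butterworth
#' mask of \code{spec} (per channel: FFT, gain multiplication, inverse FFT,
#' real part); \code{highpass} uses the complementary mask \code{1 - mask},
#' so before clipping \code{lowpass(x) + highpass(x)} reconstructs \code{x}
#' exactly. With \code{clip = TRUE} (default) the result is clipped to
#' \code{[0, 1]}.
#'
#' @param image square numeric matrix or \code{H x W x C} array
#'   (\code{C} 1 or 3) with intensities in \code{[0, 1]}; side length must
#'   equal \code{spec@image_size_px}.
#' @param spec a [FilterSpec-class].
#' @param clip logical, clip the output to \code{[0, 1]}.
#' @return Filtered image of the same shape.
#' @examples
#' sp <- filterSpec(0.1, 32)
#' x <- matrix(runif(32 * 32), 32)
#' lp <- lowpass(x, sp)
#' hp <- highpass(x, sp, clip = FALSE)
#' max(abs(lowpass(x, sp, clip = FALSE) + hp - x))  # ~1e-16
#' @export
lowpass <- function(image, spec, clip = TRUE) {
  checkImage(image, spec)
  m <- maskValues(buildMask(spec))
  i <- ifftshiftIdx(nrow(m))
  out <- applyGain(image, m[i, i])
  if (clip) clip01(out) else out
}

#' @rdname lowpass
#' @export
highpass <- function(image, spec, clip = TRUE) {
  checkImage(image, spec)
  m <- 1 - maskValues(buildMask(spec))
  i <- ifftshiftIdx(nrow(m))
  out <- applyGain(image, m[i, i])
  if (clip) clip01(out) else out
}

#' Filter an in-memory image stack at every level of a bank
#'
#' Convenience used by the training and evaluation pipeline: applies the
#' low-pass filter of each level of \code{bank} to every image of a stack,
#' passing the unfiltered level (\code{NA} cutoff) through unchanged.
#'
#' @param images numeric array \code{H x W x n} with intensities in
#'   \code{[0, 1]}.
#' @param bank data.frame as returned by [sflBank()].
#' @param order_n,visual_angle_deg filter calibration, see
#'   [filterSpec()].
#' @return Named list (one element per bank level) of filtered
#'   \code{H x W x n} arrays.
#' @export
filterLevels <- function(images, bank = sflBank(), order_n = 4L,
                         visual_angle_deg = 60) {
  stopifnot(length(dim(images)) == 3L)
  n_img <- dim(images)[3]
  size <- dim(images)[1]
  out <- vector("list", nrow(bank))
  names(out) <- bank$label
  for (k in seq_len(nrow(bank))) {
    if (is.na(bank$cutoff_cpd[k])) {
      out[[k]] <- images
      next
    }
    sp <- filterSpec(bank$cutoff_cpd[k], size, order_n, visual_angle_deg)
    m <- maskValues(buildMask(sp))
    i <- ifftshiftIdx(size)
    gu <- m[i, i]
    filtered <- images
    for (j in seq_len(n_img))
      filtered[, , j] <- clip01(applyGain(images[, , j], gu))
    out[[k]] <- filtered
  }
  out
}

readImageArray <- function(path, size) {
  img <- EBImage::readImage(path)
  img <- EBImage::resize(img, w = size, h = size)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L && dim(dat)[3] > 3L)
    dat <- dat[, , 1:3]  # drop alpha
  clip01(dat)
}

#' Filter a directory of images at every level of a bank
#'
#' Reads every PNG/JPEG under \code{input_dir} (recursively, sorted paths),
#' resizes each to \code{image_size} (bilinear, square stretch), writes one
#' complete low-pass-filtered copy per bank level plus the unfiltered
#' passthrough under \code{output_root/<level>/}, and records everything in a
#' manifest.
#'
#' @param input_dir directory containing images (\code{.png}, \code{.jpg},
#'   \code{.jpeg}).
#' @param output_root output directory; one subdirectory per level.
#' @param bank data.frame as returned by [sflBank()].
#' @param image_size working square size in pixels (default 224).
#' @param order_n,visual_angle_deg filter calibration.
#' @return data.frame manifest with columns \code{source}, \code{level},
#'   \code{path}, also written to \code{output_root/manifest.csv}; the number
#'   of unreadable (skipped) source images is attached as attribute
#'   \code{"n_skipped"}.
#' @export
filterDataset <- function(input_dir, output_root, bank = sflBank(),
                          image_size = 224L, order_n = 4L,
                          visual_angle_deg = 60) {
  files <- sort(list.files(input_dir, pattern = "\\.(png|jpe?g)$",
                           ignore.case = TRUE, recursive = TRUE,
                           full.names = TRUE))
  dir.create(output_root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_root))
    stop("cannot create output directory: ", output_root)
  if (length(files) == 0L) {
    warning("no readable images found under ", input_dir,
            "; writing an empty manifest")
    manifest <- data.frame(source = character(), level = character(),
                           path = character(), stringsAsFactors = FALSE)
    utils::write.csv(manifest, file.path(output_root, "manifest.csv"),
                     row.names = FALSE)
    attr(manifest, "n_skipped") <- 0L
    return(manifest)
  }
  specs <- lapply(seq_len(nrow(bank)), function(k) {
    if (is.na(bank$cutoff_cpd[k])) NULL
    else filterSpec(bank$cutoff_cpd[k], image_size, order_n,
                    visual_angle_deg)
  })
  rows <- list()
  n_skipped <- 0L
  for (f in files) {
    dat <- tryCatch(readImageArray(f, image_size), error = function(e) NULL)
    if (is.null(dat)) {
      message("skipping unreadable image: ", f)
      n_skipped <- n_skipped + 1L
      next
    }
    base <- sub("\\.[^.]+$", "", basename(f))
    for (k in seq_len(nrow(bank))) {
      lv <- bank$label[k]
      dir.create(file.path(output_root, lv), showWarnings = FALSE)
      out <- if (is.null(specs[[k]])) dat else
        clip01(lowpass(dat, specs[[k]], clip = FALSE))
      dest <- file.path(output_root, lv, paste0(base, ".png"))
      ok <- tryCatch({
        EBImage::writeImage(EBImage::Image(out,
          colormode = if (length(dim(out)) == 3L) "Color" else "Grayscale"),
          dest)
        TRUE
      }, error = function(e)
        stop("failed to write ", dest, ": ", conditionMessage(e)))
      rows[[length(rows) + 1L]] <-
        data.frame(source = f, level = lv, path = dest,
                   stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(output_root, "manifest.csv"),
                   row.names = FALSE)
  attr(manifest, "n_skipped") <- n_skipped
  manifest
}
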