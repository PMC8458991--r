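## evaluate `code` under a private RNG stream seeded with `seed`,
## restoring the caller's RNG state afterwards
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## scaling factor applied to the SFL radii for spectral cue placement:
## the nominal radii r = cutoff * theta can exceed the Nyquist radius N/2 at
## small working sizes, so the generator compresses its cue placement
## proportionally to keep the highest level inside the representable band
radiusScale <- function(image_size_px, visual_angle_deg = 60) {
  max_r <- 0.8 * visual_angle_deg
  nyq <- image_size_px / 2
  if (max_r > 0.45 * nyq) 0.45 * nyq / max_r else 1
}

#' Specify a synthetic shape+texture dataset
#'
#' Builds the per-class cue prototypes deterministically from the class
#' index: blob centers are spread on a ring around the image center with
#' class-varying radii (the coarse, low-frequency shape cue), and texture
#' carriers are oriented sinusoids at class-specific orientation and radial
#' frequency above the (rescaled) SFL4 radius (the fine, high-frequency
#' cue). When the nominal SFL radii exceed the Nyquist limit at
#' \code{image_size_px}, the generator's cue placement is compressed by a
#' proportional \code{radius_scale} (with a warning); the filters themselves
#' always use the size-independent calibration \code{r = cutoff * angle}.
#'
#' @param n_classes number of categories (default 10).
#' @param images_per_class images generated per category.
#' @param image_size_px square side in pixels (default 64).
#' @param shape_informativeness,texture_informativeness probability in
#'   \code{[0, 1]} that the respective cue's family matches the image label;
#'   below 1, the family is drawn uniformly from the other classes.
#' @param noise_sd Gaussian pixel noise standard deviation (default 0.08).
#' @param seed integer seed; generation is fully reproducible.
#' @param visual_angle_deg assumed angular size (default 60).
#' @param shape_ring radius of the ring of class blob centers, as a fraction
#'   of the image side; small values make the coarse cue a fine positional
#'   discrimination.
#' @param radius_step per-class step of the blob radii (fraction of the
#'   image side); together with \code{scale_jitter} it sets how separable
#'   the blob sizes are.
#' @param center_jitter per-image uniform center jitter (fraction of the
#'   image side).
#' @param scale_jitter per-image uniform blob scale jitter (fraction of 1).
#' @return A [SynthSpec-class].
#' @export
synthSpec <- function(n_classes = 10L, images_per_class = 20L,
                      image_size_px = 64L, shape_informativeness = 1,
                      texture_informativeness = 1, noise_sd = 0.08,
                      seed = 1L, visual_angle_deg = 60,
                      shape_ring = 0.04, radius_step = 0.008,
                      center_jitter = 0.05, scale_jitter = 0.05) {
  n_classes <- as.integer(n_classes)
  N <- as.integer(image_size_px)
  s <- radiusScale(N, visual_angle_deg)
  if (s < 1)
    warning(sprintf(
      "SFL radii exceed the Nyquist radius at %d px; cue placement rescaled by %.3g",
      N, s))
  nyq <- N / 2
  k <- seq_len(n_classes)
  shape_params <- data.frame(
    class = k,
    center_x = 0.5 * N + shape_ring * N * cos(2 * pi * (k - 1) / n_classes),
    center_y = 0.5 * N + shape_ring * N * sin(2 * pi * (k - 1) / n_classes),
    radius_x = N * (0.20 + radius_step * ((k - 1) %% 5)),
    radius_y = N * (0.20 + radius_step * (((k - 1) * 2) %% 5)),
    edge_w = 3.5,
    ## fine shape detail: a small bump on the silhouette boundary at a
    ## class-specific angle; its spatial scale puts it between the SFL1 and
    ## SFL2 cutoff radii, so it is erased by the lowest-frequency view but
    ## crisp in all higher ones (as fine contour detail of real objects is)
    bump_angle = 2 * pi * (k - 1) / n_classes + pi / n_classes,
    bump_sigma = 0.04 * N,
    bump_amp = 0.6,
    center_jitter = center_jitter,
    scale_jitter = scale_jitter
  )
  texture_params <- data.frame(
    class = k,
    carrier = nyq * (0.50 + 0.03 * ((k - 1) %/% 5)),
    orientation = pi * ((k - 1) %% 5) / 5,
    phase = 0.7 * k
  )
  new("SynthSpec",
      n_classes = n_classes,
      images_per_class = as.integer(images_per_class),
      image_size_px = N,
      visual_angle_deg = as.numeric(visual_angle_deg),
      shape_informativeness = as.numeric(shape_informativeness),
      texture_informativeness = as.numeric(texture_informativeness),
      noise_sd = as.numeric(noise_sd),
      seed = as.integer(seed),
      shape_params = shape_params,
      texture_params = texture_params,
      radius_scale = s)
}

## soft-edged elliptical silhouette; rows index y, columns x, 0-based pixel
## coords; edge_w is the soft edge width in pixels (small = sharp boundary,
## which places a slice of the shape's energy above the lowest cutoffs, as
## real object contours do)
renderBlob <- function(N, cx, cy, rx, ry, edge_w = 2) {
  x <- seq_len(N) - 1
  d <- sqrt(outer(rep(1, N), ((x - cx) / rx)^2) +
            outer(((x - cy) / ry)^2, rep(1, N)))
  1 / (1 + exp((d - 1) * (rx + ry) / 2 / edge_w))
}

## localized zero-mean ripple at a point on the ellipse boundary: a Gaussian
## envelope times an oriented sinusoid at mid-band frequency (between the
## SFL1 and SFL2 cutoff radii), so the detail is erased by the lowest-level
## view but crisp in all higher ones
renderBump <- function(N, cx, cy, rx, ry, angle, sigma, freq = 11) {
  bx <- cx + rx * cos(angle)
  by <- cy + ry * sin(angle)
  x <- seq_len(N) - 1
  env <- exp(-0.5 * (outer(rep(1, N), ((x - bx) / sigma)^2) +
                     outer(((x - by) / sigma)^2, rep(1, N))))
  phase <- outer((x - by) * sin(angle), rep(1, N)) +
    outer(rep(1, N), (x - bx) * cos(angle))
  env * sin(2 * pi * freq * phase / N)
}

## oriented sinusoid, carrier in cycles/image
renderCarrier <- function(N, carrier, orientation, phase) {
  x <- seq_len(N) - 1
  fx <- carrier * cos(orientation) / N
  fy <- carrier * sin(orientation) / N
  px <- outer(rep(1, N), x * fx)
  py <- outer(x * fy, rep(1, N))
  sin(2 * pi * (px + py) + phase)
}

## fraction of non-DC spectral energy at distance <= radius from DC
spectralEnergyBelow <- function(img, radius) {
  N <- nrow(img)
  p <- Mod(stats::fft(img))^2
  i <- fftshiftIdx(N)
  p <- p[i, i]
  off <- seq_len(N) - 1L - floor(N / 2)
  D <- sqrt(outer(off^2, off^2, "+"))
  dc <- floor(N / 2) + 1L
  p[dc, dc] <- 0
  tot <- sum(p)
  if (tot == 0) return(NA_real_)
  sum(p[D <= radius]) / tot
}

## rendering amplitudes shared by the dataset and hybrid-source generators
synthAmplitudes <- function() {
  list(bg = 0.15, blob = 0.30, texture = 0.50)
}

synthImage <- function(spec, shape_class, texture_class, jitter = NULL) {
  N <- spec@image_size_px
  amp <- synthAmplitudes()
  sp <- spec@shape_params[shape_class, ]
  tp <- spec@texture_params[texture_class, ]
  if (is.null(jitter)) jitter <- list(dx = 0, dy = 0, scale = 1)
  blob <- renderBlob(N, sp$center_x + jitter$dx, sp$center_y + jitter$dy,
                     sp$radius_x * jitter$scale, sp$radius_y * jitter$scale,
                     sp$edge_w)
  ## the texture is windowed by a softened copy of the blob so its spectral
  ## footprint stays a narrow band around the carrier
  win <- renderBlob(N, sp$center_x + jitter$dx, sp$center_y + jitter$dy,
                    sp$radius_x * jitter$scale, sp$radius_y * jitter$scale,
                    5)
  bump <- renderBump(N, sp$center_x + jitter$dx, sp$center_y + jitter$dy,
                     sp$radius_x * jitter$scale, sp$radius_y * jitter$scale,
                     sp$bump_angle, sp$bump_sigma)
  tex <- renderCarrier(N, tp$carrier, tp$orientation, tp$phase)
  amp$bg + amp$blob * (blob + sp$bump_amp * bump) + amp$texture * tex * win
}

## generation-time spectral audit of the cue prototypes
verifySpectralPlacement <- function(spec, tol = 0.9) {
  N <- spec@image_size_px
  s <- spec@radius_scale
  r_sfl1 <- 0.1 * spec@visual_angle_deg * s
  r_sfl4 <- 0.8 * spec@visual_angle_deg * s
  amp <- synthAmplitudes()
  for (k in seq_len(spec@n_classes)) {
    sp <- spec@shape_params[k, ]
    blob <- renderBlob(N, sp$center_x, sp$center_y, sp$radius_x,
                       sp$radius_y, sp$edge_w)
    bump <- renderBump(N, sp$center_x, sp$center_y, sp$radius_x,
                       sp$radius_y, sp$bump_angle, sp$bump_sigma)
    shape <- blob + sp$bump_amp * bump
    f_lo <- spectralEnergyBelow(amp$blob * shape, r_sfl1)
    if (is.na(f_lo) || f_lo < tol)
      stop(sprintf(
        "shape prototype %d places only %.1f%% of its non-DC energy below the scaled SFL1 radius %.3g",
        k, 100 * f_lo, r_sfl1))
    tp <- spec@texture_params[k, ]
    win <- renderBlob(N, sp$center_x, sp$center_y, sp$radius_x,
                      sp$radius_y, 5)
    tex <- renderCarrier(N, tp$carrier, tp$orientation, tp$phase)
    f_hi <- 1 - spectralEnergyBelow(amp$texture * tex * win, r_sfl4)
    if (is.na(f_hi) || f_hi < tol)
      stop(sprintf(
        "texture prototype %d places only %.1f%% of its energy above the scaled SFL4 radius %.3g",
        k, 100 * f_hi, r_sfl4))
  }
  invisible(TRUE)
}

## with probability p the cue family equals the label, otherwise a
## uniformly drawn *other* class
drawCueClass <- function(label, p, n_classes) {
  if (stats::runif(1) <= p || n_classes < 2L) return(label)
  others <- setdiff(seq_len(n_classes), label)
  others[sample.int(length(others), 1L)]
}

#' Generate a labeled synthetic image dataset
#'
#' Each image is a soft blob silhouette (the class's coarse shape cue) plus a
#' fixed-phase oriented sinusoidal texture windowed by the blob (the class's
#' fine texture cue) plus Gaussian pixel noise, clipped to \code{[0, 1]}.
#' Blob center and size receive a small per-image jitter. Generation is
#' class-balanced and fully deterministic given \code{spec@seed}; the
#' spectral placement of the cue prototypes (blob energy below the scaled
#' SFL1 radius, texture energy above the scaled SFL4 radius) is audited at
#' generation time.
#'
#' @param spec a [SynthSpec-class].
#' @return A [SynthDataset-class].
#' @examples
#' ds <- generateDataset(synthSpec(n_classes = 3, images_per_class = 2))
#' dim(ds@images)
#' @export
generateDataset <- function(spec) {
  validObject(spec)
  verifySpectralPlacement(spec)
  N <- spec@image_size_px
  n <- spec@n_classes * spec@images_per_class
  withSeed(spec@seed, {
    images <- array(0, dim = c(N, N, n))
    labels <- integer(n)
    shape_class <- integer(n)
    texture_class <- integer(n)
    idx <- 0L
    for (cls in seq_len(spec@n_classes)) {
      for (j in seq_len(spec@images_per_class)) {
        idx <- idx + 1L
        labels[idx] <- cls
        shape_class[idx] <-
          drawCueClass(cls, spec@shape_informativeness, spec@n_classes)
        texture_class[idx] <-
          drawCueClass(cls, spec@texture_informativeness, spec@n_classes)
        cj <- spec@shape_params$center_jitter[1]
        sj <- spec@shape_params$scale_jitter[1]
        jit <- list(dx = stats::runif(1, -cj, cj) * N,
                    dy = stats::runif(1, -cj, cj) * N,
                    scale = stats::runif(1, 1 - sj, 1 + sj))
        img <- synthImage(spec, shape_class[idx], texture_class[idx], jit)
        if (spec@noise_sd > 0)
          img <- img + matrix(stats::rnorm(N * N, 0, spec@noise_sd), N, N)
        images[, , idx] <- clip01(img)
      }
    }
    manifest <- data.frame(
      id = sprintf("img%05d", seq_len(n)),
      label = sprintf("class%02d", labels),
      shape_class = shape_class,
      texture_class = texture_class,
      stringsAsFactors = FALSE)
    new("SynthDataset",
        images = images,
        labels = factor(manifest$label,
                        levels = sprintf("class%02d", seq_len(spec@n_classes))),
        manifest = manifest,
        spec = spec)
  })
}

#' Generate source images for the hybrid stimulus set
#'
#' Produces the inputs [buildHybridSet()] expects: 9 low-band sources that
#' differ only in blob geometry, 9 high-band sources that differ only in
#' texture carrier/orientation, plus one shared low-band and one shared
#' high-band source distinct from the varying ones. Sources are noiseless
#' and deterministic given the specification object.
#'
#' @param spec a [SynthSpec-class]; only size and calibration are used.
#' @return list with elements \code{lsf_sources} (list of 9 matrices),
#'   \code{hsf_sources} (list of 9), \code{shared_low}, \code{shared_high}.
#' @export
generateHybridSources <- function(spec) {
  validObject(spec)
  N <- spec@image_size_px
  nyq <- N / 2
  amp <- synthAmplitudes()
  blobGeom <- function(k) {
    ang <- 2 * pi * (k - 1) / 10
    renderBlob(N,
               0.5 * N + 0.16 * N * cos(ang),
               0.5 * N + 0.16 * N * sin(ang),
               N * (0.12 + 0.02 * ((k - 1) %% 4)),
               N * (0.12 + 0.02 * ((k + 1) %% 4)),
               3)
  }
  lowImage <- function(k) clip01(amp$bg + 0.5 * blobGeom(k))
  window0 <- renderBlob(N, 0.5 * N, 0.5 * N, 0.18 * N, 0.18 * N, 5)
  highImage <- function(k) {
    carrier <- nyq * (0.66 + 0.18 * ((k - 1) %% 2))
    tex <- renderCarrier(N, carrier, pi * (k - 1) / 10, 0.4 * k)
    clip01(0.5 + 0.3 * tex * window0)
  }
  list(lsf_sources = lapply(1:9, lowImage),
       hsf_sources = lapply(1:9, highImage),
       shared_low = lowImage(10L),
       shared_high = highImage(10L))
}
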