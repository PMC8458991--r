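#' Split a dataset and build per-level pools
#'
#' Splits a [SynthDataset-class] class-balanced into train/validation/test
#' subsets (in stored order within each class) and filters every subset at
#' every level of the bank, producing the pool structure consumed by
#' [trainCurriculum()] and [evaluateAcrossLevels()].
#'
#' @param dataset a [SynthDataset-class].
#' @param n_train,n_val,n_test images per class in each split; must sum to
#'   at most \code{images_per_class}.
#' @param bank data.frame as returned by [sflBank()].
#' @param order_n,visual_angle_deg filter calibration.
#' @return list with elements \code{train}, \code{val}, \code{test}: each a
#'   named list (per level) of pools \code{list(x = array, y = labels)}.
#' @export
makeLevelPools <- function(dataset, n_train, n_val, n_test,
                           bank = sflBank(), order_n = 4L,
                           visual_angle_deg = 60) {
  stopifnot(is(dataset, "SynthDataset"))
  per <- dataset@spec@images_per_class
  if (n_train + n_val + n_test > per)
    stop("splits need ", n_train + n_val + n_test,
         " images per class but the dataset has ", per)
  y <- as.integer(dataset@labels)
  splits <- list(train = integer(), val = integer(), test = integer())
  for (cls in seq_len(dataset@spec@n_classes)) {
    idx <- which(y == cls)
    splits$train <- c(splits$train, idx[seq_len(n_train)])
    splits$val <- c(splits$val, idx[n_train + seq_len(n_val)])
    splits$test <- c(splits$test, idx[n_train + n_val + seq_len(n_test)])
  }
  lapply(splits, function(idx) {
    filtered <- filterLevels(dataset@images[, , idx, drop = FALSE], bank,
                             order_n, visual_angle_deg)
    lapply(filtered, function(x) list(x = x, y = y[idx]))
  })
}

#' Run the scaled-down three-regime curriculum experiment
#'
#' End-to-end desk-scale analogue of the full study: generates one synthetic
#' shape+texture dataset, filters it at all frequency levels, trains the
#' reference small CNN under each requested regime with identical
#' initialization, and evaluates per-level test accuracy. The study
#' conditions default to 64x64 images, 10 classes, 5 stages of 4 epochs and
#' a small-batch SGD setup.
#'
#' @param regimes character vector of regimes to run.
#' @param n_classes,image_size,noise_sd,shape_informativeness,
#'   texture_informativeness passed to [synthSpec()].
#' @param n_train,n_val,n_test images per class per split.
#' @param stage_length epochs per curriculum stage (default 4).
#' @param batch_size,steps_per_epoch,initial_lr,momentum optimizer setup.
#' @param seed master seed: offsets are derived from it for data generation,
#'   model initialization and batch sampling.
#' @param verbose print stage-transition messages (default FALSE).
#' @return list with \code{histories} (per regime), \code{reports} (per
#'   regime [evaluateAcrossLevels()] data.frames), \code{comparison}
#'   (regimes-by-levels test-accuracy data.frame), \code{models}, and the
#'   generating \code{spec}.
#' @export
runExperiment <- function(regimes = c("full", "gradual", "mixed"),
                          n_classes = 10L, image_size = 64L,
                          noise_sd = 0.08, shape_informativeness = 1,
                          texture_informativeness = 1,
                          n_train = 60L, n_val = 12L, n_test = 20L,
                          stage_length = 4L, batch_size = 16L,
                          steps_per_epoch = 120L, initial_lr = 0.03,
                          momentum = 0.9, seed = 1L, verbose = FALSE) {
  spec <- synthSpec(n_classes = n_classes,
                    images_per_class = n_train + n_val + n_test,
                    image_size_px = image_size,
                    shape_informativeness = shape_informativeness,
                    texture_informativeness = texture_informativeness,
                    noise_sd = noise_sd, seed = seed)
  dataset <- generateDataset(spec)
  pools <- makeLevelPools(dataset, n_train, n_val, n_test)
  run_one <- function(regime) {
    schedule <- regimeTable(regime, stage_length = stage_length)
    config <- trainingConfig(batch_size = batch_size,
                             steps_per_epoch = steps_per_epoch,
                             momentum = momentum, initial_lr = initial_lr,
                             seed = seed + 1L)
    model <- smallCNN(image_size, n_classes, seed = seed + 2L)
    fit <- if (verbose)
      trainCurriculum(model, schedule, config,
                      list(train = pools$train, val = pools$val))
    else
      suppressMessages(
        trainCurriculum(model, schedule, config,
                        list(train = pools$train, val = pools$val)))
    report <- evaluateAcrossLevels(fit$model, pools$test,
                                   metadata = list(regime = regime,
                                                   seed = seed))
    list(model = fit$model, history = fit$history, report = report)
  }
  runs <- lapply(stats::setNames(regimes, regimes), run_one)
  comparison <- do.call(rbind, lapply(regimes, function(rg) {
    rep_ <- runs[[rg]]$report
    row <- data.frame(regime = rg, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(rep_))) row[[rep_$level[i]]] <- rep_$accuracy[i]
    row
  }))
  list(histories = lapply(runs, `[[`, "history"),
       reports = lapply(runs, `[[`, "report"),
       comparison = comparison,
       models = lapply(runs, `[[`, "model"),
       spec = spec)
}

#' Hybrid-set RSA for a trained model and the pixel observers
#'
#' Builds the 18-image hybrid set from synthetic sources, computes RDMs for
#' the requested model layers and for the training-free low/high-band pixel
#' observers, and correlates each with the LSF and HSF conceptual models,
#' with permutation p values and bootstrap SDs.
#'
#' @param model optional classifier implementing the model contract; when
#'   NULL only the pixel observers are analyzed.
#' @param spec a [SynthSpec-class] controlling image size/calibration of the
#'   hybrid sources.
#' @param layers model layer tags for [extractActivations()].
#' @param n_perm,n_boot inference replicate counts.
#' @return list with \code{rsa} (data.frame: observer/layer, conceptual
#'   model, rho, p, p_conventional, boot_sd), \code{hybrids} (the stimulus
#'   array) and \code{layout}.
#' @export
hybridRSA <- function(model = NULL, spec = synthSpec(),
                      layers = c("mid_conv", "final_fc"),
                      n_perm = 1e4, n_boot = 1e4) {
  src <- generateHybridSources(spec)
  hs <- buildHybridSet(src$lsf_sources, src$hsf_sources, src$shared_low,
                       src$shared_high)
  models <- list(LSF = conceptualRDM(hs$layout, "LSF"),
                 HSF = conceptualRDM(hs$layout, "HSF"))
  observers <- list(
    observer_low = rdmFromActivations(pixelObserver(hs$images, "low")),
    observer_high = rdmFromActivations(pixelObserver(hs$images, "high")))
  if (!is.null(model)) {
    for (ly in layers)
      observers[[paste0("layer_", ly)]] <-
        rdmFromActivations(extractActivations(model, hs$images, ly))
  }
  rows <- list()
  for (ob in names(observers)) {
    for (cm in names(models)) {
      pt <- permutationTestRDM(observers[[ob]], models[[cm]],
                               n_perm = n_perm)
      bs <- suppressMessages(
        bootstrapSdRDM(observers[[ob]], models[[cm]], n_boot = n_boot))
      rows[[length(rows) + 1L]] <- data.frame(
        source = ob, conceptual_model = cm, rho = pt$rho, p = pt$p,
        p_conventional = pt$p_conventional, boot_sd = bs$sd,
        stringsAsFactors = FALSE)
    }
  }
  list(rsa = do.call(rbind, rows), hybrids = hs$images,
       layout = hs$layout, rdms = observers, conceptual = models)
}
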