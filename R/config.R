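#' Read and validate a run configuration
#'
#' Loads a YAML configuration with sections \code{synth}, \code{filter},
#' \code{train} and \code{rsa} plus global keys \code{seed} and
#' \code{output_root}, filling unset keys from the package defaults.
#'
#' @param path YAML file path, or NULL for the pure defaults.
#' @return Nested named list.
#' @export
readRunConfig <- function(path = NULL) {
  defaults <- list(
    seed = 1L,
    output_root = "runs",
    synth = list(n_classes = 10L, images_per_class = 92L, image_size = 64L,
                 noise_sd = 0.08, shape_informativeness = 1,
                 texture_informativeness = 1),
    filter = list(input_dir = NULL, image_size = 224L,
                  visual_angle_deg = 60, order_n = 4L),
    train = list(regime = "mixed", stage_length = 4L, batch_size = 16L,
                 steps_per_epoch = 120L, initial_lr = 0.03, momentum = 0.9,
                 n_train = 60L, n_val = 12L, n_test = 20L),
    rsa = list(n_perm = 10000L, n_boot = 10000L,
               layers = c("mid_conv", "final_fc")))
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  merge2 <- function(def, usr) {
    for (k in names(usr)) {
      def[[k]] <- if (is.list(usr[[k]]) && is.list(def[[k]]))
        merge2(def[[k]], usr[[k]]) else usr[[k]]
    }
    def
  }
  merge2(defaults, user)
}

## fetch a config key by dotted path, failing loudly when absent
cfgGet <- function(config, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- config
  for (k in keys) {
    if (!is.list(node) || is.null(node[[k]]))
      stop("missing config key: ", path, call. = FALSE)
    node <- node[[k]]
  }
  node
}

## sidecar metadata written next to every command's outputs
writeRunMeta <- function(dir, config, command) {
  cfg_file <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, cfg_file)
  meta <- list(
    run_id = format(Sys.time(), "%Y%m%dT%H%M%S"),
    command = command,
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    package_version = as.character(utils::packageVersion("coarse2fine")))
  jsonlite::write_json(meta, file.path(dir, "run_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(meta)
}

cmdDir <- function(config, command) {
  d <- file.path(cfgGet(config, "output_root"), command)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

synthSpecFromConfig <- function(config) {
  synthSpec(n_classes = cfgGet(config, "synth.n_classes"),
            images_per_class = cfgGet(config, "synth.images_per_class"),
            image_size_px = cfgGet(config, "synth.image_size"),
            shape_informativeness =
              cfgGet(config, "synth.shape_informativeness"),
            texture_informativeness =
              cfgGet(config, "synth.texture_informativeness"),
            noise_sd = cfgGet(config, "synth.noise_sd"),
            seed = cfgGet(config, "seed"))
}

writeImageStack <- function(images, paths) {
  for (i in seq_along(paths))
    EBImage::writeImage(EBImage::Image(images[, , i]), paths[i])
}

#' Pipeline commands
#'
#' Thin command wrappers used by the shipped command-line script
#' (\code{system.file("cli", "c2f.R", package = "coarse2fine")}); each
#' validates its part of the configuration, runs the corresponding package
#' functions, and writes CSV outputs plus a sidecar \code{run_meta.json}
#' (run id, seed, config hash) under \code{output_root/<command>/}.
#'
#' \code{cmdSynth} generates the labeled dataset (PNGs + manifest) and the
#' hybrid stimulus set; \code{cmdFilter} batch-filters an image directory at
#' all bank levels; \code{cmdTrain} trains one regime and writes the history
#' and a model checkpoint; \code{cmdEvaluate} writes the per-level accuracy
#' report for a checkpoint; \code{cmdRsa} writes hybrid-set RDM correlations
#' with permutation and bootstrap inference; \code{cmdExperiment} runs all
#' three regimes on one dataset and writes the comparison table.
#'
#' @param config nested configuration list from [readRunConfig()].
#' @return The main result of each command, invisibly; all artifacts are
#'   written under \code{output_root}.
#' @name pipeline-commands
NULL

#' @rdname pipeline-commands
#' @export
cmdSynth <- function(config) {
  out <- cmdDir(config, "synth")
  spec <- synthSpecFromConfig(config)
  ds <- generateDataset(spec)
  img_dir <- file.path(out, "images")
  dir.create(img_dir, showWarnings = FALSE)
  paths <- file.path(img_dir, paste0(ds@manifest$id, ".png"))
  writeImageStack(ds@images, paths)
  manifest <- cbind(ds@manifest, path = paths)
  utils::write.csv(manifest, file.path(out, "manifest.csv"),
                   row.names = FALSE)
  src <- generateHybridSources(spec)
  hs <- buildHybridSet(src$lsf_sources, src$hsf_sources, src$shared_low,
                       src$shared_high)
  hyb_dir <- file.path(out, "hybrids")
  dir.create(hyb_dir, showWarnings = FALSE)
  writeImageStack(hs$images, file.path(hyb_dir, sprintf("hyb%02d.png", 1:18)))
  utils::write.csv(layoutManifest(hs$layout),
                   file.path(out, "hybrid_layout.csv"), row.names = FALSE)
  writeRunMeta(out, config, "synth")
  invisible(manifest)
}

#' @rdname pipeline-commands
#' @export
cmdFilter <- function(config) {
  out <- cmdDir(config, "filter")
  manifest <- filterDataset(cfgGet(config, "filter.input_dir"), out,
                            image_size = cfgGet(config, "filter.image_size"),
                            order_n = cfgGet(config, "filter.order_n"),
                            visual_angle_deg =
                              cfgGet(config, "filter.visual_angle_deg"))
  writeRunMeta(out, config, "filter")
  invisible(manifest)
}

experimentArgs <- function(config, regimes) {
  list(regimes = regimes,
       n_classes = cfgGet(config, "synth.n_classes"),
       image_size = cfgGet(config, "synth.image_size"),
       noise_sd = cfgGet(config, "synth.noise_sd"),
       shape_informativeness = cfgGet(config, "synth.shape_informativeness"),
       texture_informativeness =
         cfgGet(config, "synth.texture_informativeness"),
       n_train = cfgGet(config, "train.n_train"),
       n_val = cfgGet(config, "train.n_val"),
       n_test = cfgGet(config, "train.n_test"),
       stage_length = cfgGet(config, "train.stage_length"),
       batch_size = cfgGet(config, "train.batch_size"),
       steps_per_epoch = cfgGet(config, "train.steps_per_epoch"),
       initial_lr = cfgGet(config, "train.initial_lr"),
       momentum = cfgGet(config, "train.momentum"),
       seed = cfgGet(config, "seed"))
}

#' @rdname pipeline-commands
#' @export
cmdTrain <- function(config) {
  out <- cmdDir(config, "train")
  regime <- cfgGet(config, "train.regime")
  res <- do.call(runExperiment, experimentArgs(config, regime))
  utils::write.csv(res$histories[[regime]],
                   file.path(out, paste0("history_", regime, ".csv")),
                   row.names = FALSE)
  saveRDS(res$models[[regime]],
          file.path(out, paste0("model_", regime, ".rds")))
  writeRunMeta(out, config, "train")
  invisible(res)
}

#' @rdname pipeline-commands
#' @export
cmdEvaluate <- function(config) {
  out <- cmdDir(config, "evaluate")
  regime <- cfgGet(config, "train.regime")
  ckpt <- file.path(cfgGet(config, "output_root"), "train",
                    paste0("model_", regime, ".rds"))
  if (!file.exists(ckpt))
    stop("no checkpoint at ", ckpt, "; run the train command first")
  model <- readRDS(ckpt)
  spec <- synthSpecFromConfig(config)
  ds <- generateDataset(spec)
  pools <- makeLevelPools(ds, cfgGet(config, "train.n_train"),
                          cfgGet(config, "train.n_val"),
                          cfgGet(config, "train.n_test"))
  report <- evaluateAcrossLevels(model, pools$test,
                                 metadata = list(regime = regime,
                                                 seed = config$seed))
  utils::write.csv(report, file.path(out, paste0("eval_", regime, ".csv")),
                   row.names = FALSE)
  writeRunMeta(out, config, "evaluate")
  invisible(report)
}

#' @rdname pipeline-commands
#' @export
cmdRsa <- function(config) {
  out <- cmdDir(config, "rsa")
  regime <- cfgGet(config, "train.regime")
  ckpt <- file.path(cfgGet(config, "output_root"), "train",
                    paste0("model_", regime, ".rds"))
  model <- if (file.exists(ckpt)) readRDS(ckpt) else NULL
  res <- hybridRSA(model, synthSpecFromConfig(config),
                   layers = cfgGet(config, "rsa.layers"),
                   n_perm = cfgGet(config, "rsa.n_perm"),
                   n_boot = cfgGet(config, "rsa.n_boot"))
  utils::write.csv(res$rsa, file.path(out, "rsa.csv"), row.names = FALSE)
  for (nm in names(res$rdms))
    utils::write.csv(rdmValues(res$rdms[[nm]]),
                     file.path(out, paste0("rdm_", nm, ".csv")))
  writeRunMeta(out, config, "rsa")
  invisible(res$rsa)
}

#' @rdname pipeline-commands
#' @export
cmdExperiment <- function(config) {
  out <- cmdDir(config, "experiment")
  res <- do.call(runExperiment,
                 experimentArgs(config, c("full", "gradual", "mixed")))
  utils::write.csv(res$comparison, file.path(out, "comparison.csv"),
                   row.names = FALSE)
  for (rg in names(res$histories))
    utils::write.csv(res$histories[[rg]],
                     file.path(out, paste0("history_", rg, ".csv")),
                     row.names = FALSE)
  writeRunMeta(out, config, "experiment")
  invisible(res)
}
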