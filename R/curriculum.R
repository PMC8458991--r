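levelNames <- function() c("SFL1", "SFL2", "SFL3", "SFL4", "UF")

stageVec <- function(...) {
  v <- stats::setNames(numeric(5), levelNames())
  args <- list(...)
  if (length(args)) v[names(args)] <- unlist(args)
  v
}

#' Canonical curriculum training regimes
#'
#' Returns the named five-stage schedule over frequency levels:
#' \describe{
#'   \item{full}{unfiltered images only, every stage (the standard training
#'     baseline).}
#'   \item{gradual}{one level per stage, SFL1 through SFL4 then UF; each
#'     switch discards the previous level entirely.}
#'   \item{mixed}{each switch halves the running mixture and gives the new
#'     level the other half, so earlier (lower-frequency) levels are
#'     retained throughout: stage 4 is exact sixths
#'     \eqn{1/6, 1/6, 1/6, 1/2} and stage 5 eighths
#'     \eqn{1/8, 1/8, 1/8, 1/8, 1/2}.}
#' }
#' Stage proportions always sum to exactly 1. The reference stage length is
#' 100 epochs; the fifth stage extends to \code{total_epochs}.
#'
#' @param name \code{"full"}, \code{"gradual"} or \code{"mixed"}.
#' @param stage_length epochs per stage (default 100).
#' @param total_epochs total training epochs (default
#'   \code{5 * stage_length}).
#' @return A [RegimeSchedule-class].
#' @examples
#' regimeTable("mixed")
#' @export
regimeTable <- function(name = c("full", "gradual", "mixed"),
                        stage_length = 100L,
                        total_epochs = 5L * stage_length) {
  name <- match.arg(name)
  stages <- switch(name,
    full = replicate(5, stageVec(UF = 1), simplify = FALSE),
    gradual = lapply(levelNames(), function(lv) {
      v <- stageVec()
      v[lv] <- 1
      v
    }),
    mixed = list(
      stageVec(SFL1 = 1),
      stageVec(SFL1 = 1/2, SFL2 = 1/2),
      stageVec(SFL1 = 1/4, SFL2 = 1/4, SFL3 = 1/2),
      stageVec(SFL1 = 1/6, SFL2 = 1/6, SFL3 = 1/6, SFL4 = 1/2),
      stageVec(SFL1 = 1/8, SFL2 = 1/8, SFL3 = 1/8, SFL4 = 1/8, UF = 1/2)))
  new("RegimeSchedule", name = name, stages = stages,
      stage_length = as.integer(stage_length),
      total_epochs = as.integer(total_epochs))
}

#' Mixing proportions in force at a given epoch
#'
#' Stage \eqn{k} covers epochs \eqn{(k-1)L+1, \dots, kL} for \eqn{k \le 4};
#' the fifth stage extends to \code{total_epochs}.
#'
#' @param schedule a [RegimeSchedule-class].
#' @param epoch epoch number in \code{1..total_epochs}.
#' @return Named numeric vector of proportions over \code{SFL1..SFL4, UF}.
#' @export
proportionsAt <- function(schedule, epoch) {
  stopifnot(is(schedule, "RegimeSchedule"))
  if (epoch < 1L || epoch > schedule@total_epochs)
    stop("epoch ", epoch, " outside 1..", schedule@total_epochs)
  stage <- min(5L, (as.integer(epoch) - 1L) %/% schedule@stage_length + 1L)
  schedule@stages[[stage]]
}

#' Learning rate in force at a given epoch
#'
#' Piecewise-constant schedule: the initial rate up to 80\% of the total
#' epochs, one fifth of it up to 90\%, and one fiftieth thereafter. At the
#' reference scale (500 epochs, initial rate 0.5) this is 0.5 for epochs
#' 1-400, 0.1 for 401-450 and 0.01 for 451-500; at other scales the
#' breakpoints keep the same fractional positions.
#'
#' @param schedule a [RegimeSchedule-class] (supplies \code{total_epochs}).
#' @param epoch epoch number in \code{1..total_epochs}.
#' @param initial_lr initial learning rate (default 0.5).
#' @return numeric(1), the learning rate.
#' @export
lrAt <- function(schedule, epoch, initial_lr = 0.5) {
  stopifnot(is(schedule, "RegimeSchedule"))
  if (epoch < 1L || epoch > schedule@total_epochs)
    stop("epoch ", epoch, " outside 1..", schedule@total_epochs)
  b1 <- round(0.8 * schedule@total_epochs)
  b2 <- round(0.9 * schedule@total_epochs)
  if (epoch <= b1) initial_lr
  else if (epoch <= b2) initial_lr / 5
  else initial_lr / 50
}

#' Optimizer and run-size configuration
#'
#' @param batch_size mini-batch size (default 192).
#' @param steps_per_epoch gradient steps per epoch (default 100).
#' @param momentum Nesterov momentum coefficient (default 0.9).
#' @param initial_lr initial learning rate (default 0.5).
#' @param seed integer seed for sampling and initialization.
#' @return A [TrainingConfig-class].
#' @export
trainingConfig <- function(batch_size = 192L, steps_per_epoch = 100L,
                           momentum = 0.9, initial_lr = 0.5, seed = 1L) {
  new("TrainingConfig", batch_size = as.integer(batch_size),
      steps_per_epoch = as.integer(steps_per_epoch),
      momentum = as.numeric(momentum), initial_lr = as.numeric(initial_lr),
      seed = as.integer(seed))
}

#' Largest-remainder apportionment of a batch over levels
#'
#' Splits \code{batch_size} items over the levels proportionally: each level
#' receives the floor of its exact share, and the remaining items go to the
#' levels with the largest fractional parts (ties broken by level order), so
#' the counts are deterministic and sum exactly to \code{batch_size}.
#'
#' @param proportions named non-negative vector summing to 1.
#' @param batch_size number of items to apportion.
#' @return Named integer vector of per-level counts.
#' @export
apportionBatch <- function(proportions, batch_size) {
  if (abs(sum(proportions) - 1) > 1e-9 || any(proportions < 0))
    stop("proportions must be non-negative and sum to 1")
  exact <- proportions * batch_size
  counts <- floor(exact)
  rem <- batch_size - sum(counts)
  if (rem > 0) {
    frac <- exact - counts
    give <- order(-frac, seq_along(frac))[seq_len(rem)]
    counts[give] <- counts[give] + 1L
  }
  stats::setNames(as.integer(counts), names(proportions))
}

## sampling state for without-replacement draws within an epoch-level pass:
## per level, a shuffled ordering consumed by a cursor, reshuffled on
## exhaustion
newPoolState <- function(pool_sizes) {
  st <- new.env(parent = emptyenv())
  st$order <- lapply(pool_sizes, sample.int)
  st$cursor <- lapply(pool_sizes, function(n) 0L)
  st$sizes <- pool_sizes
  st
}

drawFromPool <- function(state, level, k) {
  n <- state$sizes[[level]]
  out <- integer(0)
  while (k > 0L) {
    cur <- state$cursor[[level]]
    if (cur >= n) {
      state$order[[level]] <- sample.int(n)
      state$cursor[[level]] <- 0L
      cur <- 0L
    }
    take <- min(k, n - cur)
    out <- c(out, state$order[[level]][(cur + 1L):(cur + take)])
    state$cursor[[level]] <- cur + take
    k <- k - take
  }
  out
}

#' Compose one labeled mini-batch from per-level pools
#'
#' Per-level counts follow [apportionBatch()]; items are drawn uniformly
#' without replacement within an epoch-level pass from the current RNG
#' stream (reshuffling a level's pool when it is exhausted).
#'
#' @param pools named list of per-level pools, each a list with elements
#'   \code{x} (\code{H x W x n} array) and \code{y} (integer labels).
#' @param proportions named proportions over the pool names, summing to 1.
#' @param batch_size items in the batch.
#' @param state internal sampling state from a previous call, or NULL to
#'   start a fresh pass.
#' @return list with \code{x} (\code{H x W x batch_size} array), \code{y}
#'   (integer labels), \code{counts} (per-level counts) and \code{state}
#'   (to thread into the next call).
#' @export
composeBatch <- function(pools, proportions, batch_size, state = NULL) {
  active <- names(proportions)[proportions > 0]
  missing_pool <- setdiff(active, names(pools))
  for (lv in active) {
    if (lv %in% missing_pool || is.null(pools[[lv]]) ||
        dim(pools[[lv]]$x)[3] == 0L)
      stop("level '", lv, "' has proportion ", proportions[[lv]],
           " but an empty or missing pool")
  }
  if (is.null(state))
    state <- newPoolState(lapply(pools, function(p) dim(p$x)[3]))
  counts <- apportionBatch(proportions, batch_size)
  N <- dim(pools[[active[1]]]$x)[1]
  x <- array(0, dim = c(N, N, batch_size))
  y <- integer(batch_size)
  at <- 0L
  for (lv in names(counts)) {
    k <- counts[[lv]]
    if (k == 0L) next
    idx <- drawFromPool(state, lv, k)
    x[, , (at + 1L):(at + k)] <- pools[[lv]]$x[, , idx, drop = FALSE]
    y[(at + 1L):(at + k)] <- pools[[lv]]$y[idx]
    at <- at + k
  }
  list(x = x, y = y, counts = counts, state = state)
}

## accuracy of a model on one pool, computed in chunks
poolAccuracy <- function(model, pool, chunk = 128L) {
  n <- dim(pool$x)[3]
  if (n == 0L) return(NA_real_)
  correct <- 0L
  for (start in seq(1L, n, by = chunk)) {
    end <- min(n, start + chunk - 1L)
    scores <- modelPredict(model, pool$x[, , start:end, drop = FALSE])
    correct <- correct + sum(max.col(scores, ties.method = "first") ==
                               pool$y[start:end])
  }
  correct / n
}

#' Train a classifier under a spatial-frequency curriculum
#'
#' Runs \code{total_epochs * steps_per_epoch} mini-batch updates, switching
#' the per-level mixing proportions and the learning rate according to the
#' schedule. After every epoch, validation accuracy is measured on each
#' level's validation pool (images filtered at that same level) and training
#' accuracy is the mean over the epoch's own mini-batches. The run is
#' deterministic given \code{config@seed}.
#'
#' @param model a classifier implementing the model contract
#'   (see [model-contract]); typically a [SmallCNN-class].
#' @param schedule a [RegimeSchedule-class].
#' @param config a [TrainingConfig-class].
#' @param data list with elements \code{train} and \code{val}, each a named
#'   list of per-level pools (\code{list(x = array, y = labels)}) covering
#'   every level the schedule uses.
#' @param eval_hook optional \code{function(epoch, model, row)} called after
#'   each epoch's evaluation.
#' @return list with \code{model} (trained) and \code{history} (data.frame
#'   with one row per epoch: \code{epoch}, \code{stage}, \code{lr},
#'   \code{loss}, \code{train_acc} and one validation-accuracy column per
#'   level).
#' @export
trainCurriculum <- function(model, schedule, config, data,
                            eval_hook = NULL) {
  stopifnot(is(schedule, "RegimeSchedule"), is(config, "TrainingConfig"))
  validObject(schedule); validObject(config)
  lv <- levelNames()
  hist_rows <- vector("list", schedule@total_epochs)
  if (schedule@total_epochs == 0L)
    return(list(model = model, history = data.frame()))
  withSeed(config@seed, {
    state <- NULL
    last_stage <- 0L
    for (epoch in seq_len(schedule@total_epochs)) {
      props <- proportionsAt(schedule, epoch)
      lr <- lrAt(schedule, epoch, config@initial_lr)
      stage <- min(5L, (epoch - 1L) %/% schedule@stage_length + 1L)
      if (stage != last_stage) {
        message(sprintf(
          "[%s] epoch %d: entering stage %d (lr %.3g, mix %s)",
          schedule@name, epoch, stage, lr,
          paste(sprintf("%s=%.3g", names(props)[props > 0],
                        props[props > 0]), collapse = " ")))
        last_stage <- stage
      }
      losses <- accs <- numeric(config@steps_per_epoch)
      for (step in seq_len(config@steps_per_epoch)) {
        b <- composeBatch(data$train, props, config@batch_size, state)
        state <- b$state
        upd <- modelUpdate(model, b$x, b$y, lr, config@momentum)
        if (!is.finite(upd$loss))
          stop(sprintf("non-finite loss at epoch %d step %d", epoch, step))
        model <- upd$model
        losses[step] <- upd$loss
        accs[step] <- upd$accuracy
      }
      val_acc <- vapply(lv, function(l) {
        if (is.null(data$val[[l]])) NA_real_
        else poolAccuracy(model, data$val[[l]])
      }, numeric(1))
      row <- data.frame(epoch = epoch, stage = stage, lr = lr,
                        loss = mean(losses), train_acc = mean(accs))
      for (l in lv) row[[paste0("val_", l)]] <- val_acc[[l]]
      hist_rows[[epoch]] <- row
      if (!is.null(eval_hook)) eval_hook(epoch, model, row)
    }
  })
  list(model = model, history = do.call(rbind, hist_rows))
}
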