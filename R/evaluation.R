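#' Top-1 accuracy
#'
#' Fraction of items whose highest-scoring class equals the label; argmax
#' ties are broken deterministically by the lowest class index.
#'
#' @param scores numeric items-by-classes score matrix.
#' @param labels integer class indices (or factor), one per item.
#' @return numeric(1) in \code{[0, 1]}.
#' @export
top1Accuracy <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.integer(labels)
  if (nrow(scores) != length(labels))
    stop("scores has ", nrow(scores), " rows but ", length(labels),
         " labels were given")
  if (ncol(scores) < 1L) stop("scores must have at least one class column")
  mean(max.col(scores, ties.method = "first") == labels)
}

#' Top-1 accuracy restricted to a class subset
#'
#' Mirrors the restricted n-way readout: scores over the full class set are
#' first restricted to \code{allowed_classes}, and an item is correct when
#' its true class attains the highest score within that subset (even if some
#' disallowed class scores higher globally).
#'
#' @param scores numeric items-by-classes score matrix over the full class
#'   set.
#' @param allowed_classes integer indices of the candidate classes.
#' @param labels integer class indices; must all lie in
#'   \code{allowed_classes}.
#' @return numeric(1) in \code{[0, 1]}.
#' @export
restrictedTop1 <- function(scores, allowed_classes, labels) {
  scores <- as.matrix(scores)
  labels <- as.integer(labels)
  allowed_classes <- as.integer(allowed_classes)
  if (any(allowed_classes < 1L) || any(allowed_classes > ncol(scores)))
    stop("allowed_classes outside the score matrix columns")
  if (!all(labels %in% allowed_classes))
    stop("labels occur outside allowed_classes: ",
         paste(unique(setdiff(labels, allowed_classes)), collapse = ", "))
  sub <- scores[, allowed_classes, drop = FALSE]
  pick <- allowed_classes[max.col(sub, ties.method = "first")]
  mean(pick == labels)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return numeric(2), \code{c(low, high)}; always brackets \code{k/n},
#'   with \code{low >= 0} and \code{high <= 1}.
#' @export
binomialCI <- function(k, n, level = 0.95) {
  if (n < 1L || k < 0L || k > n)
    stop("need 0 <= k <= n with n >= 1, got k=", k, ", n=", n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, center - half), high = min(1, center + half))
}

#' Select categories with accuracy consistent with the mean
#'
#' Keeps the classes whose accuracy lies within \code{tolerance} of the mean
#' accuracy, read as absolute percentage points (a class at 0.80 is excluded
#' when the mean is 0.60 and the tolerance 0.15). If more than \code{k}
#' classes qualify, the \code{k} closest to the mean are returned (ties by
#' class index); fewer than \code{k} qualifying classes is an error.
#'
#' @param per_class_accuracy numeric vector of accuracies in \code{[0, 1]},
#'   optionally named.
#' @param k number of categories to select (default 10).
#' @param tolerance absolute deviation band around the mean (default 0.15).
#' @return Indices (or names, when given) of the selected classes, in class
#'   order.
#' @export
selectConsistentCategories <- function(per_class_accuracy, k = 10L,
                                       tolerance = 0.15) {
  a <- per_class_accuracy
  if (any(a < 0) || any(a > 1))
    stop("per-class accuracies must lie in [0, 1]")
  dev <- abs(a - mean(a))
  qual <- which(dev <= tolerance + 1e-12)
  if (length(qual) < k)
    stop("only ", length(qual), " classes lie within ", tolerance,
         " of the mean accuracy; ", k, " are required")
  keep <- qual[order(dev[qual], qual)][seq_len(k)]
  keep <- sort(keep)
  if (!is.null(names(a))) names(a)[keep] else keep
}

#' Per-level accuracy report with binomial confidence intervals
#'
#' Evaluates a model on every frequency level's test pool(s) and reports
#' counts, accuracy and the Wilson confidence interval per level and split.
#'
#' @param model a classifier implementing [modelPredict()].
#' @param pools named list: one pool (\code{list(x = array, y = labels)}) per
#'   level, or one named list of split pools per level.
#' @param level confidence level for the intervals (default 0.95).
#' @param metadata optional named list recorded as attributes (regime, seed,
#'   model id, ...).
#' @return data.frame with columns \code{level}, \code{split},
#'   \code{n_correct}, \code{n_total}, \code{accuracy}, \code{ci_low},
#'   \code{ci_high}; empty pools yield a warning and an NA row.
#' @export
evaluateAcrossLevels <- function(model, pools, level = 0.95,
                                 metadata = list()) {
  rows <- list()
  for (lv in names(pools)) {
    p <- pools[[lv]]
    splits <- if (!is.null(p$x)) list(test = p) else p
    for (sp in names(splits)) {
      pool <- splits[[sp]]
      n <- if (is.null(pool$x)) 0L else dim(pool$x)[3]
      if (n == 0L) {
        warning("empty pool for level ", lv, " split ", sp, "; skipped")
        rows[[length(rows) + 1L]] <- data.frame(
          level = lv, split = sp, n_correct = NA_integer_,
          n_total = 0L, accuracy = NA_real_, ci_low = NA_real_,
          ci_high = NA_real_, stringsAsFactors = FALSE)
        next
      }
      correct <- 0L
      for (start in seq(1L, n, by = 128L)) {
        end <- min(n, start + 127L)
        scores <- modelPredict(model, pool$x[, , start:end, drop = FALSE])
        correct <- correct +
          sum(max.col(scores, ties.method = "first") == pool$y[start:end])
      }
      ci <- binomialCI(correct, n, level)
      rows[[length(rows) + 1L]] <- data.frame(
        level = lv, split = sp, n_correct = correct, n_total = n,
        accuracy = correct / n, ci_low = ci[["low"]],
        ci_high = ci[["high"]], stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  for (nm in names(metadata)) attr(report, nm) <- metadata[[nm]]
  report
}
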