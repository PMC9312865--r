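#' @include model.R
NULL

#' Root-mean-square error
#'
#' @param pred,ref equal-length numeric vectors, kcal/mol.
#' @return RMSE, kcal/mol.
#' @export
rmse <- function(pred, ref) {
  if (length(pred) != length(ref) || length(pred) == 0)
    stop("pred and ref must have equal, non-zero length")
  sqrt(mean((pred - ref)^2))
}

#' Shuffled train/test split at a fixed ratio
#'
#' `ratio = 3` gives the 3:1 split (a 368-item dataset yields 276 training
#' and 92 held-out items). Disjoint, exhaustive, seed-reproducible.
#'
#' @param dataset list of items.
#' @param ratio train:test ratio (train gets `ratio/(ratio+1)` of items).
#' @param seed integer seed.
#' @return list with elements `train` and `test`.
#' @export
splitTrainTest <- function(dataset, ratio = 3, seed = 1L) {
  n <- length(dataset)
  if (n < 4) stop("dataset must have at least 4 items")
  nTrain <- round(n * ratio / (ratio + 1))
  idx <- .withSeed(seed, sample.int(n))
  list(train = dataset[idx[seq_len(nTrain)]],
       test = dataset[idx[(nTrain + 1):n]])
}

# seed-reproducible fold ids, sizes differing by at most one
.foldIds <- function(n, k, seed) {
  ids <- rep(seq_len(k), length.out = n)
  .withSeed(seed, sample(ids))
}

#' k-fold cross-validation
#'
#' Trains on k-1 folds and validates on the held-out fold, k times; every
#' item is validated exactly once. Reports per-fold train/validation RMSE,
#' their mean and standard deviation (sd across folds), and the full
#' per-epoch loss curves.
#'
#' @param dataset list of labeled items (see [trainPGNN()]).
#' @param config from [pgnnConfig()].
#' @param k number of folds (default 4).
#' @param usePhysics `FALSE` for the graph-only ablation.
#' @return list with `k`, `folds` (fold id per item), `perFold`
#'   (data.frame: fold, trainRMSE, valRMSE), `meanTrainRMSE`, `sdTrainRMSE`,
#'   `meanValRMSE`, `sdValRMSE`, and `lossCurves` (data.frame: fold, epoch,
#'   trainLoss, valLoss).
#' @export
crossValidate <- function(dataset, config = pgnnConfig(), k = 4L,
                          usePhysics = TRUE) {
  n <- length(dataset)
  if (k < 2) stop("k must be at least 2")
  if (n < k) stop("dataset smaller than the number of folds")
  folds <- .foldIds(n, k, config$seed)
  perFold <- data.frame()
  curves <- data.frame()
  for (f in seq_len(k)) {
    hold <- which(folds == f)
    fit <- trainPGNN(dataset[-hold], config, valData = dataset[hold],
                     usePhysics = usePhysics)
    trPred <- predictDdg(fit, dataset[-hold])
    vaPred <- predictDdg(fit, dataset[hold])
    trY <- vapply(dataset[-hold], `[[`, numeric(1), "ddg")
    vaY <- vapply(dataset[hold], `[[`, numeric(1), "ddg")
    perFold <- rbind(perFold, data.frame(
      fold = f, trainRMSE = rmse(trPred, trY), valRMSE = rmse(vaPred, vaY)))
    curves <- rbind(curves, cbind(fold = f, fit@trainingLog))
  }
  list(k = k, folds = folds, perFold = perFold,
       meanTrainRMSE = mean(perFold$trainRMSE),
       sdTrainRMSE = stats::sd(perFold$trainRMSE),
       meanValRMSE = mean(perFold$valRMSE),
       sdValRMSE = stats::sd(perFold$valRMSE),
       lossCurves = curves)
}

#' Noise specification for the entropy feature
#'
#' The literal robustness protocol draws noise from
#' \eqn{N(\mu, \sigma^2)} where \eqn{\mu} and \eqn{\sigma} are the mean and
#' standard deviation of the entropy feature over the dataset (a biased
#' noise). `centered = TRUE` gives the conventional zero-mean variant.
#'
#' @param dataset list of labeled items.
#' @param seed integer seed for the draws.
#' @param centered use mu = 0 instead of the dataset mean.
#' @param scale multiplier on sigma (default 1).
#' @return list with `mu`, `sigma`, `seed`.
#' @export
noiseSpec <- function(dataset, seed = 1L, centered = FALSE, scale = 1) {
  ent <- vapply(dataset, function(it) it$P[["entropy"]], numeric(1))
  list(mu = if (centered) 0 else mean(ent),
       sigma = scale * stats::sd(ent), seed = as.integer(seed))
}

#' Add Gaussian noise to the entropy feature
#'
#' Independent draws from \eqn{N(\mu, \sigma^2)} are added to each item's
#' entropy entry; the other 15 physics features and the labels are
#' untouched. The input dataset is not modified. `sigma = 0, mu = 0` is the
#' identity.
#'
#' @param dataset list of labeled items.
#' @param spec list with `mu`, `sigma`, `seed` (see [noiseSpec()]).
#' @return a new dataset list.
#' @export
injectEntropyNoise <- function(dataset, spec) {
  if (spec$sigma < 0) stop("sigma must be non-negative")
  noise <- .withSeed(spec$seed,
                     stats::rnorm(length(dataset), spec$mu, spec$sigma))
  mapply(function(it, eps) {
    it$P[["entropy"]] <- it$P[["entropy"]] + eps
    it
  }, dataset, noise, SIMPLIFY = FALSE)
}

#' Entropy-noise robustness experiment
#'
#' Trains and tests on the original dataset and on a variant with Gaussian
#' noise injected into the entropy feature, using identical seeds and the
#' identical train/test partition, and reports the RMSE change for the
#' training and test sets separately.
#'
#' @param dataset list of labeled items.
#' @param config from [pgnnConfig()].
#' @param spec noise specification (default: the literal protocol via
#'   [noiseSpec()] with the training seed).
#' @param ratio train:test ratio (default 3).
#' @return data.frame with columns `set`, `rmseClean`, `rmseNoisy`,
#'   `deltaRMSE`.
#' @export
robustnessExperiment <- function(dataset, config = pgnnConfig(),
                                 spec = NULL, ratio = 3) {
  if (is.null(spec)) spec <- noiseSpec(dataset, seed = config$seed)
  noisy <- injectEntropyNoise(dataset, spec)
  sp <- splitTrainTest(dataset, ratio = ratio, seed = config$seed)
  spN <- splitTrainTest(noisy, ratio = ratio, seed = config$seed)
  evalOne <- function(split) {
    fit <- trainPGNN(split$train, config)
    trY <- vapply(split$train, `[[`, numeric(1), "ddg")
    teY <- vapply(split$test, `[[`, numeric(1), "ddg")
    c(train = rmse(predictDdg(fit, split$train), trY),
      test = rmse(predictDdg(fit, split$test), teY))
  }
  clean <- evalOne(sp)
  noisyR <- evalOne(spN)
  data.frame(set = c("train", "test"),
             rmseClean = as.numeric(clean),
             rmseNoisy = as.numeric(noisyR),
             deltaRMSE = as.numeric(noisyR - clean))
}

#' Correlation matrix of the physics features
#'
#' Pairwise Pearson (or Spearman) correlations of the physics features
#' across the dataset: either the 16-element vectors (`which = "all"`) or
#' only the complex-structure terms (`which = "complex"`). Zero-variance
#' features give `NA` entries (flagged undefined) rather than propagating
#' NaN; the diagonal is exactly 1.
#'
#' @param dataset list of labeled items (>= 3).
#' @param which `"all"` (16 x 16) or `"complex"` (5 x 5 + entropy).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
featureCorrelation <- function(dataset, which = c("all", "complex"),
                               method = c("pearson", "spearman")) {
  which <- match.arg(which)
  method <- match.arg(method)
  if (length(dataset) < 3) stop("need at least 3 items")
  P <- do.call(rbind, lapply(dataset, `[[`, "P"))
  colnames(P) <- physicsFeatureNames()
  if (which == "complex")
    P <- P[, c(grep("\\.complex$", colnames(P), value = TRUE), "entropy")]
  sds <- apply(P, 2, stats::sd)
  out <- matrix(NA_real_, ncol(P), ncol(P),
                dimnames = list(colnames(P), colnames(P)))
  ok <- sds > 0
  if (any(ok))
    out[ok, ok] <- stats::cor(P[, ok, drop = FALSE], method = method)
  diag(out) <- 1
  out
}

#' Render a feature-correlation heatmap
#'
#' Uses \pkg{pheatmap} when available, else base graphics. `NA` entries
#' (undefined correlations) are shown blank.
#'
#' @param mat matrix from [featureCorrelation()].
#' @param file optional PNG path; plots to the active device if `NULL`.
#' @return `file` (or `NULL`), invisibly.
#' @export
plotFeatureCorrelation <- function(mat, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 800)
    on.exit(grDevices::dev.off())
  }
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(mat, cluster_rows = FALSE, cluster_cols = FALSE,
                       display_numbers = TRUE, na_col = "white")
  } else {
    graphics::image(seq_len(ncol(mat)), seq_len(nrow(mat)), t(mat[rev(seq_len(nrow(mat))), ]),
                    axes = FALSE, xlab = "", ylab = "", zlim = c(-1, 1))
    graphics::axis(1, seq_len(ncol(mat)), colnames(mat), las = 2, cex.axis = 0.7)
    graphics::axis(2, seq_len(nrow(mat)), rev(rownames(mat)), las = 2, cex.axis = 0.7)
  }
  invisible(file)
}

#' Coefficient comparison before vs after training
#'
#' Side-by-side table of the interpretable final-layer coefficients of two
#' models sharing a configuration, with the maximum absolute drift over all
#' 17 coefficients and the model-variable coefficient reported separately.
#'
#' @param modelBefore,modelAfter [PGNNModel-class] objects.
#' @return list with `table` (before/after columns), `maxDrift`, and
#'   `modelVariable` (named vector: before, after).
#' @export
interpretabilityReport <- function(modelBefore, modelAfter) {
  before <- modelBefore@weights$headW
  after <- modelAfter@weights$headW
  tb <- headCoefficients(modelBefore)
  ta <- headCoefficients(modelAfter)
  tab <- merge(tb, ta, by = "parameter", suffixes = c(".before", ".after"),
               sort = FALSE)
  list(table = tab,
       maxDrift = max(abs(after - before)),
       modelVariable = c(before = unname(before["modelVariable"]),
                         after = unname(after["modelVariable"])))
}
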