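#' Random-forest-style regression ensemble
#'
#' Bootstrap-aggregated regression trees with per-split feature subsampling,
#' used as the default PlayerLoad regressor behind [fit_load_model()]. The
#' ensemble is deliberately plain — variance-reduction splits, no pruning —
#' because the load model only has to interpolate seven locomotor metrics.
#'
#' @param x Numeric matrix of predictors (one row per session).
#' @param y Numeric response (PlayerLoad, arbitrary units).
#' @param ntree Number of trees.
#' @param mtry Features considered at each split; default `floor(p/3)`,
#'   at least 1.
#' @param min_node Minimum observations in a terminal node.
#' @param max_depth Maximum tree depth.
#' @param seed Integer seed for the ensemble's own RNG stream (independent of
#'   R's global RNG).
#' @return An object of class `pl_forest`.
#' @examples
#' x <- matrix(runif(200), ncol = 2)
#' f <- pl_forest(x, x[, 1] + x[, 2], ntree = 25, seed = 1)
#' head(predict(f, x))
#' @export
pl_forest <- function(x, y, ntree = 200, mtry = max(1L, floor(ncol(x) / 3)),
                      min_node = 5L, max_depth = 25L, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  stopifnot(nrow(x) == length(y), ntree >= 1, min_node >= 1)
  if (anyNA(x) || anyNA(y)) stop("NA values in training data")
  trees <- rf_fit_cpp(x, as.numeric(y), as.integer(ntree), as.integer(mtry),
                      as.integer(min_node), as.integer(max_depth),
                      as.integer(seed))
  structure(list(trees = trees, features = colnames(x), ntree = ntree,
                 mtry = mtry, min_node = min_node, seed = seed),
            class = "pl_forest")
}

#' @param object,newdata A `pl_forest` and a matrix/data frame with the
#'   training columns.
#' @param ... Unused.
#' @rdname pl_forest
#' @export
predict.pl_forest <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    if (!is.null(object$features)) newdata <- newdata[object$features]
    newdata <- as.matrix(newdata)
  }
  storage.mode(newdata) <- "double"
  rf_predict_cpp(object$trees, newdata)
}

#' @export
#' @method print pl_forest
print.pl_forest <- function(x, ...) {
  cat("Random-forest-style regression ensemble\n")
  cat(sprintf("  trees: %d   mtry: %d   min node: %d\n",
              x$ntree, x$mtry, x$min_node))
  if (!is.null(x$features))
    cat("  features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}
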