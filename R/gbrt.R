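# Gradient boosted regression trees: squared loss, depth-limited CART base
# learners with variance-reduction splits, shrinkage, no subsampling — fully
# deterministic given the data and configuration.

# Best variance-reduction split over all features at once. Rows of the node
# are visited in pre-sorted order per feature (`ord_mat` is computed once per
# training matrix), so each node costs one vectorised pass instead of a sort
# per feature. Returns NULL when no split improves on the parent.
best_split_node <- function(X, y, idx, ord_mat, min_leaf) {
  n <- length(idx)
  p <- ncol(X)
  N <- nrow(X)
  inn <- logical(N); inn[idx] <- TRUE
  m <- matrix(ord_mat[inn[ord_mat]], n, p)  # node rows, sorted per feature
  lin <- as.vector(m) + rep.int((seq_len(p) - 1L) * N, rep.int(n, p))
  xs <- matrix(X[lin], n, p)
  cs <- apply(matrix(y[as.vector(m)], n, p), 2, cumsum)
  S <- cs[n, 1]
  i <- seq_len(n - 1)
  score <- cs[i, , drop = FALSE]^2 / i + (S - cs[i, , drop = FALSE])^2 / (n - i)
  valid <- (xs[i + 1, , drop = FALSE] > xs[i, , drop = FALSE]) &
    (i >= min_leaf & (n - i) >= min_leaf)
  score[!valid] <- -Inf
  top <- max(score)
  if (!is.finite(top) || top <= S^2 / n + 1e-10) return(NULL)
  # ties: column-major which() lands on the smallest feature index, and within
  # it the smallest threshold (xs is sorted)
  b <- which(score == top)[1]
  row <- (b - 1L) %% (n - 1L) + 1L
  col <- (b - 1L) %/% (n - 1L) + 1L
  list(var = col, threshold = (xs[row, col] + xs[row + 1, col]) / 2)
}

# Depth-limited CART grown on rows `idx`; nodes accumulated in `env$nodes`.
grow_node <- function(X, y, idx, depth, max_depth, min_leaf, ord_mat, env) {
  id <- length(env$nodes) + 1L
  env$nodes[id] <- list(NULL)  # reserve slot
  yj <- y[idx]
  n <- length(idx)
  leaf <- list(var = NA_integer_, threshold = NA_real_,
               left = NA_integer_, right = NA_integer_, value = mean(yj))
  best <- if (depth < max_depth && n >= 2 * min_leaf && var(yj) > 0) {
    best_split_node(X, y, idx, ord_mat, min_leaf)
  }
  if (is.null(best)) {
    env$nodes[[id]] <- leaf
    return(id)
  }
  go_left <- X[idx, best$var] <= best$threshold
  left <- grow_node(X, y, idx[go_left], depth + 1L, max_depth, min_leaf,
                    ord_mat, env)
  right <- grow_node(X, y, idx[!go_left], depth + 1L, max_depth, min_leaf,
                     ord_mat, env)
  env$nodes[[id]] <- list(var = best$var, threshold = best$threshold,
                          left = left, right = right, value = mean(yj))
  id
}

fit_tree <- function(X, y, max_depth, min_leaf,
                     ord_mat = apply(X, 2, order, method = "radix")) {
  env <- new.env()
  env$nodes <- list()
  grow_node(X, y, seq_len(nrow(X)), 0L, max_depth, min_leaf, ord_mat, env)
  env$nodes
}

predict_tree <- function(nodes, X) {
  out <- numeric(nrow(X))
  stack <- list(list(node = 1L, rows = seq_len(nrow(X))))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- nodes[[top$node]]
    if (is.na(nd$var)) {
      out[top$rows] <- nd$value
    } else {
      go_left <- X[top$rows, nd$var] <= nd$threshold
      if (any(go_left)) stack[[length(stack) + 1L]] <-
          list(node = nd$left, rows = top$rows[go_left])
      if (any(!go_left)) stack[[length(stack) + 1L]] <-
          list(node = nd$right, rows = top$rows[!go_left])
    }
  }
  out
}

#' Fit a gradient boosted regression tree ensemble
#'
#' Stagewise squared-loss boosting: the model starts at the training mean and
#' each of `n_trees` rounds fits a depth-limited regression tree to the
#' current residuals, added with shrinkage `learning_rate`. Tree splits
#' maximise variance reduction; ties go to the smallest wavelength index, then
#' the smallest threshold, so fits are bit-reproducible.
#'
#' @param X Spectra matrix, n x p.
#' @param y Response vector.
#' @param n_trees Number of boosting rounds M (>= 0; M = 0 predicts the mean).
#' @param learning_rate Shrinkage in (0, 1].
#' @param max_depth Maximum tree depth (>= 1; depth 1 gives stumps).
#' @param min_samples_leaf Minimum rows per leaf (>= 1).
#'
#' @return An object of class `gbrt_model`: `initial_prediction`, the list of
#'   `trees`, `learning_rate`, and the per-round training RMSE path
#'   (`train_rmse`, length M + 1 including round 0).
#' @examples
#' X <- matrix(runif(40), 20, 2)
#' y <- sin(4 * X[, 1])
#' m <- fit_gbrt(X, y, n_trees = 25, learning_rate = 0.3, max_depth = 2)
#' glance(m)
#' @export
fit_gbrt <- function(X, y, n_trees = 200L, learning_rate = 0.05,
                     max_depth = 3L, min_samples_leaf = 2L) {
  X <- check_matrix(X)
  if (nrow(X) == 0) abort("Empty training set.")
  if (length(y) != nrow(X)) abort("`y` length must match rows of `X`.")
  n_trees <- check_scalar_int(n_trees, "n_trees")
  if (n_trees < 0) abort("`n_trees` must be >= 0.")
  if (learning_rate <= 0 || learning_rate > 1) abort("`learning_rate` must be in (0, 1].")
  init <- mean(y)
  pred <- rep(init, nrow(X))
  trees <- vector("list", n_trees)
  rmse <- numeric(n_trees + 1)
  rmse[1] <- sqrt(mean((y - pred)^2))
  ord_mat <- apply(X, 2, order, method = "radix")
  for (m in seq_len(n_trees)) {
    trees[[m]] <- fit_tree(X, y - pred, max_depth, min_samples_leaf, ord_mat)
    pred <- pred + learning_rate * predict_tree(trees[[m]], X)
    rmse[m + 1] <- sqrt(mean((y - pred)^2))
  }
  structure(
    list(initial_prediction = init, trees = trees,
         learning_rate = learning_rate, n_trees = n_trees,
         max_depth = max_depth, min_samples_leaf = min_samples_leaf,
         p = ncol(X), n_train = nrow(X), train_rmse = rmse),
    class = "gbrt_model"
  )
}

#' Predict from a GBRT ensemble
#'
#' @param model A `gbrt_model`.
#' @param X Spectra matrix (or single spectrum) with the feature count seen at
#'   fit time.
#' @return Numeric vector: initial prediction plus shrinkage times the sum of
#'   tree outputs.
#' @export
gbrt_predict <- function(model, X) {
  if (!inherits(model, "gbrt_model")) abort("`model` must be a gbrt_model.")
  if (is.null(dim(X))) X <- matrix(X, 1)
  X <- check_matrix(X)
  if (ncol(X) != model$p) abort("Feature count differs from fit time.")
  pred <- rep(model$initial_prediction, nrow(X))
  for (tr in model$trees) pred <- pred + model$learning_rate * predict_tree(tr, X)
  pred
}

#' @export
predict.gbrt_model <- function(object, newdata, ...) gbrt_predict(object, newdata)

#' @export
print.gbrt_model <- function(x, ...) {
  cat(sprintf("<gbrt_model> %d trees (depth <= %d, nu = %g), %d features\n",
              x$n_trees, x$max_depth, x$learning_rate, x$p))
  invisible(x)
}

#' Tune GBRT hyperparameters by cross-validation
#'
#' Evaluates each `(n_trees, learning_rate, max_depth)` row of `grid` by
#' k-fold CV RMSE and returns the grid with a `cv_rmse` column, best row
#' first (ties keep grid order).
#'
#' @param X,y Training data.
#' @param grid Tibble/data frame with columns `n_trees`, `learning_rate`,
#'   `max_depth` (optionally `min_samples_leaf`).
#' @param folds CV folds (>= 2).
#' @param seed Seed for fold assignment.
#' @return The grid tibble sorted by `cv_rmse`.
#' @export
tune_gbrt <- function(X, y,
                      grid = tidyr::expand_grid(
                        n_trees = c(100L, 200L),
                        learning_rate = c(0.05, 0.1),
                        max_depth = c(2L, 3L)
                      ),
                      folds = 5L, seed = 1L) {
  X <- check_matrix(X)
  if (nrow(grid) < 1) abort("`grid` must be non-empty.")
  n <- nrow(X)
  assign_f <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  grid <- tibble::as_tibble(grid)
  if (!"min_samples_leaf" %in% names(grid)) grid$min_samples_leaf <- 2L
  grid$cv_rmse <- purrr::pmap_dbl(grid, function(n_trees, learning_rate,
                                                 max_depth, min_samples_leaf, ...) {
    sse <- 0
    for (f in seq_len(folds)) {
      tr <- assign_f != f
      m <- fit_gbrt(X[tr, , drop = FALSE], y[tr], n_trees, learning_rate,
                    max_depth, min_samples_leaf)
      sse <- sse + sum((y[!tr] - gbrt_predict(m, X[!tr, , drop = FALSE]))^2)
    }
    sqrt(sse / n)
  })
  dplyr::arrange(grid, .data$cv_rmse)
}

#' @rdname pearnir-tidiers
#' @export
#' @exportS3Method generics::tidy
tidy.gbrt_model <- function(x, ...) {
  tibble::tibble(
    tree = seq_len(x$n_trees),
    n_nodes = vapply(x$trees, length, integer(1)),
    n_leaves = vapply(x$trees, function(tr) {
      sum(vapply(tr, function(nd) is.na(nd$var), logical(1)))
    }, integer(1)),
    train_rmse = x$train_rmse[-1]
  )
}

#' @rdname pearnir-tidiers
#' @export
#' @exportS3Method generics::glance
glance.gbrt_model <- function(x, ...) {
  tibble::tibble(
    n_trees = x$n_trees,
    learning_rate = x$learning_rate,
    max_depth = x$max_depth,
    min_samples_leaf = x$min_samples_leaf,
    n_train = x$n_train,
    train_rmse = x$train_rmse[x$n_trees + 1]
  )
}
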