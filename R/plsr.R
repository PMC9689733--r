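# Partial least squares regression, single response (PLS1), via NIPALS.

nipals_pls1 <- function(X, y, k, scale = FALSE) {
  x_mean <- colMeans(X)
  x_sd <- if (scale) {
    s <- apply(X, 2, sd); s[s == 0] <- 1; s
  } else rep(1, ncol(X))
  y_mean <- mean(y)
  Xc <- X - rep(x_mean, each = nrow(X))
  if (scale) Xc <- Xc / rep(x_sd, each = nrow(X))
  yc <- y - y_mean
  p <- ncol(X)
  W <- matrix(0, p, k); P <- matrix(0, p, k); q <- numeric(k)
  k_eff <- 0L
  for (a in seq_len(k)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break  # response already fully explained
    w <- w / nw
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pl <- drop(crossprod(Xc, t)) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pl)
    yc <- yc - qa * t
    W[, a] <- w; P[, a] <- pl; q[a] <- qa
    k_eff <- a
  }
  list(x_mean = x_mean, x_sd = x_sd, y_mean = y_mean,
       W = W[, seq_len(max(k_eff, 1)), drop = FALSE],
       P = P[, seq_len(max(k_eff, 1)), drop = FALSE],
       q = q[seq_len(max(k_eff, 1))],
       k = k_eff, scale = scale)
}

plsr_coef_at <- function(fit, k) {
  k <- min(k, max(fit$k, 1L))
  W <- fit$W[, seq_len(k), drop = FALSE]
  P <- fit$P[, seq_len(k), drop = FALSE]
  if (fit$k == 0) return(list(coef = rep(0, nrow(W)), intercept = fit$y_mean))
  B <- drop(W %*% solve(crossprod(P, W), fit$q[seq_len(k)]))
  B <- B / fit$x_sd
  list(coef = B, intercept = fit$y_mean - sum(fit$x_mean * B))
}

#' Fit a PLS1 calibration model
#'
#' NIPALS partial least squares with a single response: components maximise
#' covariance between the centred spectra and the centred response, with
#' deflation after each component. The fitted object carries the equivalent
#' linear form (coefficients per wavelength plus intercept) reconstructed from
#' the weight/loading triplets.
#'
#' @param X Spectra matrix, n x p.
#' @param y Response vector (one analyte concentration per row of `X`).
#' @param k Number of latent components, `1 <= k <= min(n - 1, p)`.
#' @param scale Autoscale columns to unit variance before fitting (columns
#'   share units, so the default is centring only).
#'
#' @return An object of class `plsr_model`: `coefficients`, `intercept`,
#'   `n_components` (effective count; fewer than `k` if the response is
#'   exhausted early), the component triplets (`weights`, `loadings`,
#'   `y_loadings`), and centring statistics.
#' @examples
#' X <- matrix(rnorm(60), 12, 5)
#' y <- X[, 1] - 2 * X[, 3] + rnorm(12, 0, 0.01)
#' m <- fit_plsr(X, y, k = 3)
#' glance(m)
#' @export
fit_plsr <- function(X, y, k, scale = FALSE) {
  X <- check_matrix(X)
  if (length(y) != nrow(X)) abort("`y` length must match rows of `X`.")
  if (anyNA(y) || any(!is.finite(y))) abort("`y` must be finite.")
  if (sd(y) == 0) abort("Degenerate target: `y` has zero variance.")
  k <- check_scalar_int(k, "k")
  if (k < 1 || k > min(nrow(X) - 1, ncol(X))) {
    abort("`k` must satisfy 1 <= k <= min(n - 1, p).")
  }
  fit <- nipals_pls1(X, y, k, scale = scale)
  cf <- plsr_coef_at(fit, fit$k)
  structure(
    list(coefficients = cf$coef, intercept = cf$intercept,
         n_components = max(fit$k, 1L), requested_components = k,
         weights = fit$W, loadings = fit$P, y_loadings = fit$q,
         x_mean = fit$x_mean, x_sd = fit$x_sd, y_mean = fit$y_mean,
         scale = scale, p = ncol(X), n_train = nrow(X)),
    class = "plsr_model"
  )
}

#' Predict from a PLS1 model
#'
#' @param model A `plsr_model`.
#' @param X Spectra matrix (or single spectrum) with the wavelength count seen
#'   at fit time.
#' @return Numeric vector of predictions, `X %*% coefficients + intercept`.
#' @export
plsr_predict <- function(model, X) {
  if (!inherits(model, "plsr_model")) abort("`model` must be a plsr_model.")
  if (is.null(dim(X))) X <- matrix(X, 1)
  X <- check_matrix(X)
  if (ncol(X) != model$p) abort("Wavelength count differs from fit time.")
  drop(X %*% model$coefficients) + model$intercept
}

#' @export
predict.plsr_model <- function(object, newdata, ...) plsr_predict(object, newdata)

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d components, %d wavelengths, n_train = %d\n",
              x$n_components, x$p, x$n_train))
  invisible(x)
}

# Cross-validated RMSE for k = 1..k_max (single NIPALS per fold).
cv_rmse_plsr <- function(X, y, k_max, folds = 10L, seed = 1L, scale = FALSE) {
  n <- nrow(X)
  if (folds < 2) abort("`folds` must be at least 2.")
  if (folds > n) abort("More folds than samples.")
  assign_f <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  k_cap <- min(k_max, n - ceiling(n / folds) - 1, ncol(X))
  if (k_cap < 1) abort("Too few samples for this fold count.")
  sse <- numeric(k_cap)
  for (f in seq_len(folds)) {
    tr <- assign_f != f
    fit <- nipals_pls1(X[tr, , drop = FALSE], y[tr], k_cap, scale = scale)
    y0 <- y[!tr]
    # score-space prediction recursion: equivalent to the per-k coefficient
    # reconstruction but needs no linear solves
    X0 <- X[!tr, , drop = FALSE]
    X0c <- X0 - rep(fit$x_mean, each = nrow(X0))
    if (scale) X0c <- X0c / rep(fit$x_sd, each = nrow(X0))
    pred <- rep(fit$y_mean, nrow(X0c))
    k_eff <- max(fit$k, 1L)
    for (a in seq_len(k_eff)) {
      t0 <- drop(X0c %*% fit$W[, a])
      pred <- pred + fit$q[a] * t0
      X0c <- X0c - tcrossprod(t0, fit$P[, a])
      sse[a] <- sse[a] + sum((y0 - pred)^2)
    }
    if (k_eff < k_cap) {
      sse[(k_eff + 1):k_cap] <- sse[(k_eff + 1):k_cap] + sum((y0 - pred)^2)
    }
  }
  sqrt(sse / n)
}

#' Choose the PLSR component count by cross-validation
#'
#' k-fold cross-validation over `1..k_max` components (capped so every
#' training fold can support the count); returns the k minimising CV RMSE,
#' with ties broken toward the smaller k. Fold assignment is seeded and
#' reproducible.
#'
#' @param X Spectra matrix.
#' @param y Response vector.
#' @param k_max Largest candidate component count.
#' @param folds Number of CV folds (>= 2).
#' @param seed Integer seed for fold assignment.
#' @param scale Autoscaling switch, as in [fit_plsr()].
#' @return The chosen component count (integer).
#' @export
select_components <- function(X, y, k_max = 20L, folds = 10L, seed = 1L,
                              scale = FALSE) {
  X <- check_matrix(X)
  if (sd(y) == 0) abort("Degenerate target: `y` has zero variance.")
  rmse <- cv_rmse_plsr(X, y, k_max, folds, seed, scale)
  which.min(rmse)  # which.min takes the first (smallest k) on ties
}

#' @rdname pearnir-tidiers
#' @export
#' @exportS3Method generics::tidy
tidy.plsr_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients) %||%
               paste0("wl_", seq_along(x$coefficients))),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' @rdname pearnir-tidiers
#' @export
#' @exportS3Method generics::glance
glance.plsr_model <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    n_train = x$n_train,
    n_wavelengths = x$p,
    scaled = x$scale
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
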