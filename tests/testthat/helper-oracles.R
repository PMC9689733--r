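# Independent naive-loop oracles. These deliberately avoid the package's own
# vectorised code paths: explicit loops, lm() fits, exhaustive searches.

naive_mean_rows <- function(R) {
  out <- numeric(ncol(R))
  for (j in seq_len(ncol(R))) {
    s <- 0
    for (i in seq_len(nrow(R))) s <- s + R[i, j]
    out[j] <- s / nrow(R)
  }
  out
}

# Savitzky-Golay by brute-force local polynomial regression; edges evaluate
# the nearest complete window's fit at the edge position.
naive_sg_row <- function(x, window, polyorder) {
  p <- length(x)
  h <- (window - 1) / 2
  out <- numeric(p)
  for (t in seq_len(p)) {
    s <- min(max(1, t - h), p - window + 1)
    pos <- s:(s + window - 1)
    fit <- lm(x[pos] ~ poly(pos, polyorder, raw = TRUE))
    out[t] <- unname(predict(fit, data.frame(pos = t)))
  }
  out
}

naive_derivative_row <- function(x, order, h) {
  p <- length(x)
  out <- numeric(p)
  if (order == 1) {
    for (t in 2:(p - 1)) out[t] <- (x[t + 1] - x[t - 1]) / (2 * h)
    out[1] <- (x[2] - x[1]) / h
    out[p] <- (x[p] - x[p - 1]) / h
  } else {
    for (t in 2:(p - 1)) out[t] <- (x[t + 1] - 2 * x[t] + x[t - 1]) / h^2
    out[1] <- (x[3] - 2 * x[2] + x[1]) / h^2
    out[p] <- (x[p] - 2 * x[p - 1] + x[p - 2]) / h^2
  }
  out
}

naive_msc_row <- function(x, ref) {
  fit <- lm(x ~ ref)
  (x - coef(fit)[1]) / coef(fit)[2]
}

naive_snv_row <- function(x) (x - mean(x)) / sd(x)

naive_metrics <- function(y, yhat) {
  n <- length(y)
  sse <- 0
  for (i in seq_len(n)) sse <- sse + (y[i] - yhat[i])^2
  rmse <- sqrt(sse / n)
  list(r2 = cor(y, yhat)^2, rmse = rmse, rpd = sd(y) / rmse)
}

# textbook loop-wise NIPALS PLS1 (no matrix products)
naive_pls1_coef <- function(X, y, k) {
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  W <- matrix(0, p, k); P <- matrix(0, p, k); q <- numeric(k)
  for (a in 1:k) {
    w <- numeric(p)
    for (j in 1:p) w[j] <- sum(Xc[, j] * yc)
    w <- w / sqrt(sum(w^2))
    t <- numeric(n)
    for (i in 1:n) t[i] <- sum(Xc[i, ] * w)
    tt <- sum(t^2)
    pl <- numeric(p)
    for (j in 1:p) pl[j] <- sum(Xc[, j] * t) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - outer(t, pl)
    yc <- yc - qa * t
    W[, a] <- w; P[, a] <- pl; q[a] <- qa
  }
  B <- W %*% solve(t(P) %*% W) %*% q
  list(coef = drop(B), intercept = ym - sum(xm * B))
}

# exhaustive best single stump (squared loss), smallest threshold on ties
naive_best_stump <- function(x, y, min_leaf = 1) {
  xs <- sort(unique(x))
  best <- NULL
  for (i in seq_len(length(xs) - 1)) {
    thr <- (xs[i] + xs[i + 1]) / 2
    L <- y[x <= thr]; R <- y[x > thr]
    if (length(L) < min_leaf || length(R) < min_leaf) next
    sse <- sum((L - mean(L))^2) + sum((R - mean(R))^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(threshold = thr, left = mean(L), right = mean(R), sse = sse)
    }
  }
  best
}

# recursive naive CART with the same split rule (variance reduction, smallest
# feature index then smallest threshold on ties), grown feature-by-feature
naive_tree_predict <- function(X, y, Xnew, max_depth, min_leaf, depth = 0) {
  n <- length(y)
  if (depth >= max_depth || n < 2 * min_leaf || var(y) == 0) {
    return(rep(mean(y), nrow(Xnew)))
  }
  base_sse <- sum((y - mean(y))^2)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    st <- naive_best_stump(X[, j], y, min_leaf)
    if (!is.null(st) && base_sse - st$sse > 1e-10 &&
        (is.null(best) || st$sse < best$sse - 1e-10)) {
      best <- c(st, var = j)
    }
  }
  if (is.null(best)) return(rep(mean(y), nrow(Xnew)))
  go <- X[, best$var] <= best$threshold
  go_new <- Xnew[, best$var] <= best$threshold
  out <- numeric(nrow(Xnew))
  out[go_new] <- naive_tree_predict(X[go, , drop = FALSE], y[go],
                                    Xnew[go_new, , drop = FALSE],
                                    max_depth, min_leaf, depth + 1)
  out[!go_new] <- naive_tree_predict(X[!go, , drop = FALSE], y[!go],
                                     Xnew[!go_new, , drop = FALSE],
                                     max_depth, min_leaf, depth + 1)
  out
}

naive_gbrt_predict <- function(X, y, Xnew, M, nu, max_depth, min_leaf) {
  pred <- rep(mean(y), length(y))
  pred_new <- rep(mean(y), nrow(Xnew))
  for (m in seq_len(M)) {
    both <- naive_tree_predict(X, y - pred, rbind(X, Xnew),
                               max_depth, min_leaf)
    pred <- pred + nu * both[seq_len(nrow(X))]
    pred_new <- pred_new + nu * both[-seq_len(nrow(X))]
  }
  pred_new
}

# a small random spectra-like matrix
rand_spectra <- function(n = 20, p = 228, seed = 1) {
  set.seed(seed)
  matrix(runif(n * p, 0.2, 0.8), n, p)
}

# wavelengths within `mult` band widths of any band centre of a spec
planted_wavelengths <- function(spec, grid, mult = 1.5) {
  hit <- rep(FALSE, length(grid))
  for (j in seq_along(spec$band_centers_nm)) {
    hit <- hit | abs(grid - spec$band_centers_nm[j]) <=
      mult * spec$band_widths_nm[j]
  }
  hit
}
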