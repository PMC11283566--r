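#' Presence filter for metabolite feature tables
#'
#' Retains features whose maximum intensity across samples meets
#' `min_max_abundance` (default 500 counts — untargeted LC-MS features below
#' that are dominated by integration noise).
#'
#' @param fm samples x features intensity matrix (non-negative).
#' @param min_max_abundance threshold on the per-feature maximum.
#' @return filtered matrix (possibly zero features, with a warning).
#' @export
presence_filter <- function(fm, min_max_abundance = 500) {
  fm <- as.matrix(fm)
  if (any(fm < 0)) stop("intensities must be non-negative")
  keep <- apply(fm, 2, max) >= min_max_abundance
  if (!any(keep)) warning("presence filter removed every feature")
  fm[, keep, drop = FALSE]
}

#' Interquartile-range filter
#'
#' Drops the least-variable features: those whose IQR falls below the
#' `drop_quantile` quantile of all feature IQRs. `drop_quantile = 0` is the
#' identity.
#'
#' @param fm samples x features matrix.
#' @param drop_quantile fraction of low-IQR features to drop, in \[0,1).
#' @return filtered matrix.
#' @export
iqr_filter <- function(fm, drop_quantile = 0.25) {
  if (drop_quantile < 0 || drop_quantile >= 1)
    stop("drop_quantile must lie in [0, 1)")
  fm <- as.matrix(fm)
  iqrs <- apply(fm, 2, stats::IQR)
  fm[, iqrs >= quantile(iqrs, drop_quantile), drop = FALSE]
}

#' Log-transform and scale a feature matrix
#'
#' Zeros are replaced per feature (default: half that feature's smallest
#' positive value), intensities are log-transformed, and each feature is
#' scaled: `"pareto"` (mean-centered, divided by the square root of the SD —
#' shrinks the dominance of high-variance features without amplifying noise
#' as much as unit scaling), `"unit"` (autoscaling), or `"none"`
#' (log only). Entirely-zero features are dropped with a warning.
#'
#' @param fm samples x features matrix of non-negative intensities.
#' @param log_base logarithm base (default 10).
#' @param zero_policy `"half_min"` or a positive numeric replacement.
#' @param scaling `"pareto"` (default), `"unit"`, or `"none"`.
#' @return normalized numeric matrix.
#' @export
normalize_features <- function(fm, log_base = 10, zero_policy = "half_min",
                               scaling = c("pareto", "unit", "none")) {
  scaling <- match.arg(scaling)
  fm <- as.matrix(fm)
  if (any(fm < 0)) stop("intensities must be non-negative")
  all_zero <- apply(fm, 2, function(v) all(v == 0))
  if (any(all_zero)) {
    warning("dropping entirely-zero features: ",
            paste(colnames(fm)[all_zero], collapse = ", "))
    fm <- fm[, !all_zero, drop = FALSE]
  }
  fm <- apply(fm, 2, function(v) {
    repl <- if (identical(zero_policy, "half_min")) min(v[v > 0]) / 2
            else as.numeric(zero_policy)
    v[v == 0] <- repl
    v
  })
  x <- log(fm, base = log_base)
  switch(scaling,
         none = x,
         unit = scale(x, center = TRUE, scale = TRUE),
         pareto = {
           ctr <- scale(x, center = TRUE, scale = FALSE)
           s <- sqrt(apply(x, 2, sd))
           sweep(ctr, 2, ifelse(s > 0, s, 1), "/")  # constant -> centered 0
         })
}

#' PCA scores and explained variance
#'
#' Centered singular-value decomposition via [stats::prcomp()].
#'
#' @param x samples x features numeric matrix (already normalized).
#' @param n_components number of components to return.
#' @return list: `scores` (samples x components), `explained_variance`
#'   (fractions, summing to at most 1 over the returned components),
#'   `loadings`.
#' @export
pca_scores <- function(x, n_components = 2) {
  x <- as.matrix(x)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  if (n_components > ncol(pc$rotation))
    stop("n_components exceeds the rank of the data (", ncol(pc$rotation), ")")
  idx <- seq_len(n_components)
  list(scores = pc$x[, idx, drop = FALSE],
       explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[idx],
       loadings = pc$rotation[, idx, drop = FALSE])
}

#' Partial least-squares discriminant analysis with VIP scores
#'
#' NIPALS PLS2 on the centered data with a centered one-hot class response.
#' The variable importance in projection of feature `j` is
#' `VIP_j = sqrt(p * sum_a SSY_a * (w_aj / ||w_a||)^2 / sum_a SSY_a)` where
#' `SSY_a` is the response sum of squares explained by component `a` and
#' `w_a` its weight vector; `sum_j VIP_j^2 = p` by construction.
#'
#' @param x samples x features numeric matrix (already normalized).
#' @param class_labels factor/character of class membership (>= 2 classes,
#'   each with >= 2 samples).
#' @param n_components number of latent components (default 2; reduced with
#'   a warning if the data are exhausted earlier).
#' @return list of class `plsda_model`: `vip` (named), `weights`, `scores`,
#'   `x_loadings`, `y_loadings`, `ssy`, `n_components`, `classes`.
#' @export
plsda_vip <- function(x, class_labels, n_components = 2) {
  x <- as.matrix(x)
  g <- factor(class_labels)
  if (nlevels(g) < 2) stop("need at least two classes")
  if (any(table(g) < 2)) stop("every class needs at least two samples")
  if (nrow(x) != length(g)) stop("class_labels must match the rows of x")
  n <- nrow(x); p <- ncol(x)
  y <- stats::model.matrix(~ g - 1)
  colnames(y) <- levels(g)
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- scale(y, center = TRUE, scale = FALSE)

  a_max <- min(n_components, n - 1, p)
  w_mat <- matrix(0, p, a_max); t_mat <- matrix(0, n, a_max)
  p_mat <- matrix(0, p, a_max); q_mat <- matrix(0, ncol(y), a_max)
  ssy <- numeric(a_max)
  a_used <- 0
  for (a in seq_len(a_max)) {
    u <- yc[, which.max(colSums(yc^2))]
    if (sum(u^2) < 1e-12) break
    for (it in 1:500) {
      w <- crossprod(xc, u); w <- w / sqrt(sum(w^2))
      tt <- xc %*% w
      q <- crossprod(yc, tt) / sum(tt^2)
      u_new <- yc %*% q / sum(q^2)
      if (sqrt(sum((u_new - u)^2)) < 1e-10 * sqrt(sum(u^2))) { u <- u_new; break }
      u <- u_new
    }
    if (sum(tt^2) < 1e-12) break
    pl <- crossprod(xc, tt) / sum(tt^2)
    ssy[a] <- sum(tt^2) * sum(q^2)       # SS of Y explained by component a
    w_mat[, a] <- w; t_mat[, a] <- tt
    p_mat[, a] <- pl; q_mat[, a] <- q
    xc <- xc - tcrossprod(tt, pl)
    yc <- yc - tcrossprod(tt, q)
    a_used <- a
  }
  if (a_used == 0) stop("no PLS component could be extracted")
  if (a_used < n_components)
    warning("data exhausted after ", a_used, " component(s)")
  idx <- seq_len(a_used)
  w_mat <- w_mat[, idx, drop = FALSE]
  vip <- sqrt(p * as.vector(w_mat^2 %*% ssy[idx]) / sum(ssy[idx]))
  names(vip) <- colnames(x)
  structure(list(vip = vip,
                 weights = w_mat,
                 scores = t_mat[, idx, drop = FALSE],
                 x_loadings = p_mat[, idx, drop = FALSE],
                 y_loadings = q_mat[, idx, drop = FALSE],
                 ssy = ssy[idx],
                 n_components = a_used,
                 classes = g),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("PLS-DA model: %d components, %d features, classes: %s\n",
              x$n_components, length(x$vip),
              paste(levels(x$classes), collapse = ", ")))
  invisible(x)
}

#' Top-VIP heatmap matrix with Euclidean/Ward ordering
#'
#' Selects the `n_top` features with the highest VIP, log-transforms their
#' raw intensities (half-minimum zero replacement), scales each feature to
#' \[0,1\] by its maximum, and orders rows and columns by agglomerative
#' clustering (Euclidean distance, Ward.D linkage).
#'
#' @param model a `plsda_model`.
#' @param fm raw samples x features intensity matrix containing the model's
#'   features.
#' @param n_top number of features (default 50; clipped with a warning).
#' @return list: `matrix` (reordered samples x features, values in \[0,1\]),
#'   `feature_order`, `sample_order`, `vip` of the selected features.
#' @export
top_vip_heatmap <- function(model, fm, n_top = 50) {
  stopifnot(inherits(model, "plsda_model"))
  fm <- as.matrix(fm)
  if (n_top > length(model$vip)) {
    warning("n_top exceeds the number of features; using all ",
            length(model$vip))
    n_top <- length(model$vip)
  }
  top <- names(sort(model$vip, decreasing = TRUE))[seq_len(n_top)]
  x <- normalize_features(fm[, top, drop = FALSE], scaling = "none")
  # anchor any feature whose log values dip below zero, then divide by the
  # maximum so every feature lives on [0, 1] and attains 1 somewhere
  x <- apply(x, 2, function(v) if (min(v) < 0) v - min(v) else v)
  mx <- apply(x, 2, max)
  scaled <- sweep(x, 2, ifelse(mx > 0, mx, 1), "/")
  f_ord <- hclust(dist(t(scaled)), method = "ward.D")$order
  s_ord <- hclust(dist(scaled), method = "ward.D")$order
  list(matrix = scaled[s_ord, f_ord, drop = FALSE],
       feature_order = colnames(scaled)[f_ord],
       sample_order = rownames(scaled)[s_ord],
       vip = model$vip[top])
}
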