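#' Group-size-corrected phi coefficient ("r.g.") of a taxon and a sample set
#'
#' The abundance-based phi coefficient is the Pearson correlation between a
#' taxon's abundance vector and the 0/1 membership indicator of a target
#' sample set. To correct for unequal group sizes, samples are weighted
#' `w_i = N / (K * n_g(i))` so every group contributes equal total weight;
#' with equal group sizes this reduces to the ordinary (point-biserial)
#' correlation.
#'
#' @param x abundance vector over all samples.
#' @param membership logical/0-1 vector: is the sample in the target set?
#' @param groups factor of group assignment (defines `K` and the `n_g`).
#' @return correlation in \[-1,1\], or `NA` when `x` (or the membership) has
#'   zero weighted variance.
#' @export
phi_rg <- function(x, membership, groups) {
  groups <- factor(groups)
  if (length(x) != length(membership) || length(x) != length(groups))
    stop("x, membership, and groups must have equal length")
  n_g <- table(groups)
  if (any(n_g == 0)) stop("empty group")
  w <- as.numeric(length(x) / (nlevels(groups) * n_g[groups]))
  y <- as.numeric(membership)
  weighted_cor(matrix(x, ncol = 1), y, w)[1]
}

# column-wise weighted Pearson correlation of x (matrix) with y (vector)
weighted_cor <- function(x, y, w) {
  sw <- sum(w)
  mx <- colSums(w * x) / sw
  my <- sum(w * y) / sw
  cov_xy <- colSums(w * x * y) / sw - mx * my
  var_x <- colSums(w * x * x) / sw - mx^2
  var_y <- sum(w * y * y) / sw - my^2
  out <- cov_xy / sqrt(var_x * var_y)
  out[var_x <= 0 | var_y <= 0] <- NA_real_
  pmin(1, pmax(-1, out))
}

target_sets <- function(levs, include_unions) {
  sets <- as.list(levs)
  if (include_unions && length(levs) > 2) {
    for (k in 2:(length(levs) - 1))
      sets <- c(sets, combn(levs, k, simplify = FALSE))
  }
  names(sets) <- vapply(sets, paste, "", collapse = "+")
  sets
}

#' Indicator taxon analysis with the group-equalized phi coefficient
#'
#' Every taxon is scored with [phi_rg()] against every target set (the
#' singleton groups and, optionally, their unions, excluding the all-groups
#' set); the maximizing set is assigned. One-sided p-values (large phi) come
#' from permuting the sample-to-group assignment and recomputing the maximum
#' statistic, using `(b+1)/(B+1)`; Benjamini-Hochberg q-values are computed
#' across taxa. Taxa with negative best phi ("avoiders") are reported but
#' never flagged as indicators.
#'
#' @param table samples x taxa abundance matrix (counts or relative).
#' @param groups factor of group labels in row order of `table`.
#' @param include_unions also evaluate multi-group target sets.
#' @param n_perm,seed permutation settings.
#' @param alpha q-value threshold for the `indicator` flag.
#' @return data.frame: `taxon_id`, `best_set`, `phi`, `p_value`, `q_value`,
#'   `indicator`.
#' @export
indicator_analysis <- function(table, groups, include_unions = FALSE,
                               n_perm = 999, seed = NULL, alpha = 0.05) {
  x <- as.matrix(table)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) == 0)) stop("group with zero samples")
  levs <- levels(groups)
  sets <- target_sets(levs, include_unions)
  n <- nrow(x)
  n_g <- table(groups)
  w0 <- as.numeric(n / (nlevels(groups) * n_g[groups]))

  phi_all <- function(g_perm, w_perm) {
    # taxa x sets matrix of weighted correlations
    res <- vapply(sets, function(s)
      weighted_cor(x, as.numeric(g_perm %in% s), w_perm),
      numeric(ncol(x)))
    matrix(res, nrow = ncol(x), ncol = length(sets))
  }
  obs <- phi_all(groups, w0)
  best <- apply(obs, 1, function(r)
    if (all(is.na(r))) NA_integer_ else which.max(r))
  phi_best <- obs[cbind(seq_len(nrow(obs)), best)]

  exceed <- numeric(ncol(x))
  with_seed(seed, for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    mx <- phi_all(groups[p], w0[p])
    mx <- suppressWarnings(apply(mx, 1, max, na.rm = TRUE))
    exceed <- exceed + (mx >= phi_best - 1e-12)
  })
  pval <- (1 + exceed) / (1 + n_perm)
  pval[is.na(phi_best)] <- NA
  qval <- p.adjust(pval, method = "BH")
  data.frame(taxon_id = colnames(x),
             best_set = names(sets)[best],
             phi = phi_best,
             p_value = pval,
             q_value = qval,
             indicator = !is.na(qval) & qval < alpha & phi_best > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Exact Venn partition of 2-4 named sets
#'
#' @param sets named list of 2-4 character vectors.
#' @return data.frame with one row per non-empty region combination:
#'   `region` (set names joined by `&`), `count`, and `members`
#'   (list-column). Region counts sum to the size of the union.
#' @export
venn_partition <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("`sets` must be a named list")
  if (length(sets) < 2 || length(sets) > 4)
    stop("venn_partition supports 2 to 4 sets")
  sets <- lapply(sets, unique)
  universe <- Reduce(union, sets)
  sig <- vapply(universe, function(el)
    paste(names(sets)[vapply(sets, function(s) el %in% s, logical(1))],
          collapse = "&"), "")
  regions <- split(universe, sig)
  # stable output: order regions by how many sets they involve, then name
  n_sets <- vapply(strsplit(names(regions), "&", fixed = TRUE), length, 1L)
  regions <- regions[order(n_sets, names(regions))]
  out <- data.frame(region = names(regions),
                    count = lengths(regions),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$members <- unname(regions)
  out
}
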