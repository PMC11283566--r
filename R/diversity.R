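#' Bray-Curtis dissimilarity matrix
#'
#' `d[i,j] = 1 - 2 * sum(min(x_i, x_j)) / sum(x_i + x_j)` over taxa, on
#' counts or relative abundances (the two differ only when row sums differ).
#' Computed through [vegan::vegdist()]. A pair of all-zero samples has an
#' undefined dissimilarity and is set to 0 with a warning.
#'
#' @param table samples x taxa matrix of non-negative abundances.
#' @return symmetric matrix with zero diagonal and entries in \[0,1\].
#' @export
bray_curtis <- function(table) {
  if (nrow(table) < 2) stop("need at least two samples")
  if (any(table < 0)) stop("abundances must be non-negative")
  d <- as.matrix(suppressWarnings(vegan::vegdist(table, method = "bray")))
  if (anyNA(d)) {
    warning("all-zero sample pair(s): dissimilarity set to 0")
    d[is.na(d)] <- 0
  }
  diag(d) <- 0
  d
}

as_dist_matrix <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-8))
    stop("distance matrix must be square and symmetric")
  dm
}

# Gower-centered inner-product matrix G = -1/2 * J %*% D^2 %*% J
gower_center <- function(dm) {
  a <- -0.5 * dm^2
  n <- nrow(a)
  j <- diag(n) - matrix(1 / n, n, n)
  j %*% a %*% j
}

#' Principal coordinates analysis
#'
#' Double-centers the squared distance matrix, eigendecomposes, and returns
#' coordinates scaled by the square root of the positive eigenvalues.
#' Negative eigenvalues (non-Euclidean distances) are reported and their
#' axes excluded; explained-variance fractions are computed over the
#' positive eigenvalues.
#'
#' @param dm symmetric distance matrix.
#' @return list: `coordinates` (samples x positive axes), `eigenvalues`
#'   (all), `prop_explained` (per positive axis), `negative_mass` (sum of
#'   absolute negative eigenvalues).
#' @export
pcoa <- function(dm) {
  dm <- as_dist_matrix(dm)
  g <- gower_center(dm)
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords,
       eigenvalues = e$values,
       prop_explained = e$values[pos] / sum(e$values[pos]),
       negative_mass = sum(abs(e$values[e$values < -tol])))
}

hat_matrix <- function(x) {
  qrx <- qr(x)
  q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
  tcrossprod(q)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions a distance matrix by design factors using sequential (Type I)
#' sums of squares: with the Gower-centered matrix `G`, the SS of each term
#' is the increment in `tr(H G)` as its columns join the cumulative design
#' hat matrix `H`. Pseudo-F per term is `(SS/df) / (SS_res/df_res)` and
#' p-values come from free permutation of samples, using the `(b+1)/(B+1)`
#' estimator (or complete enumeration with `exhaustive = TRUE`, restricted
#' to small n).
#'
#' @param dm symmetric distance matrix with sample names.
#' @param metadata data.frame with a `sample_id` column (or rownames)
#'   matching `dm`.
#' @param terms character vector of model terms in the order they enter the
#'   model, e.g. `c("planted", "drought", "planted:drought")`.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @param exhaustive enumerate all `n!` permutations (requires `n <= 8`).
#' @return data.frame: one row per term plus `Residual` and `Total`, with
#'   `df`, `sum_of_squares`, `r_squared`, `pseudo_f`, `p_value`,
#'   `n_permutations`.
#' @export
permanova <- function(dm, metadata, terms, n_perm = 999, seed = NULL,
                      exhaustive = FALSE) {
  dm <- as_dist_matrix(dm)
  n <- nrow(dm)
  md <- align_metadata(metadata, rownames(dm))
  g <- gower_center(dm)
  ss_total <- sum(diag(g))

  fmls <- lapply(seq_along(terms), function(i)
    stats::reformulate(terms[seq_len(i)]))
  designs <- lapply(fmls, model.matrix, data = md)
  hats <- c(list(matrix(1 / n, n, n)), lapply(designs, hat_matrix))
  ranks <- c(1L, vapply(designs, function(x) qr(x)$rank, integer(1)))
  dfs <- diff(ranks)
  if (any(dfs == 0))
    stop("aliased (confounded) model term(s): ",
         paste(terms[dfs == 0], collapse = ", "))
  df_res <- n - ranks[length(ranks)]
  if (df_res <= 0) stop("no residual degrees of freedom")

  # SS per term for a given permutation of G
  term_ss <- function(gp) {
    tr <- vapply(hats, function(h) sum(h * gp), numeric(1))
    diff(tr)
  }
  h_full <- hats[[length(hats)]]
  ss <- term_ss(g)
  ss_res <- ss_total - sum(h_full * g)   # tr(H G), G symmetric
  f_obs <- (ss / dfs) / (ss_res / df_res)

  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration limited to n <= 8")
    perms <- all_permutations(n)
    f_perm <- apply(perms, 1, function(p) {
      gp <- g[p, p]
      ssp <- term_ss(gp)
      (ssp / dfs) / ((ss_total - sum(h_full * gp)) / df_res)
    })
    f_perm <- matrix(f_perm, nrow = length(terms))
    pval <- rowMeans(f_perm >= f_obs - 1e-12)
    nperm_used <- ncol(f_perm)
  } else {
    exceed <- numeric(length(terms))
    with_seed(seed, for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      gp <- g[p, p]
      ssp <- term_ss(gp)
      fp <- (ssp / dfs) / ((ss_total - sum(h_full * gp)) / df_res)
      exceed <- exceed + (fp >= f_obs - 1e-12)
    })
    pval <- (1 + exceed) / (1 + n_perm)
    nperm_used <- n_perm
  }

  data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(dfs, df_res, n - 1L),
    sum_of_squares = c(ss, ss_res, ss_total),
    r_squared = c(ss, ss_res, ss_total) / ss_total,
    pseudo_f = c(f_obs, NA, NA),
    p_value = c(pval, NA, NA),
    n_permutations = c(rep(nperm_used, length(terms)), NA, NA),
    row.names = NULL, stringsAsFactors = FALSE)
}

align_metadata <- function(metadata, ids) {
  if (!is.null(metadata$sample_id)) {
    idx <- match(ids, metadata$sample_id)
  } else {
    idx <- match(ids, rownames(metadata))
  }
  if (anyNA(idx))
    stop("metadata missing for samples: ",
         paste(ids[is.na(idx)], collapse = ", "))
  metadata[idx, , drop = FALSE]
}

#' Pairwise post-hoc PERMANOVA between factor levels
#'
#' Runs a one-factor [permanova()] on every pair of levels and adjusts the
#' p-values across pairs with Benjamini-Hochberg.
#'
#' @param dm distance matrix.
#' @param metadata metadata (see [permanova()]).
#' @param factor_name name of the grouping column.
#' @param n_perm,seed permutation settings.
#' @return data.frame with one row per level pair: `pseudo_f`, `r_squared`,
#'   `p_value`, `q_value`.
#' @export
pairwise_permanova <- function(dm, metadata, factor_name, n_perm = 999,
                               seed = NULL) {
  dm <- as_dist_matrix(dm)
  md <- align_metadata(metadata, rownames(dm))
  gr <- as.character(md[[factor_name]])
  levs <- unique(gr[!is.na(gr)])
  if (length(levs) < 2) stop("factor must have at least two levels")
  pairs <- combn(levs, 2, simplify = FALSE)
  rows <- list()
  for (k in seq_along(pairs)) {
    pr <- pairs[[k]]
    sel <- which(gr %in% pr)
    if (min(table(gr[sel])) < 2) {
      warning("skipping pair ", paste(pr, collapse = " vs "),
              ": a level has fewer than two samples")
      next
    }
    sub <- permanova(dm[sel, sel], md[sel, , drop = FALSE], factor_name,
                     n_perm = n_perm,
                     seed = if (is.null(seed)) NULL else seed + k)
    rows[[length(rows) + 1]] <- data.frame(
      level_1 = pr[1], level_2 = pr[2],
      pseudo_f = sub$pseudo_f[1], r_squared = sub$r_squared[1],
      p_value = sub$p_value[1], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out
}

weiszfeld_median <- function(x, tol = 1e-10, max_iter = 200) {
  m <- colMeans(x)
  for (i in seq_len(max_iter)) {
    d <- sqrt(rowSums(sweep(x, 2, m)^2))
    w <- 1 / pmax(d, 1e-12)
    m_new <- colSums(x * w) / sum(w)
    if (sqrt(sum((m_new - m)^2)) < tol) return(m_new)
    m <- m_new
  }
  m
}

#' Homogeneity of multivariate dispersions (PERMDISP)
#'
#' Embeds the distance matrix by [pcoa()] (positive axes only; the dropped
#' negative-eigenvalue mass is reported), computes each sample's Euclidean
#' distance to its group's spatial center (geometric median by Weiszfeld
#' iteration, or centroid), and tests group differences in these distances
#' with a one-way ANOVA F whose p-value comes from permuting group labels.
#'
#' @param dm distance matrix.
#' @param groups factor/character vector of group labels (in `dm` sample
#'   order) or a named vector.
#' @param n_perm,seed permutation settings.
#' @param center `"median"` (default) or `"centroid"`.
#' @return list of class `permdisp`: `distances` (per sample),
#'   `group_means`, `f_value`, `p_value`, `negative_mass`.
#' @export
permdisp <- function(dm, groups, n_perm = 999, seed = NULL,
                     center = c("median", "centroid")) {
  center <- match.arg(center)
  dm <- as_dist_matrix(dm)
  if (!is.null(names(groups))) groups <- groups[rownames(dm)]
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least two groups")
  if (any(table(g) < 2))
    stop("group(s) of size one have undefined dispersion: ",
         paste(names(which(table(g) < 2)), collapse = ", "))
  ord <- pcoa(dm)
  x <- ord$coordinates
  z <- numeric(nrow(x))
  for (lev in levels(g)) {
    idx <- which(g == lev)
    ctr <- if (center == "median") weiszfeld_median(x[idx, , drop = FALSE])
           else colMeans(x[idx, , drop = FALSE])
    z[idx] <- sqrt(rowSums(sweep(x[idx, , drop = FALSE], 2, ctr)^2))
  }
  f_stat <- function(zz, gg) {
    m <- tapply(zz, gg, mean)
    nk <- tabulate(gg)
    ssb <- sum(nk * (m - mean(zz))^2)
    ssw <- sum((zz - m[gg])^2)
    (ssb / (nlevels(gg) - 1)) / (ssw / (length(zz) - nlevels(gg)))
  }
  f_obs <- f_stat(z, g)
  exceed <- with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(n_perm))
      if (f_stat(z[sample.int(length(z))], g) >= f_obs - 1e-12) cnt <- cnt + 1L
    cnt
  })
  structure(list(distances = setNames(z, rownames(dm)),
                 group_means = tapply(z, g, mean),
                 f_value = f_obs,
                 p_value = (1 + exceed) / (1 + n_perm),
                 n_permutations = n_perm,
                 center = center,
                 negative_mass = ord$negative_mass),
            class = "permdisp")
}

#' @export
print.permdisp <- function(x, ...) {
  cat(sprintf("PERMDISP (%s): F = %.4g, p = %.4g (%d permutations)\n",
              x$center, x$f_value, x$p_value, x$n_permutations))
  print(round(x$group_means, 4))
  invisible(x)
}

#' Rarefaction-resampled observed richness
#'
#' Mean number of taxa with nonzero counts over repeated rarefactions to a
#' common depth.
#'
#' @param table count matrix (samples x taxa).
#' @param depth rarefaction depth.
#' @param n_resamples number of independent rarefactions (default 100).
#' @param seed integer seed.
#' @return named numeric vector of per-sample mean richness (samples below
#'   `depth` are dropped).
#' @export
resampled_richness <- function(table, depth, n_resamples = 100, seed = NULL) {
  table <- as_count_table(table)
  keep <- rowSums(table) >= depth
  if (!any(keep)) stop("all samples fall below the rarefaction depth")
  kept <- table[keep, , drop = FALSE]
  with_seed(seed, {
    acc <- numeric(nrow(kept))
    for (r in seq_len(n_resamples))
      acc <- acc + rowSums(suppressWarnings(vegan::rrarefy(kept, depth)) > 0)
    setNames(acc / n_resamples, rownames(kept))
  })
}
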