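test_that("Bray-Curtis matches the direct formula and vegan agrees", {
  x <- toy_counts(rbind(c(1, 0), c(0, 1), c(6, 2), c(2, 2)))
  d <- bray_curtis(x)
  expect_equal(d["s1", "s2"], 1.0)
  expect_equal(d["s3", "s3"], 0.0)
  expect_equal(d["s3", "s4"], 1 - 8 / 12)
  # every off-diagonal equals the independent formula
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(d[i, j], bray_formula(x[i, ], x[j, ]), tolerance = 1e-12)

  expect_error(bray_curtis(x * -1), "non-negative")
  z <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 1))
  expect_warning(dz <- bray_curtis(z), "all-zero")
  expect_equal(dz["a", "b"], 0)
})

test_that("Bray-Curtis on counts vs relative abundances differs only when row sums differ", {
  set.seed(5)
  # equal row sums by construction: counts and relative abundances agree
  xe <- t(rmultinom(4, 500, prob = runif(10)))
  dimnames(xe) <- list(paste0("s", 1:4), paste0("t", 1:10))
  expect_equal(bray_curtis(xe / rowSums(xe)), bray_curtis(xe),
               tolerance = 1e-12)
  # unequal row sums: generally different
  x <- xe; x[1, ] <- x[1, ] * 3L
  expect_gt(max(abs(bray_curtis(x) - bray_curtis(x / rowSums(x)))), 1e-6)
})

test_that("PCoA recovers closed-form geometry", {
  # three equidistant points: two equal positive eigenvalues, an
  # equilateral triangle of unit side
  d3 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d3) <- 0
  ord <- pcoa(d3)
  pos <- ord$eigenvalues[ord$eigenvalues > 1e-9]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)
  rec <- as.matrix(dist(ord$coordinates))
  expect_equal(unname(rec), unname(d3), tolerance = 1e-9)

  # Euclidean input distances are reproduced exactly
  set.seed(2)
  pts <- matrix(rnorm(14), 7, 2)
  d <- as.matrix(dist(pts)); dimnames(d) <- list(paste0("s", 1:7), paste0("s", 1:7))
  ord <- pcoa(d)
  expect_equal(unname(as.matrix(dist(ord$coordinates))), unname(d),
               tolerance = 1e-9)
  expect_equal(ord$negative_mass, 0, tolerance = 1e-8)

  # duplicated samples land on coincident coordinates
  d2 <- as.matrix(dist(pts[c(1, 1, 2:7), ]))
  dimnames(d2) <- list(paste0("s", 1:8), paste0("s", 1:8))
  ord2 <- pcoa(d2)
  expect_equal(ord2$coordinates[1, ], ord2$coordinates[2, ], tolerance = 1e-9)
})

test_that("Euclidean PERMANOVA equals classical one-way ANOVA F", {
  y <- c(0, 1, 10, 11)
  g <- data.frame(sample_id = paste0("s", 1:4), grp = c("A", "A", "B", "B"))
  d <- as.matrix(dist(y)); dimnames(d) <- list(g$sample_id, g$sample_id)
  res <- permanova(d, g, "grp", n_perm = 99, seed = 1)
  expect_equal(res$pseudo_f[1], 200, tolerance = 1e-9)

  # random balanced designs: pseudo-F == anova F to 1e-9
  set.seed(7)
  for (rep in 1:5) {
    yy <- rnorm(12)
    gg <- data.frame(sample_id = paste0("s", 1:12),
                     grp = rep(c("A", "B", "C"), each = 4))
    dd <- as.matrix(dist(yy)); dimnames(dd) <- list(gg$sample_id, gg$sample_id)
    f_classic <- anova(lm(yy ~ gg$grp))[1, "F value"]
    res <- permanova(dd, gg, "grp", n_perm = 9, seed = 1)
    expect_equal(res$pseudo_f[1], f_classic, tolerance = 1e-9)
  }
})

test_that("PERMANOVA agrees with vegan::adonis2 on multivariate data", {
  sim <- simulate_paired_assay(small_config(seed = 13))
  smp <- sim$metadata$sample_id[!sim$metadata$is_negative_control]
  x <- sim$assay$dna[smp, ]
  rel <- x / rowSums(x)
  dm <- bray_curtis(rel)
  md <- sim$metadata[match(smp, sim$metadata$sample_id), ]
  res <- permanova(dm, md, c("planted", "drought"), n_perm = 49, seed = 2)
  ref <- vegan::adonis2(as.dist(dm) ~ planted + drought, data = md,
                        permutations = 49, by = "terms")
  expect_equal(res$pseudo_f[1:2], ref$F[1:2], tolerance = 1e-8)
  expect_equal(res$r_squared[1:2], ref$R2[1:2], tolerance = 1e-8)
  expect_equal(res$sum_of_squares[1:2], ref$SumOfSqs[1:2], tolerance = 1e-8)
  # sequential R2 partition sums to one
  expect_equal(sum(res$r_squared[1:3]), 1, tolerance = 1e-12)
})

test_that("exhaustive permutation p equals complete enumeration", {
  set.seed(3)
  y <- c(0.2, 1.1, 0.7, 3.0, 2.6, 3.4)
  md <- data.frame(sample_id = paste0("s", 1:6),
                   grp = rep(c("A", "B"), each = 3))
  d <- as.matrix(dist(y)); dimnames(d) <- list(md$sample_id, md$sample_id)
  res <- permanova(d, md, "grp", exhaustive = TRUE)

  # oracle: enumerate all 720 permutations, computing the classical F
  idx <- 1:6
  all_p <- as.matrix(expand.grid(rep(list(idx), 6)))
  all_p <- all_p[apply(all_p, 1, function(r) length(unique(r)) == 6), ]
  f_of <- function(yy) anova(lm(yy ~ md$grp))[1, "F value"]
  f_obs <- f_of(y)
  f_all <- apply(all_p, 1, function(p) f_of(y[p]))
  expect_equal(res$p_value[1], mean(f_all >= f_obs - 1e-12), tolerance = 1e-12)
  expect_equal(res$n_permutations[1], 720)
})

test_that("PERMANOVA rejects confounded designs by name", {
  md <- data.frame(sample_id = paste0("s", 1:6),
                   a = rep(c("x", "y"), each = 3),
                   b = rep(c("x", "y"), each = 3))
  d <- as.matrix(dist(rnorm(6))); dimnames(d) <- list(md$sample_id, md$sample_id)
  expect_error(permanova(d, md, c("a", "b"), n_perm = 9), "aliased.*b")
})

test_that("pairwise PERMANOVA covers all level pairs with BH q-values", {
  sim <- simulate_paired_assay(small_config(seed = 17))
  smp <- sim$metadata$sample_id[!sim$metadata$is_negative_control]
  rel <- sim$assay$dna[smp, ] / rowSums(sim$assay$dna[smp, ])
  dm <- bray_curtis(rel)
  md <- sim$metadata[match(smp, sim$metadata$sample_id), ]
  pw <- pairwise_permanova(dm, md, "drought", n_perm = 49, seed = 4)
  expect_equal(nrow(pw), 3)    # pre-drought/drought/watered pairs
  expect_true(all(pw$q_value >= pw$p_value - 1e-12))
  ord <- order(pw$p_value)
  expect_true(all(diff(pw$q_value[ord]) >= -1e-12))
})

test_that("PERMDISP: symmetry gives F = 0; centroid mode matches arithmetic", {
  # mirror copies of one cloud: identical within-group distance multisets
  set.seed(8)
  pts <- matrix(rnorm(20), 10, 2)
  both <- rbind(pts, -pts)
  d <- as.matrix(dist(both))
  dimnames(d) <- list(paste0("s", 1:20), paste0("s", 1:20))
  g <- rep(c("a", "b"), each = 10)
  pd <- permdisp(d, g, n_perm = 99, seed = 1)
  expect_lt(pd$f_value, 1e-12)
  expect_equal(unname(pd$group_means[1]), unname(pd$group_means[2]),
               tolerance = 1e-9)

  # centroid mode on a 1-D embedding equals |x - group mean|
  y <- c(1, 2, 6, 4, 5, 12)
  gy <- rep(c("a", "b"), each = 3)
  dy <- as.matrix(dist(y)); dimnames(dy) <- list(paste0("s", 1:6), paste0("s", 1:6))
  pdc <- permdisp(dy, gy, n_perm = 99, seed = 1, center = "centroid")
  expect_equal(unname(pdc$distances),
               abs(y - ave(y, gy)), tolerance = 1e-9)

  expect_error(permdisp(dy, c("a", "a", "a", "a", "a", "b"), n_perm = 9),
               "size one")
})

test_that("PERMDISP agrees with vegan::betadisper on Euclidean embeddings", {
  set.seed(9)
  pts <- rbind(matrix(rnorm(24, sd = 1), 12, 2),
               matrix(rnorm(24, sd = 3), 12, 2))
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:24), paste0("s", 1:24))
  g <- rep(c("tight", "wide"), each = 12)

  pdc <- permdisp(d, g, n_perm = 99, seed = 2, center = "centroid")
  ref <- vegan::betadisper(as.dist(d), g, type = "centroid")
  expect_equal(unname(pdc$distances), unname(ref$distances), tolerance = 1e-8)
  f_ref <- anova(ref)[1, "F value"]
  expect_equal(pdc$f_value, f_ref, tolerance = 1e-8)

  pdm <- permdisp(d, g, n_perm = 99, seed = 2, center = "median")
  refm <- vegan::betadisper(as.dist(d), g, type = "median")
  expect_equal(unname(pdm$distances), unname(refm$distances), tolerance = 1e-3)
})

test_that("PERMDISP is invariant to rigid motions of the configuration", {
  set.seed(10)
  pts <- matrix(rnorm(30), 15, 2)
  g <- rep(c("a", "b", "c"), each = 5)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- pts %*% rot + matrix(c(5, -3), 15, 2, byrow = TRUE)
  d1 <- as.matrix(dist(pts)); d2 <- as.matrix(dist(moved))
  dimnames(d1) <- dimnames(d2) <- list(paste0("s", 1:15), paste0("s", 1:15))
  p1 <- permdisp(d1, g, n_perm = 49, seed = 3)
  p2 <- permdisp(d2, g, n_perm = 49, seed = 3)
  expect_equal(p1$f_value, p2$f_value, tolerance = 1e-8)
  expect_equal(p1$p_value, p2$p_value)
})

test_that("resampled richness matches exact and hypergeometric expectations", {
  m <- toy_counts(matrix(c(10L, 10L, 10L), 1, 3))
  expect_equal(unname(resampled_richness(m, depth = 30, n_resamples = 5,
                                         seed = 1)), 3)

  m2 <- toy_counts(matrix(c(1000L, 1L), 1, 2))
  r <- resampled_richness(m2, depth = 10, n_resamples = 1000, seed = 2)
  # P(rare taxon sampled) = 1 - C(1000,10)/C(1001,10) = 10/1001
  expected <- 1 + 10 / 1001
  se <- sqrt((10 / 1001) * (1 - 10 / 1001) / 1000)
  expect_lt(abs(unname(r) - expected), 4 * se)
  expect_true(r > 1 && r < 2)
})
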