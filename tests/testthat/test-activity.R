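toy_paired <- function(dna, cdna) {
  pair_assays(toy_counts(dna), toy_counts(cdna))
}

test_that("classify_activity matches the exhaustive truth-table oracle", {
  # 3 samples x 6 taxa covering every case: active at / above / below the
  # threshold, cDNA absent, phantom above and below the prevalence cut
  dna  <- rbind(c(3, 5, 6, 0, 0, 0),
                c(2, 9, 1, 0, 4, 0),
                c(1, 4, 2, 0, 2, 0))
  cdna <- rbind(c(3, 2, 0, 4, 1, 0),
                c(4, 3, 0, 2, 8, 0),
                c(0, 1, 0, 9, 1, 0))
  pa <- toy_paired(dna, cdna)
  for (th in c(0.5, 1, 2)) for (pp in c(0.05, 0.5)) {
    at <- classify_activity(pa, ratio_threshold = th, phantom_prevalence = pp)
    orc <- oracle_classify(pa$dna, pa$cdna, th, pp)
    expect_identical(at$state, orc$state)
    expect_identical(at$active_counts, orc$active)
  }
})

test_that("the spec'd single cells classify as required", {
  # taxon t4 is phantom in 2 of 3 samples (prevalence 0.67), t5 in 1 of 3
  dna  <- rbind(c(3, 5, 6, 0, 0), c(2, 9, 1, 0, 4), c(5, 1, 7, 2, 3))
  cdna <- rbind(c(3, 2, 0, 4, 2), c(4, 3, 0, 2, 8), c(5, 9, 0, 2, 3))
  at <- classify_activity(toy_paired(dna, cdna), ratio_threshold = 1,
                          phantom_prevalence = 0.5)
  expect_equal(at$state["s1", "t1"], "active")          # ratio exactly 1
  expect_equal(at$active_counts["s1", "t1"], 3L)
  expect_equal(at$state["s1", "t2"], "inactive")        # ratio 0.4
  expect_equal(at$active_counts["s1", "t2"], 0L)
  expect_equal(at$state["s1", "t4"], "phantom_rescued") # prevalence 2/3
  expect_equal(at$active_counts["s1", "t4"], 1L)
  expect_equal(at$state["s1", "t5"], "phantom_dropped") # prevalence 1/3
  expect_equal(at$state["s1", "t3"], "inactive")        # DNA only
  expect_equal(at$state["s2", "t3"], "inactive")
})

test_that("raising the ratio threshold shrinks the active set monotonically", {
  sim <- simulate_paired_assay(small_config(seed = 21))
  assay <- rarefy_assay(sim$assay, depth = 2500, seed = 3)
  sets <- lapply(c(0.5, 1, 2), function(th) {
    at <- classify_activity(assay, ratio_threshold = th)
    which(at$state %in% c("active", "phantom_rescued"))
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
  expect_gt(length(sets[[1]]), length(sets[[3]]))
})

test_that("rarefaction hits the exact depth and drops shallow samples", {
  m <- toy_counts(rbind(c(12000, 6000, 2000), c(8000, 4000, 2999),
                        c(9000, 4000, 2000)))
  expect_message(r <- rarefy(m, depth = 15000, seed = 1), "s2")
  expect_equal(attr(r, "dropped"), "s2")
  expect_equal(unname(rowSums(r)), c(15000, 15000))
  # a sample at exactly the depth is returned unchanged
  expect_identical(unname(r["s3", ]), unname(m["s3", ]))
  # per-seed determinism
  r2 <- rarefy(m, depth = 15000, seed = 1)
  expect_identical(r[, ], r2[, ])
  expect_error(rarefy(m, depth = 1e6), "below the rarefaction depth")
})

test_that("rarefaction preserves expected relative abundances", {
  x <- toy_counts(matrix(c(1000L, 500L, 100L, 10L), 1, 4))
  p0 <- x[1, ] / sum(x)
  reps <- 1000
  rel <- matrix(0, reps, 4)
  set.seed(99)
  for (r in seq_len(reps)) rel[r, ] <- rarefy(x, depth = 800)[1, ] / 800
  se <- apply(rel, 2, sd) / sqrt(reps)
  expect_true(all(abs(colMeans(rel) - p0) <= 3 * pmax(se, 1e-12)))
})

test_that("activity summary arithmetic and degenerate inputs", {
  dna  <- rbind(c(rep(2, 10)), rep(0, 10))
  cdna <- rbind(c(rep(3, 4), rep(1, 6)), rep(0, 10))
  at <- classify_activity(toy_paired(dna * c(1, 0), cdna * c(1, 0)))
  s <- activity_summary(at)
  expect_equal(s$percent_active[1], 40)      # 4 active of 10 observed
  expect_true(is.na(s$percent_active[2]))    # nothing observed
  expect_equal(s$active_reads[1], 8)         # 4 active cells of DNA 2
})

test_that("heatmap coding follows the NA/0/count/1 scheme with max scaling", {
  dna  <- rbind(c(0, 0), c(5, 0), c(7, 0), c(14, 3))
  cdna <- rbind(c(0, 2), c(0, 2), c(2, 2), c(3, 0))
  at <- classify_activity(toy_paired(dna, cdna), phantom_prevalence = 0.05)
  hm <- heatmap_code_and_standardize(at)
  expect_equal(unname(hm[, "t1"]), c(NA, 0, 0.5, 1.0))
  # phantom cells code as 1 before standardization (t2: 1,1,1,0; max 1)
  expect_equal(unname(hm[, "t2"]), c(1, 1, 1, 0))
  expect_true(all(hm >= 0 & hm <= 1, na.rm = TRUE))

  expect_error(heatmap_code_and_standardize(at, character()), "empty")
  # an all-missing taxon warns and stays missing
  dna2 <- cbind(dna, t3 = c(0, 0, 0, 0)); cdna2 <- cbind(cdna, t3 = c(0, 0, 0, 0))
  at2 <- classify_activity(toy_paired(dna2, cdna2))
  expect_warning(hm2 <- heatmap_code_and_standardize(at2), "all-missing")
  expect_true(all(is.na(hm2[, "t3"])))
})

test_that("percent active on synthetic defaults sits in the reported band", {
  sim <- simulate_paired_assay(simulation_config(crops = "bean", rng_seed = 31))
  smp <- sim$metadata$sample_id[!sim$metadata$is_negative_control]
  assay <- sim$assay
  assay$dna <- assay$dna[smp, ]; assay$cdna <- assay$cdna[smp, ]
  assay <- rarefy_assay(assay, 15000, seed = 5)
  s <- activity_summary(classify_activity(assay))
  expect_gte(mean(s$percent_active, na.rm = TRUE), 40)
  expect_lte(mean(s$percent_active, na.rm = TRUE), 60)
})
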