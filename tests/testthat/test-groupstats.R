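test_that("group means behave like pixelwise averages", {
  m <- matrix(rnorm(36), 6, 6)
  expect_equal(group_mean(list(m, m, m)), m)
  expect_equal(group_mean(list(m, -m)), matrix(0, 6, 6))
  ms <- null_maps(5, 6, 6, seed = 2)
  expect_equal(group_mean(ms), group_mean(rev(ms)))
  expect_error(group_mean(list(m, matrix(0, 3, 3))), "grid")
})

test_that("FDR masking controls the false-discovery fraction under the null", {
  q <- 0.05
  fdp <- vapply(1:150, function(rep) {
    maps <- null_maps(19, 12, 12, seed = 1000 + rep)
    res <- pixel_ttest_fdr(maps, q = q)
    n_disc <- sum(res$fdr_mask)
    if (n_disc == 0) 0 else 1   # every discovery under the null is false
  }, 0)
  expect_lte(mean(fdp), q + 2 * sqrt(q * (1 - q) / 150))
})

test_that("FDR masking detects a constant offset and masks nest across q", {
  maps <- null_maps(19, 12, 12, seed = 7)
  hot <- cbind(rep(2:4, each = 4), rep(3:6, 3))[1:10, ]
  maps <- lapply(maps, function(m) { m[hot] <- m[hot] + 1.5; m })
  res01 <- pixel_ttest_fdr(maps, q = 0.01)
  res05 <- pixel_ttest_fdr(maps, q = 0.05)
  expect_gte(sum(res01$fdr_mask[hot]), 8)
  expect_true(all(res05$fdr_mask[res01$fdr_mask]))   # nesting
  # masked mean zeroes non-significant pixels
  expect_true(all(res01$masked_mean[!res01$fdr_mask] == 0))
  expect_error(pixel_ttest_fdr(null_maps(2)), "at least 3")
  expect_warning(res0 <- pixel_ttest_fdr(list(matrix(0, 4, 4),
                                              matrix(0, 4, 4),
                                              matrix(0, 4, 4))),
                 "zero variance")
  expect_false(any(res0$fdr_mask))
})

test_that("cluster labeling distinguishes 4- and 8-connectivity", {
  mask <- matrix(FALSE, 5, 5)
  mask[1:2, 1:2] <- TRUE       # one 4-connected blob
  mask[4:5, 4:5] <- TRUE       # second blob, touching the first diagonally?
  mask[3, 3] <- TRUE           # bridge pixel touching both only diagonally
  lab4 <- aciglm:::label_components(mask, 4)
  lab8 <- aciglm:::label_components(mask, 8)
  expect_equal(max(lab4), 3L)  # diagonal touches do not merge
  expect_equal(max(lab8), 1L)  # with 8-connectivity they do
})

test_that("the cluster permutation test finds injected differences and not null ones", {
  g1 <- null_maps(8, 12, 12, seed = 11)
  g2 <- null_maps(8, 12, 12, seed = 12)
  region <- as.matrix(expand.grid(4:6, 7:9))
  g2_eff <- lapply(g2, function(m) { m[region] <- m[region] + 2; m })
  res <- cluster_permutation_test(g1, g2_eff, alpha_threshold = 0.05,
                                  n_permutations = 300, seed = 5)
  expect_true(nrow(res$clusters) >= 1)
  top <- which.max(res$clusters$mass)
  expect_lt(res$clusters$p[top], 0.05)
  # the winning cluster overlaps the injected region
  reg_idx <- (region[, 2] - 1) * 12 + region[, 1]
  expect_gt(length(intersect(which(res$cluster_map == top), reg_idx)), 0)
  # identical groups produce no suprathreshold pixels at all
  none <- cluster_permutation_test(g1, g1, n_permutations = 120, seed = 5)
  expect_equal(nrow(none$clusters), 0L)
  expect_warning(cluster_permutation_test(g1, g2, n_permutations = 50,
                                          seed = 1), "permutations")
})

test_that("cluster results are invariant to relabeling both groups identically", {
  g1 <- null_maps(6, 10, 10, seed = 21)
  g2 <- lapply(null_maps(6, 10, 10, seed = 22),
               function(m) m + 0.7)
  a <- cluster_permutation_test(g1, g2, n_permutations = 200, seed = 9)
  b <- cluster_permutation_test(g1[c(3, 1, 2, 6, 5, 4)],
                                g2[c(2, 1, 4, 3, 6, 5)],
                                n_permutations = 200, seed = 9)
  expect_equal(sort(a$clusters$mass), sort(b$clusters$mass))
  expect_equal(a$t_threshold, b$t_threshold)
})

test_that("weight sets obey the size threshold, connectivity and annotations", {
  base <- null_maps(19, 16, 12, seed = 31)
  blob <- as.matrix(expand.grid(5:9, 4:5))          # 10 pixels, 4-connected
  small_blob <- as.matrix(expand.grid(12:14, 8:9))  # 6 pixels only
  maps <- lapply(base, function(m) {
    m <- m * 0.3
    m[blob] <- m[blob] + 3
    m[small_blob] <- m[small_blob] + 3
    m
  })
  sets <- extract_weight_sets(maps, p_threshold = 1e-10, min_size = 7,
                              time_bin = 0.02,
                              center_freqs = small_fb()$center_freqs)
  expect_length(sets, 1L)                    # the 6-pixel blob is excluded
  expect_equal(sets[[1]]$size, 10L)
  expect_equal(sets[[1]]$sign, "positive")
  expect_equal(sort(sets[[1]]$pixels), sort((blob[, 2] - 1) * 16 + blob[, 1]))
  # centroid in physical units: frame centers (ms), channel centers (Hz)
  expect_equal(sets[[1]]$centroid[["t"]], mean((5:9 - 0.5) * 20))
  expect_equal(sets[[1]]$extent[["dt"]], 5 * 20)
  # two blobs touching only diagonally stay distinct under 4-connectivity
  blob2 <- as.matrix(expand.grid(1:4, 7:8))
  diag_blob <- cbind(blob2[, 1] + 4, blob2[, 2] + 2)  # corners touch
  maps2 <- lapply(base, function(m) {
    m <- m * 0.3; m[blob2] <- m[blob2] + 3; m[diag_blob] <- m[diag_blob] + 3; m
  })
  sets2 <- extract_weight_sets(maps2, p_threshold = 1e-10, min_size = 7)
  expect_length(sets2, 2L)
  # deterministic given identical input
  expect_identical(lapply(sets2, `[[`, "pixels"),
                   lapply(extract_weight_sets(maps2, p_threshold = 1e-10,
                                              min_size = 7),
                          `[[`, "pixels"))
})

test_that("ROI tests flag only genuinely amplified sets", {
  base <- null_maps(10, 12, 12, seed = 41)
  blobA <- as.matrix(expand.grid(2:4, 2:4))
  blobB <- as.matrix(expand.grid(8:10, 8:10))
  mk <- function(seed, boost) {
    lapply(null_maps(10, 12, 12, seed = seed), function(m) {
      m <- m * 0.3
      m[blobA] <- m[blobA] + 3
      m[blobB] <- m[blobB] + 3 * boost
      m
    })
  }
  g1 <- mk(42, 1)
  g2 <- mk(43, 1.8)
  sets <- extract_weight_sets(c(g1, g2), p_threshold = 1e-10, min_size = 7)
  expect_gte(length(sets), 2L)
  roi <- roi_group_test(sets, g1, g2)
  expect_equal(nrow(roi), length(sets))
  # locate the amplified set among the extracted ones
  idxB <- which(vapply(sets, function(s) {
    all(((blobB[, 2] - 1) * 12 + blobB[, 1]) %in% s$pixels)
  }, TRUE))
  expect_length(idxB, 1L)
  expect_lt(roi$p[idxB], 0.01)
  # identical groups: nothing systematically significant
  roi_null <- roi_group_test(sets, g1, g1)
  expect_true(all(roi_null$p > 0.99))   # identical samples, t = 0
  expect_equal(nrow(roi_group_test(list(), g1, g2)), 0L)
})
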