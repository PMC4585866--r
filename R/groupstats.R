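# Group-level inference on classification images: mean maps, pixelwise
# one-sample t-tests with FDR correction, cluster-based permutation tests
# for group differences, and extraction/characterization of weight sets
# (regions of consistently non-zero weights across listeners).

map_stack <- function(maps) {
  dims <- dim(maps[[1]])
  for (m in maps) {
    if (!identical(dim(m), dims)) stop("maps must share one grid")
  }
  t(vapply(maps, as.vector, numeric(prod(dims))))
}

#' Group-average classification image
#'
#' Pixelwise arithmetic mean of individually z-scored maps.
#'
#' @param z_maps list of matrices on a shared grid.
#' @return mean map (matrix).
#' @export
group_mean <- function(z_maps) {
  stopifnot(length(z_maps) >= 1)
  S <- map_stack(z_maps)
  matrix(colMeans(S), nrow = nrow(z_maps[[1]]), ncol = ncol(z_maps[[1]]))
}

# vectorized one-sample t over pixels of a stacked map matrix (n x p)
one_sample_t <- function(S) {
  n <- nrow(S)
  m <- colMeans(S)
  sd_ <- sqrt(colSums(sweep(S, 2, m)^2) / (n - 1))
  t_ <- m / (sd_ / sqrt(n))
  p_ <- 2 * stats::pt(-abs(t_), df = n - 1)
  list(t = t_, p = p_, mean = m)
}

# vectorized two-sample (pooled) t per pixel for group matrices
two_sample_t <- function(S1, S2) {
  n1 <- nrow(S1); n2 <- nrow(S2)
  m1 <- colMeans(S1); m2 <- colMeans(S2)
  v1 <- colSums(sweep(S1, 2, m1)^2)
  v2 <- colSums(sweep(S2, 2, m2)^2)
  sp <- sqrt((v1 + v2) / (n1 + n2 - 2) * (1 / n1 + 1 / n2))
  (m1 - m2) / sp
}

#' Pixelwise one-sample t-test with FDR correction
#'
#' Tests each pixel of the group's z-scored maps against zero and masks
#' the t-map by Benjamini-Hochberg FDR at rate `q`. The returned masked
#' mean map has non-significant pixels set to zero, matching the standard
#' display of group classification images.
#'
#' @param z_maps list of at least 3 maps on a shared grid.
#' @param q FDR level (default 0.01).
#' @return list with `t_map`, `p_map`, `fdr_mask` (logical), and
#'   `masked_mean` (all matrices on the grid).
#' @export
pixel_ttest_fdr <- function(z_maps, q = 0.01) {
  if (length(z_maps) < 3) stop("need at least 3 maps for pixelwise t-tests")
  S <- map_stack(z_maps)
  ts <- one_sample_t(S)
  dims <- dim(z_maps[[1]])
  if (all(!is.finite(ts$t))) {
    warning("t undefined at every pixel (zero variance); empty mask")
    mask <- rep(FALSE, length(ts$t))
  } else {
    padj <- stats::p.adjust(ts$p, method = "BH")
    mask <- !is.na(padj) & padj <= q
  }
  mean_map <- matrix(ts$mean, dims[1], dims[2])
  list(t_map = matrix(ts$t, dims[1], dims[2]),
       p_map = matrix(ts$p, dims[1], dims[2]),
       fdr_mask = matrix(mask, dims[1], dims[2]),
       masked_mean = mean_map * matrix(mask, dims[1], dims[2]))
}

# Label connected components of a logical matrix (4- or 8-connectivity).
# Union-find over the TRUE pixels only.
label_components <- function(mask, connectivity = 4) {
  nt <- nrow(mask); nf <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nt, nf)
  if (length(idx) == 0) return(lab)
  pos <- match(seq_len(nt * nf), idx)      # matrix index -> pixel rank
  parent <- seq_along(idx)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[ra] <<- rb
  }
  rr <- ((idx - 1) %% nt) + 1
  cc <- ((idx - 1) %/% nt) + 1
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) {
    offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  }
  for (k in seq_along(idx)) {
    for (o in offs) {
      r2 <- rr[k] + o[1]; c2 <- cc[k] + o[2]
      if (r2 >= 1 && r2 <= nt && c2 >= 1 && c2 <= nf) {
        j <- (c2 - 1L) * nt + r2
        if (!is.na(pos[j])) union_(k, pos[j])
      }
    }
  }
  roots <- vapply(seq_along(idx), find, 0L)
  lab[idx] <- match(roots, unique(roots))
  lab
}

#' Cluster-based permutation test for a group difference
#'
#' Pixelwise two-sample t between the groups' maps; pixels with |t|
#' exceeding the two-sided `alpha_threshold` quantile are grouped into
#' connected clusters whose mass is the sum of |t|. The null distribution
#' of the maximum cluster mass is built by randomly relabeling listeners
#' across groups; each observed cluster's p-value is the proportion of
#' null maxima at least as large (with the observed statistic included,
#' so p is never exactly 0).
#'
#' @param maps_group1,maps_group2 lists of >= 2 maps each, shared grid.
#' @param alpha_threshold pixel-inclusion alpha (two-sided).
#' @param n_permutations number of random relabelings.
#' @param seed permutation seed.
#' @param connectivity 4 (default) or 8.
#' @return list with `clusters` (data.frame: id, size, mass, p),
#'   `cluster_map` (integer matrix), `t_map`, `t_threshold`, `null_max`.
#' @export
cluster_permutation_test <- function(maps_group1, maps_group2,
                                     alpha_threshold = 0.05,
                                     n_permutations = 1000, seed = 1L,
                                     connectivity = 4) {
  stopifnot(length(maps_group1) >= 2, length(maps_group2) >= 2)
  if (n_permutations < 100) {
    warning("fewer than 100 permutations gives a coarse null distribution")
  }
  S1 <- map_stack(maps_group1); S2 <- map_stack(maps_group2)
  n1 <- nrow(S1); n2 <- nrow(S2)
  dims <- dim(maps_group1[[1]])
  S <- rbind(S1, S2)
  t_thr <- stats::qt(1 - alpha_threshold / 2, df = n1 + n2 - 2)

  max_mass <- function(tv) {
    supra <- abs(tv) > t_thr
    if (!any(supra)) return(0)
    lab <- label_components(matrix(supra, dims[1], dims[2]), connectivity)
    masses <- as.numeric(rowsum(abs(tv)[supra], lab[lab > 0]))
    max(masses)
  }

  t_obs <- two_sample_t(S1, S2)
  supra <- abs(t_obs) > t_thr
  cluster_map <- label_components(matrix(supra, dims[1], dims[2]),
                                  connectivity)
  n_clusters <- max(cluster_map)
  obs_mass <- if (n_clusters > 0) {
    as.numeric(rowsum(abs(t_obs)[cluster_map > 0],
                      cluster_map[cluster_map > 0]))
  } else numeric(0)

  null_max <- with_seed(derive_seed(seed, 31L), {
    vapply(seq_len(n_permutations), function(b) {
      pick <- sample.int(n1 + n2, n1)
      max_mass(two_sample_t(S[pick, , drop = FALSE],
                            S[-pick, , drop = FALSE]))
    }, 0)
  })

  p_vals <- vapply(obs_mass, function(m) {
    (1 + sum(null_max >= m)) / (1 + n_permutations)
  }, 0)
  sizes <- if (n_clusters > 0) tabulate(cluster_map[cluster_map > 0]) else integer(0)
  list(
    clusters = data.frame(id = seq_len(n_clusters), size = sizes,
                          mass = obs_mass, p = p_vals),
    cluster_map = cluster_map,
    t_map = matrix(t_obs, dims[1], dims[2]),
    t_threshold = t_thr,
    null_max = null_max
  )
}

#' Extract weight sets from pooled maps
#'
#' Pools all listeners' z-scored maps (regardless of group), tests each
#' pixel against zero, keeps pixels with p below `p_threshold`, and
#' returns the connected components of at least `min_size` pixels. Each
#' set is annotated with its size, sign (of the mean pooled weight),
#' centroid, and temporal/spectral extent in physical units when grid
#' metadata is given.
#'
#' @param all_maps list of >= 3 maps (pooled across groups).
#' @param p_threshold inclusion threshold on the per-pixel p-value.
#' @param min_size minimum pixels per set.
#' @param connectivity 4 (default) or 8.
#' @param time_bin frame duration in seconds (for ms annotations).
#' @param center_freqs channel center frequencies in Hz.
#' @return list of `weight_set` objects, each a list with `id`, `pixels`
#'   (matrix indices), `size`, `sign`, `centroid` (t_ms, f_hz), `extent`
#'   (dt_ms, df_hz), `mean_weight`; plus attribute `p_map`.
#' @export
extract_weight_sets <- function(all_maps, p_threshold = 1e-10, min_size = 7,
                                connectivity = 4, time_bin = NULL,
                                center_freqs = NULL) {
  if (length(all_maps) < 3) stop("need at least 3 maps")
  S <- map_stack(all_maps)
  ts <- one_sample_t(S)
  dims <- dim(all_maps[[1]])
  mask <- matrix(!is.na(ts$p) & ts$p < p_threshold, dims[1], dims[2])
  lab <- label_components(mask, connectivity)
  mean_map <- matrix(ts$mean, dims[1], dims[2])
  sets <- list()
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_size)
    ord <- keep[order(-sizes[keep])]
    for (s_id in seq_along(ord)) {
      comp <- ord[s_id]
      pix <- which(lab == comp)
      tt <- ((pix - 1) %% dims[1]) + 1
      ff <- ((pix - 1) %/% dims[1]) + 1
      t_ms <- if (!is.null(time_bin)) (tt - 0.5) * time_bin * 1000 else tt
      f_hz <- if (!is.null(center_freqs)) center_freqs[ff] else ff
      dt <- if (!is.null(time_bin)) {
        (diff(range(tt)) + 1) * time_bin * 1000
      } else diff(range(tt)) + 1
      sets[[s_id]] <- structure(list(
        id = s_id, pixels = pix, size = length(pix),
        sign = if (mean(mean_map[pix]) >= 0) "positive" else "negative",
        centroid = c(t = mean(t_ms), f = mean(f_hz)),
        extent = c(dt = dt, df = diff(range(f_hz))),
        mean_weight = mean(mean_map[pix])
      ), class = "weight_set")
    }
  }
  attr(sets, "p_map") <- matrix(ts$p, dims[1], dims[2])
  sets
}

#' ROI group comparison on weight sets
#'
#' For each weight set, averages each listener's map over the set's
#' pixels and compares the two groups with a two-sample t-test. Reported
#' uncorrected (as is conventional for these set tables), with a
#' Bonferroni column for transparency.
#'
#' @param weight_sets list from [extract_weight_sets()].
#' @param maps_group1,maps_group2 lists of maps per group.
#' @return data.frame: one row per set with size, sign, centroid, extent,
#'   per-group mean/SD of the set weight, t, p, p_bonferroni.
#' @export
roi_group_test <- function(weight_sets, maps_group1, maps_group2) {
  if (length(weight_sets) == 0) {
    return(data.frame(id = integer(0), size = integer(0),
                      sign = character(0), centroid_t = numeric(0),
                      centroid_f = numeric(0), extent_t = numeric(0),
                      extent_f = numeric(0), mean_g1 = numeric(0),
                      sd_g1 = numeric(0), mean_g2 = numeric(0),
                      sd_g2 = numeric(0), t = numeric(0), p = numeric(0),
                      p_bonferroni = numeric(0)))
  }
  rows <- lapply(weight_sets, function(ws) {
    w1 <- vapply(maps_group1, function(m) mean(m[ws$pixels]), 0)
    w2 <- vapply(maps_group2, function(m) mean(m[ws$pixels]), 0)
    tt <- stats::t.test(w1, w2, var.equal = TRUE)
    data.frame(id = ws$id, size = ws$size, sign = ws$sign,
               centroid_t = ws$centroid[["t"]], centroid_f = ws$centroid[["f"]],
               extent_t = ws$extent[["dt"]], extent_f = ws$extent[["df"]],
               mean_g1 = mean(w1), sd_g1 = stats::sd(w1),
               mean_g2 = mean(w2), sd_g2 = stats::sd(w2),
               t = unname(tt$statistic), p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}
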