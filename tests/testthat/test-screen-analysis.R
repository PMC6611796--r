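test_that("robust Z matches direct median/MAD arithmetic", {
  mock <- data.frame(net_area = c(10, 12, 14, 16, 18))
  trt <- data.frame(net_area = 20)
  z <- robust_z(trt, mock, params = "net_area")
  expect_equal(unname(z), (20 - 14) / (1.4826 * 2), tolerance = 1e-12)

  degen <- data.frame(net_area = rep(5, 12))
  expect_error(robust_z(trt, degen, params = "net_area"),
               "net_area")
})

test_that("robust Z is invariant under positive affine plate transforms", {
  set.seed(1)
  mock <- data.frame(net_area = rlnorm(40, log(1e4), 0.2))
  trt <- data.frame(net_area = rlnorm(25, log(8e3), 0.2))
  z0 <- robust_z(trt, mock, "net_area")
  for (a in c(0.5, 2, 17)) {
    for (b in c(-100, 0, 250)) {
      z1 <- robust_z(transform(trt, net_area = a * net_area + b),
                     transform(mock, net_area = a * net_area + b),
                     "net_area")
      expect_equal(unname(z1), unname(z0), tolerance = 1e-9)
    }
  }
})

test_that("well QC applies the 10-track minimum with inclusive boundary", {
  prof <- data.frame(n_tracks = 0:11, qc_pass = TRUE)
  out <- apply_well_qc(prof)
  expect_equal(sum(!out$qc_pass), 10)     # counts 0..9 fail
  expect_true(out$qc_pass[out$n_tracks == 10])
  expect_false(out$qc_pass[out$n_tracks == 9])
})

test_that("replicate aggregation averages Z and applies knockdown QC", {
  mk <- function(trt, z, n_tracks, n_images) {
    data.frame(plate_id = paste0("P", seq_along(z)), well_id = "B2",
               treatment = trt, sirna_kind = "smartpool",
               technical = 1, biological = 1, cell_line = "Hs578T",
               n_tracks = n_tracks, n_images = n_images, qc_pass = TRUE,
               raw_net_area = 1e4, z_net_area = z)
  }
  prof <- mk("G1", c(1, 2, 3, 2), c(20, 20, 20, 20), c(9, 9, 9, 9))
  agg <- aggregate_replicates(prof, cell_line = "Hs578T",
                              params = "net_area")
  expect_equal(agg$z_net_area, 2)
  expect_true(agg$qc_pass)

  # Hs578T: 59 summed tracks excluded, 60 kept
  a59 <- aggregate_replicates(mk("G1", rep(0, 4), c(15, 15, 15, 14),
                                 rep(9, 4)),
                              cell_line = "Hs578T", params = "net_area")
  a60 <- aggregate_replicates(mk("G1", rep(0, 4), c(15, 15, 15, 15),
                                 rep(9, 4)),
                              cell_line = "Hs578T", params = "net_area")
  expect_false(a59$qc_pass)
  expect_true(a60$qc_pass)

  # MDA-MB-231 uses the 150-track minimum
  m149 <- aggregate_replicates(mk("G1", rep(0, 4), c(38, 37, 37, 37),
                                  rep(9, 4)),
                               cell_line = "MDA-MB-231", params = "net_area")
  m150 <- aggregate_replicates(mk("G1", rep(0, 4), c(38, 38, 37, 37),
                                  rep(9, 4)),
                               cell_line = "MDA-MB-231", params = "net_area")
  expect_false(m149$qc_pass)
  expect_true(m150$qc_pass)

  # fewer than 3 images excluded
  a2 <- aggregate_replicates(mk("G1", rep(0, 2), c(40, 40), c(1, 1)),
                             cell_line = "Hs578T", params = "net_area")
  expect_false(a2$qc_pass)

  expect_error(aggregate_replicates(mk("G1", 0, 60, 9),
                                    cell_line = "T47D",
                                    params = "net_area"),
               "track-count minimum")
})

test_that("phenotype classification matches the printed rules", {
  base <- list(raw_net_area = 10000, raw_axial_ratio = 2.0,
               raw_major_axis = 170, raw_roughness = 6,
               z_net_area = 0, z_axial_ratio = 0, z_major_axis = 0)
  cl <- function(mods) {
    p <- modifyList(base, mods)
    classify_phenotype(p)$primary_class
  }
  expect_equal(cl(list(z_net_area = -5)), "small")
  expect_equal(cl(list(raw_axial_ratio = 2.5, raw_major_axis = 250,
                       raw_roughness = 6, z_axial_ratio = 2,
                       z_major_axis = 2)), "long_rough")
  expect_equal(cl(list(raw_axial_ratio = 2.2, raw_major_axis = 190,
                       raw_roughness = 4)), "long_smooth")
  expect_equal(cl(list(raw_net_area = 7000, raw_axial_ratio = 1.6,
                       z_net_area = -2, z_axial_ratio = -3.5)),
               "small_round")
  expect_equal(cl(list(raw_net_area = 9000, raw_axial_ratio = 1.5,
                       z_net_area = 2, z_axial_ratio = -4.5)),
               "big_round")
  expect_equal(cl(list()), "unclassified")
  expect_error(classify_phenotype(base[-1]), "raw_net_area")
})

test_that("classifier agrees with the brute-force oracle on a grid sample", {
  g <- threshold_grid()
  set.seed(3)
  idx <- sample(nrow(g), 500)
  for (i in idx) {
    p <- list(raw_net_area = g$raw_net[i], raw_axial_ratio = g$raw_axial[i],
              raw_major_axis = g$raw_major[i],
              raw_roughness = g$raw_rough[i],
              z_net_area = g$z_net[i], z_axial_ratio = g$z_axial[i],
              z_major_axis = g$z_major[i])
    got <- classify_phenotype(p)
    expect_identical(got$primary_class,
                     oracle_classify(g$raw_net[i], g$raw_axial[i],
                                     g$raw_major[i], g$raw_rough[i],
                                     g$z_net[i], g$z_axial[i],
                                     g$z_major[i]))
    expect_identical(got$all_matching_classes,
                     oracle_classify_all(g$raw_net[i], g$raw_axial[i],
                                         g$raw_major[i], g$raw_rough[i],
                                         g$z_net[i], g$z_axial[i],
                                         g$z_major[i]))
  }
})

test_that("hit calling and cross-line overlap follow the same-class rule", {
  calls <- data.frame(
    treatment = c("A", "B", "C", "mock", "A", "B", "C", "mock"),
    cell_line = rep(c("Hs578T", "MDA-MB-231"), each = 4),
    primary_class = c("small", "long_smooth", "unclassified", "small",
                      "small", "small", "small", "unclassified"),
    stringsAsFactors = FALSE)
  out <- call_primary_hits(calls)
  expect_equal(sort(out$hits$treatment[out$hits$cell_line == "Hs578T"]),
               c("A", "B"))
  # A: same class in both lines -> overlap; B: different classes -> not
  expect_equal(out$overlap$treatment, "A")

  empty <- call_primary_hits(calls[calls$primary_class == "unclassified", ])
  expect_equal(nrow(empty$hits), 0)
})

test_that("PCA of phenotype Z matrices is ordered, scaled and sign-fixed", {
  # rank-1 matrix: PC1 carries all variance
  v <- c(1, 2, 3, 4, 5)
  r1 <- outer(v, c(1, -2, 0.5)) + 0
  p1 <- pca_phenotypes(r1)
  expect_equal(p1$explained_variance[1], 1, tolerance = 1e-9)

  # isotropic data: all ratios near 1/p
  set.seed(8)
  iso <- matrix(rnorm(1000 * 8), 1000, 8)
  p2 <- pca_phenotypes(iso)
  expect_true(all(abs(p2$explained_variance - 1 / 8) < 0.25 / 8))
  # sign convention: largest-magnitude loading positive
  for (j in 1:8) {
    expect_gt(p2$loadings[which.max(abs(p2$loadings[, j])), j], 0)
  }

  # two planted clusters separate on PC1
  cl <- rbind(matrix(rnorm(50 * 4, 0), 50, 4),
              matrix(rnorm(50 * 4, 6), 50, 4))
  p3 <- pca_phenotypes(cl)
  s <- p3$scores[, 1]
  gap <- abs(mean(s[1:50]) - mean(s[51:100]))
  pooled_sd <- sqrt((var(s[1:50]) + var(s[51:100])) / 2)
  expect_gt(gap, 3 * pooled_sd)

  const <- cbind(iso[, 1:2], rep(1, 1000))
  expect_warning(pca_phenotypes(const), "constant")
})

test_that("deconvolution validation implements the two-singles contract", {
  pool <- c(net_area = -4, axial_ratio = 0)
  mk <- function(z) c(net_area = z, axial_ratio = 0)
  ok <- validate_deconvolution(pool, lapply(c(-3, -2.5, -0.1, 0.4), mk))
  expect_true(ok$valid)
  expect_equal(ok$n_significant_singles, 2)

  one <- validate_deconvolution(pool, lapply(c(-3, 2.5, -0.1, 0.4), mk))
  expect_false(one$valid)

  null_pool <- validate_deconvolution(c(net_area = 0, axial_ratio = 0),
                                      lapply(c(-3, -3, -3, -3), mk))
  expect_false(null_pool$valid)

  missing <- validate_deconvolution(pool, list(mk(-3), mk(-2.5), NULL, NULL))
  expect_true(missing$valid)
  expect_equal(missing$missing_singles, c(3, 4))
})
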