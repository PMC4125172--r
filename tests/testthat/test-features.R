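# First-order feature engine: voxel collection, percentiles, moments,
# texture, volume/density/mass and the two window sizes.

test_that("collect_voxels returns the in-mask HU multiset and checks shapes", {
  vol <- tiny_volume(c(-800, -700, -600), dims = c(3, 1, 1))
  m <- nodule_mask(array(TRUE, c(3, 1, 1)))
  expect_setequal(collect_voxels(vol, m), c(-800L, -700L, -600L))

  full <- tiny_volume(-500, dims = c(4, 4, 2))
  expect_length(collect_voxels(full, full_mask(full)), 32)

  other <- nodule_mask(array(TRUE, c(2, 2, 2)))
  expect_error(collect_voxels(full, other), "shape mismatch")
})

test_that("percentiles use linear interpolation and shift with translation", {
  p <- histogram_percentiles(1:100)
  expect_equal(unname(p["p50_hu"]), 50.5)
  shifted <- histogram_percentiles(1:100 + 100)
  expect_equal(unname(shifted), unname(p) + 100)
  expect_error(histogram_percentiles(5), "at least 2")
})

test_that("percentiles match a sort-and-interpolate oracle on random samples", {
  set.seed(42)
  probs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  for (i in 1:50) {
    n <- sample(10:1000, 1)
    x <- round(stats::rnorm(n, -600, 150))
    got <- unname(histogram_percentiles(x))
    want <- vapply(probs, function(p) oracle_percentile(x, p), numeric(1))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("shape statistics follow the moment definitions", {
  sym <- rep(c(-1, 0, 1), 50)
  s <- shape_stats(sym)
  expect_equal(unname(s["skewness"]), 0)
  expect_error(shape_stats(rep(5, 10)), "zero variance")
  expect_error(shape_stats(c(1, 2)), "at least 3")
  # non-excess convention: a large Gaussian sample has kurtosis near 3
  set.seed(7)
  g <- shape_stats(stats::rnorm(1e6))
  expect_equal(unname(g["kurtosis"]), 3, tolerance = 0.05)
})

test_that("texture identities hold exactly for canonical histograms", {
  u256 <- texture_stats(seq(-700L, by = 1L, length.out = 256L))
  expect_identical(unname(u256["entropy_bits"]), 8)
  expect_identical(unname(u256["uniformity"]), 1 / 256)

  const <- texture_stats(rep(-650L, 100))
  expect_identical(unname(const["entropy_bits"]), 0)
  expect_identical(unname(const["uniformity"]), 1)

  two <- texture_stats(rep(c(-700L, -600L), each = 64))
  expect_identical(unname(two["entropy_bits"]), 1)
  expect_identical(unname(two["uniformity"]), 0.5)

  expect_error(texture_stats(integer(0)), "empty")
})

test_that("texture respects occupancy bounds", {
  set.seed(11)
  for (i in 1:20) {
    x <- round(stats::rnorm(500, -600, sample(5:80, 1)))
    tx <- texture_stats(x)
    m <- length(unique(x))
    expect_lte(tx[["entropy_bits"]], log2(m) + 1e-12)
    expect_gte(tx[["uniformity"]], 1 / m - 1e-12)
    expect_equal(tx[["entropy_bits"]] == 0, tx[["uniformity"]] == 1)
  }
})

test_that("volume, density and mass follow their definitions", {
  v <- volume_density_mass(rep(-600L, 1000), c(1, 1, 1))
  expect_equal(unname(v["volume_cm3"]), 1.0)
  expect_equal(unname(v["density"]), 0.40)
  expect_equal(unname(v["mass_g"]), 0.40)
  # density clamps at 0 below -1000 HU mean
  v2 <- volume_density_mass(rep(-1024L, 10), c(1, 1, 1))
  expect_equal(unname(v2["density"]), 0)
  expect_equal(unname(v2["mass_g"]), 0)
})

test_that("lung-window size matches geometry and the brute-force oracle", {
  ball <- ball_mask(15)
  expect_equal(size_lung(ball, c(1, 1, 1)), 15, tolerance = 1)

  single <- array(FALSE, c(5, 5, 3)); single[3, 3, 2] <- TRUE
  expect_equal(size_lung(nodule_mask(single), c(0.7, 0.7, 1.25)), 0.7)

  set.seed(3)
  for (i in 1:10) {
    m <- array(stats::runif(4 * 5 * 3) < 0.4, c(4, 5, 3))
    if (!any(m)) m[2, 2, 2] <- TRUE
    sp <- c(0.7, 0.7, 1.25)
    expect_equal(size_lung(nodule_mask(m), sp), oracle_feret(m, sp))
  }
})

test_that("mediastinal size measures the largest solid component", {
  vol <- tiny_volume(-700, dims = c(20, 20, 8))
  expect_equal(size_mediastinal(vol, full_mask(vol)), 0)

  nod <- quick_phantom(101, class_label = "INV", diameter = 14, solid = 3,
                       invasion = 7)
  got <- size_mediastinal(nod$volume, nod$mask)
  expect_lt(abs(got - 3), 1.5)  # within about one voxel of ground truth

  pure <- quick_phantom(102, class_label = "AIS", tail_w = 0.02,
                        invasion = 0)
  expect_equal(size_mediastinal(pure$volume, pure$mask), 0)
})

test_that("extract_features flags undefined moments and is observer-symmetric", {
  vol <- tiny_volume(-700, dims = c(8, 8, 4))
  m <- full_mask(vol)
  f <- extract_features(vol, m)
  expect_true(is.na(f$skewness) && is.na(f$kurtosis))
  expect_equal(f$entropy_bits, 0)
  expect_equal(f$uniformity, 1)
  expect_equal(f$p2_5_hu, f$p97_5_hu)

  nod <- quick_phantom(55)
  f1 <- extract_features(nod$volume, nod$mask)
  f2 <- extract_features(nod$volume, nod$mask)
  expect_identical(f1, f2)
  avg <- average_observers(f1, f2)
  expect_equal(as.numeric(avg), as.numeric(f1))
})

test_that("feature invariants hold on random phantoms", {
  set.seed(9)
  for (i in 1:25) {
    nod <- quick_phantom(1000 + i, diameter = stats::runif(1, 6, 12),
                         ggo_sd = stats::runif(1, 25, 70),
                         tail_w = stats::runif(1, 0, 0.3))
    f <- extract_features(nod$volume, nod$mask)
    pct <- as.numeric(f[c("p2_5_hu", "p25_hu", "p50_hu", "p75_hu", "p97_5_hu")])
    expect_true(all(diff(pct) >= 0))
    expect_equal(f$mass_g, f$density * f$volume_cm3)
    expect_lte(f$size_mediastinal_mm, f$size_lung_mm)
    expect_gt(f$uniformity, 0); expect_lte(f$uniformity, 1)
    expect_gte(f$entropy_bits, 0)

    # translating all HU by +50 moves location features only
    v2 <- ct_volume(nod$volume$voxels + 50L, nod$volume$spacing_mm)
    g <- extract_features(v2, nod$mask)
    expect_equal(g$entropy_bits, f$entropy_bits)
    expect_equal(g$uniformity, f$uniformity)
    expect_equal(g$skewness, f$skewness)
    expect_equal(g$kurtosis, f$kurtosis)
    expect_equal(g$volume_cm3, f$volume_cm3)
    expect_equal(g$size_lung_mm, f$size_lung_mm)
    expect_equal(as.numeric(g[c("p2_5_hu", "p25_hu", "p50_hu", "p75_hu", "p97_5_hu")]),
                 pct + 50)
    expect_equal(g$density, f$density + 0.05)
  }
})
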