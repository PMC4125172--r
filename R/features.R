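# First-order quantitative CT features of a segmented nodule.
#
# All features are computed from the multiset of in-mask HU values plus the
# mask geometry; traversal order never matters. Texture uses 1-HU integer
# bins over the nodule's own occupied range, which makes the histogram
# exact for integer HU and translation-invariant.

#' Collect the HU sample of a segmented nodule
#'
#' @param volume a [ct_volume()].
#' @param mask a [nodule_mask()] of the same shape.
#' @return integer vector of in-mask HU values (order not meaningful).
#' @export
collect_voxels <- function(volume, mask) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "nodule_mask"))
  if (!identical(dim(volume$voxels), dim(mask$voxels))) {
    stop("shape mismatch between volume and mask")
  }
  if (!any(mask$voxels)) stop("empty mask")
  volume$voxels[mask$voxels]
}

#' Histogram percentiles of the HU sample
#'
#' Attenuation values at the 2.5th, 25th, 50th, 75th and 97.5th percentiles,
#' with linear interpolation between order statistics.
#'
#' @param sample numeric vector of HU values, length >= 2.
#' @return named numeric vector `p2_5_hu`, `p25_hu`, `p50_hu`, `p75_hu`,
#'   `p97_5_hu` (monotone non-decreasing).
#' @export
histogram_percentiles <- function(sample) {
  if (length(sample) < 2) stop("need at least 2 voxels for percentiles")
  q <- stats::quantile(sample, probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                       type = 7, names = FALSE)
  names(q) <- c("p2_5_hu", "p25_hu", "p50_hu", "p75_hu", "p97_5_hu")
  q
}

#' Skewness and kurtosis of the HU sample
#'
#' Standardized third and fourth central moments. Kurtosis is the
#' non-excess convention: a Gaussian sample gives kurtosis near 3.
#'
#' @param sample numeric vector, length >= 3, non-constant.
#' @return named numeric vector `skewness`, `kurtosis`.
#' @export
shape_stats <- function(sample) {
  n <- length(sample)
  if (n < 3) stop("need at least 3 voxels for shape statistics")
  m <- mean(sample)
  d <- sample - m
  m2 <- mean(d^2)
  if (m2 == 0) stop("zero variance: skewness/kurtosis undefined")
  c(skewness = mean(d^3) / m2^1.5, kurtosis = mean(d^4) / m2^2)
}

#' Texture entropy and uniformity of the HU histogram
#'
#' First-order texture over 1-HU-wide bins spanning the sample's own range:
#' with bin probabilities p_i = count_i / n,
#' uniformity = sum p_i^2 and entropy = -sum_{p_i > 0} p_i log2 p_i.
#' Higher entropy and lower uniformity mean a more heterogeneous nodule.
#'
#' @param sample integer HU vector, non-empty.
#' @param bin_width_hu histogram bin width in HU (default 1).
#' @return named numeric vector `uniformity`, `entropy_bits`.
#' @export
texture_stats <- function(sample, bin_width_hu = 1) {
  if (length(sample) == 0) stop("empty sample")
  stopifnot(bin_width_hu > 0)
  bins <- floor((sample - min(sample)) / bin_width_hu)
  counts <- tabulate(bins + 1L)
  p <- counts[counts > 0] / length(sample)
  c(uniformity = sum(p^2), entropy_bits = -sum(p * log2(p)))
}

#' Nodule volume, density and mass
#'
#' Volume is the voxel count times the physical voxel volume (cm^3).
#' Density follows the physical-density convention (air = 0, water = 1):
#' (mean HU + 1000) / 1000, clamped at 0. Mass is exactly density x volume
#' (g).
#'
#' @param sample HU vector of the in-mask voxels, non-empty.
#' @param spacing_mm voxel spacing (dx, dy, dz) in mm.
#' @return named numeric vector `volume_cm3`, `density`, `mass_g`.
#' @export
volume_density_mass <- function(sample, spacing_mm) {
  if (length(sample) == 0) stop("empty sample")
  stopifnot(length(spacing_mm) == 3, all(spacing_mm > 0))
  volume_cm3 <- length(sample) * prod(spacing_mm) / 1000
  density <- max(0, (mean(sample) + 1000) / 1000)
  c(volume_cm3 = volume_cm3, density = density, mass_g = density * volume_cm3)
}

# Maximum in-plane Feret (caliper) diameter over the axial slices of a
# logical mask array, in mm. Computed per slice on the convex hull of the
# voxel centres, plus one in-plane voxel extent so a single voxel measures
# one pixel across.
.max_feret_mm <- function(mask_arr, spacing_mm) {
  px <- max(spacing_mm[1:2])
  best <- 0
  for (z in seq_len(dim(mask_arr)[3])) {
    sl <- mask_arr[, , z]
    if (!any(sl)) next
    idx <- which(sl, arr.ind = TRUE)
    pts <- cbind(idx[, 1] * spacing_mm[1], idx[, 2] * spacing_mm[2])
    if (nrow(pts) > 3) {
      hull <- grDevices::chull(pts)
      pts <- pts[hull, , drop = FALSE]
    }
    d <- if (nrow(pts) == 1) 0 else max(stats::dist(pts))
    best <- max(best, d + px)
  }
  best
}

#' Nodule size in the lung window
#'
#' Largest in-plane Feret diameter of the whole mask over all axial slices
#' (mm): the caliper size a reader would measure on a lung-window image.
#'
#' @param mask a [nodule_mask()].
#' @param spacing_mm voxel spacing (dx, dy, dz) in mm.
#' @return size in mm.
#' @export
size_lung <- function(mask, spacing_mm) {
  stopifnot(inherits(mask, "nodule_mask"))
  .max_feret_mm(mask$voxels, spacing_mm)
}

#' Solid-component size in the mediastinal window
#'
#' In-mask voxels at or above the soft-tissue visibility threshold
#' (default -160 HU) form the solid component; the size is the largest
#' in-plane Feret diameter of the largest 26-connected such component, or 0
#' for a pure ground-glass nodule.
#'
#' @param volume a [ct_volume()].
#' @param mask a [nodule_mask()].
#' @param spacing_mm voxel spacing in mm (defaults to the volume's).
#' @param solid_threshold_hu HU threshold for solid tissue (default -160).
#' @return size in mm (0 if no solid voxel).
#' @export
size_mediastinal <- function(volume, mask, spacing_mm = volume$spacing_mm,
                             solid_threshold_hu = -160) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "nodule_mask"))
  solid <- mask$voxels & (volume$voxels >= solid_threshold_hu)
  if (!any(solid)) return(0)
  .max_feret_mm(largest_component(solid), spacing_mm)
}

#' Extract the full first-order feature vector of one nodule
#'
#' Composes voxel collection, histogram percentiles, shape and texture
#' statistics, volume/density/mass and the two window sizes into one row.
#' For a constant-HU nodule skewness and kurtosis are undefined and
#' recorded as `NA`.
#'
#' @param volume a [ct_volume()].
#' @param mask a [nodule_mask()] of the same shape.
#' @param bin_width_hu texture histogram bin width (HU).
#' @param solid_threshold_hu solid-component HU threshold.
#' @return one-row data frame of class `nodule_features` with columns
#'   `size_lung_mm`, `size_mediastinal_mm`, `volume_cm3`, `density`,
#'   `mass_g`, `skewness`, `kurtosis`, `p2_5_hu`, `p25_hu`, `p50_hu`,
#'   `p75_hu`, `p97_5_hu`, `uniformity`, `entropy_bits`.
#' @export
extract_features <- function(volume, mask, bin_width_hu = 1,
                             solid_threshold_hu = -160) {
  sample <- collect_voxels(volume, mask)
  sp <- volume$spacing_mm
  pct <- histogram_percentiles(sample)
  shp <- tryCatch(shape_stats(sample),
                  error = function(e) c(skewness = NA_real_, kurtosis = NA_real_))
  tex <- texture_stats(sample, bin_width_hu)
  vdm <- volume_density_mass(sample, sp)
  out <- data.frame(
    size_lung_mm = size_lung(mask, sp),
    size_mediastinal_mm = size_mediastinal(volume, mask, sp, solid_threshold_hu),
    volume_cm3 = unname(vdm["volume_cm3"]),
    density = unname(vdm["density"]),
    mass_g = unname(vdm["mass_g"]),
    skewness = unname(shp["skewness"]),
    kurtosis = unname(shp["kurtosis"]),
    p2_5_hu = unname(pct["p2_5_hu"]),
    p25_hu = unname(pct["p25_hu"]),
    p50_hu = unname(pct["p50_hu"]),
    p75_hu = unname(pct["p75_hu"]),
    p97_5_hu = unname(pct["p97_5_hu"]),
    uniformity = unname(tex["uniformity"]),
    entropy_bits = unname(tex["entropy_bits"])
  )
  class(out) <- c("nodule_features", class(out))
  out
}

#' Average feature vectors across observers
#'
#' For reader studies the working value of each CT variable is the
#' arithmetic mean of the two observers' measurements, feature by feature.
#'
#' @param ... two or more `nodule_features` rows (or a list of them).
#' @return one-row `nodule_features` data frame of per-feature means.
#' @export
average_observers <- function(...) {
  rows <- list(...)
  if (length(rows) == 1 && is.list(rows[[1]]) && !is.data.frame(rows[[1]])) {
    rows <- rows[[1]]
  }
  stopifnot(length(rows) >= 2)
  tab <- do.call(rbind, rows)
  out <- as.data.frame(as.list(colMeans(tab)))
  class(out) <- c("nodule_features", class(out))
  out
}

#' Extract features for a whole in-memory cohort
#'
#' @param cohort_data result of [generate_cohort()].
#' @param observer_noise if > 0, two observer masks are simulated per
#'   nodule, features extracted from each and averaged; per-observer tables
#'   are returned for agreement analysis.
#' @param ... passed to [extract_features()].
#' @return list with `features` (one row per nodule, nodule_id first) and,
#'   when observers are simulated, `obs1` / `obs2` per-observer tables.
#' @export
cohort_features <- function(cohort_data, observer_noise = 0, ...) {
  nods <- cohort_data$nodules
  ids <- vapply(nods, function(n) n$meta$nodule_id, character(1))
  if (observer_noise > 0) {
    f1 <- vector("list", length(nods))
    f2 <- vector("list", length(nods))
    for (i in seq_along(nods)) {
      obs <- simulate_observers(nods[[i]]$mask, observer_noise,
                                seed = nods[[i]]$meta$seed + 1L)
      f1[[i]] <- extract_features(nods[[i]]$volume, obs$obs1, ...)
      f2[[i]] <- extract_features(nods[[i]]$volume, obs$obs2, ...)
    }
    f1 <- do.call(rbind, f1); f2 <- do.call(rbind, f2)
    avg <- (as.data.frame(f1) + as.data.frame(f2)) / 2
    list(features = cbind(nodule_id = ids, avg, stringsAsFactors = FALSE),
         obs1 = cbind(nodule_id = ids, f1, stringsAsFactors = FALSE),
         obs2 = cbind(nodule_id = ids, f2, stringsAsFactors = FALSE))
  } else {
    ft <- do.call(rbind, lapply(nods, function(n) {
      extract_features(n$volume, n$mask, ...)
    }))
    list(features = cbind(nodule_id = ids, ft, stringsAsFactors = FALSE))
  }
}
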