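# Synthetic ground-glass nodule (GGN) phantoms.
#
# The generator emulates a three-class cohort of resected GGN adenocarcinomas
# (AIS / MIA / invasive) in which size, density, high-percentile attenuation
# and entropy increase with invasiveness while uniformity decreases. Each
# nodule is a smooth blob of ground-glass attenuation (a one- or
# two-component HU mixture) on a uniform lung background, optionally with a
# sub-5-mm embedded solid core. Shapes are deliberately simple: no vessels,
# airways or scanner noise model.

GGN_CLASSES <- c("AIS", "MIA", "INV")

# Voxels in the ground-glass matrix are kept strictly below the solid
# threshold so that a nodule has soft-tissue-range attenuation only where a
# solid core was placed.
GGO_HU_CEILING <- -161L
SOLID_HU_THRESHOLD <- -160

#' Specification of one synthetic ground-glass nodule
#'
#' @param class_label one of `"AIS"`, `"MIA"`, `"INV"`.
#' @param diameter_mm target lung-window diameter of the nodule (mm).
#' @param ggo_mean_hu central attenuation of the ground-glass matrix (HU);
#'   must lie in \[-900, -300\].
#' @param ggo_sd_hu voxel-level spread of the main mixture component (HU).
#' @param right_tail_weight fraction in \[0, 1\] of voxels drawn from a
#'   denser (higher-HU) mixture component; drives entropy and the upper
#'   histogram percentiles apart between classes.
#' @param solid_focus_mm diameter of an embedded solid core (HU >= -160);
#'   0 for a pure GGN. Cohort-retained nodules keep this below 5 mm.
#' @param invasion_extent_mm pathologic invasion extent ground truth:
#'   0 for AIS, in (0, 5\] for MIA, > 5 for INV.
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   voxel output.
#' @param tail_shift_hu,tail_sd_hu centre offset and spread of the denser
#'   mixture component (HU); per-nodule values are jittered around these
#'   from the seed.
#' @param mode_probs length-3 probabilities that the ground-glass matrix is
#'   single-, double- or triple-peaked; architectural complexity increases
#'   with invasiveness, raising entropy independently of the tail position.
#' @return A `phantom_spec` object (validated list).
#' @export
phantom_spec <- function(class_label, diameter_mm, ggo_mean_hu, ggo_sd_hu,
                         right_tail_weight = 0, solid_focus_mm = 0,
                         invasion_extent_mm = 0, seed = 1L,
                         tail_shift_hu = 200, tail_sd_hu = 80,
                         mode_probs = c(0.30, 0.40, 0.30)) {
  class_label <- match.arg(class_label, GGN_CLASSES)
  stopifnot(is.numeric(diameter_mm), diameter_mm > 0,
            is.numeric(ggo_sd_hu), ggo_sd_hu > 0,
            right_tail_weight >= 0, right_tail_weight <= 1,
            solid_focus_mm >= 0, invasion_extent_mm >= 0,
            tail_shift_hu > 0, tail_sd_hu > 0,
            length(mode_probs) == 3, all(mode_probs >= 0),
            sum(mode_probs) > 0)
  if (ggo_mean_hu < -900 || ggo_mean_hu > -300) {
    stop("ggo_mean_hu must lie in [-900, -300]")
  }
  ok <- switch(class_label,
    AIS = invasion_extent_mm == 0,
    MIA = invasion_extent_mm > 0 && invasion_extent_mm <= 5,
    INV = invasion_extent_mm > 5
  )
  if (!ok) {
    stop(sprintf("invasion_extent_mm %.2f inconsistent with class %s ",
                 invasion_extent_mm, class_label),
         "(AIS: 0; MIA: (0, 5]; INV: > 5)")
  }
  structure(list(
    class_label = class_label, diameter_mm = diameter_mm,
    ggo_mean_hu = ggo_mean_hu, ggo_sd_hu = ggo_sd_hu,
    right_tail_weight = right_tail_weight, solid_focus_mm = solid_focus_mm,
    invasion_extent_mm = invasion_extent_mm, seed = as.integer(seed),
    tail_shift_hu = tail_shift_hu, tail_sd_hu = tail_sd_hu,
    mode_probs = mode_probs / sum(mode_probs)
  ), class = "phantom_spec")
}

# Per-class generative presets. Values are configuration chosen so that the
# class ordering of entropy, uniformity, high percentiles, density and size
# emerges; they are not fitted to any particular cohort.
#
# The invasiveness signal is a per-nodule heterogeneity intensity `lambda`
# (class-ordered truncated normal) that each nodule expresses through a
# random split across three channels: a denser right-tail component, bulk
# multi-modality, and a wider ground-glass core. Different invasive nodules
# are therefore heterogeneous in different ways -- entropy, which
# integrates over the whole histogram, sees every channel, while any single
# percentile sees only a subset. Fields:
#   diameter: truncated-normal (mean, sd, lo, hi) of nodule diameter (mm)
#   ggo_mean: truncated-normal of matrix mean HU
#   ggo_sd_base: truncated-normal of the baseline matrix voxel SD (HU)
#   tail_base: truncated-normal of the baseline right-tail weight
#   lambda: truncated-normal of the heterogeneity intensity
#   tail_shift_hu / tail_sd_hu: denser component offset and spread
#   solid_prob / solid_range_mm: chance and size range of a solid core
#   invasion: sampler parameters for pathologic invasion extent
default_class_presets <- function() {
  base <- list(
    ggo_mean = c(-635, 50, -790, -470),
    ggo_sd_base = c(33, 5, 22, 50),
    tail_base = c(0.04, 0.02, 0, 0.10),
    tail_shift_hu = 175, tail_sd_hu = 95
  )
  list(
    AIS = c(base, list(
      diameter = c(13.2, 5.5, 6, 28),
      lambda = c(0.25, 0.20, 0, 0.9),
      solid_prob = 0.08, solid_range_mm = c(1.5, 3),
      invasion = list(type = "none")
    )),
    MIA = c(utils::modifyList(base, list(ggo_mean = c(-605, 50, -770, -450))),
            list(
      diameter = c(15.2, 5.5, 6, 28),
      lambda = c(0.60, 0.25, 0.05, 1.4),
      solid_prob = 0.13, solid_range_mm = c(1.5, 3),
      invasion = list(type = "uniform", range = c(0.5, 5))
    )),
    INV = c(utils::modifyList(base, list(ggo_mean = c(-575, 50, -750, -430))),
            list(
      diameter = c(18.3, 5.5, 7, 28),
      lambda = c(1.25, 0.32, 0.30, 2.2),
      solid_prob = 0.26, solid_range_mm = c(1.5, 4),
      invasion = list(type = "lognormal", median_mm = 9.8,
                      sdlog = 0.3, range = c(5.1, 19.7))
    ))
  )
}

#' Specification of a synthetic GGN cohort
#'
#' Defaults reproduce the composition of the reference cohort: 191 nodules
#' split 38 AIS / 61 MIA / 92 invasive, imaged at 1.25 mm slice spacing with
#' 0.7 mm in-plane pixels.
#'
#' @param n_ais,n_mia,n_inv class counts (non-negative; not all zero).
#' @param voxel_spacing_mm length-3 voxel spacing (dx, dy, dz) in mm.
#' @param class_presets per-class generative parameter distributions; see
#'   `default_class_presets()` for the structure.
#' @param observer_noise boundary perturbation magnitude, in voxels, used
#'   when simulating two independent observers (0 = perfect agreement).
#' @param master_seed integer; per-nodule seeds are derived from it
#'   deterministically, so the whole cohort is a pure function of this spec.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_ais = 38, n_mia = 61, n_inv = 92,
                        voxel_spacing_mm = c(0.7, 0.7, 1.25),
                        class_presets = default_class_presets(),
                        observer_noise = 1,
                        master_seed = 57290L) {
  stopifnot(n_ais >= 0, n_mia >= 0, n_inv >= 0)
  if (n_ais + n_mia + n_inv == 0) stop("all class counts are zero")
  stopifnot(length(voxel_spacing_mm) == 3, all(voxel_spacing_mm > 0))
  stopifnot(all(GGN_CLASSES %in% names(class_presets)))
  stopifnot(observer_noise >= 0)
  structure(list(
    n_ais = as.integer(n_ais), n_mia = as.integer(n_mia),
    n_inv = as.integer(n_inv),
    voxel_spacing_mm = as.numeric(voxel_spacing_mm),
    class_presets = class_presets,
    observer_noise = observer_noise,
    master_seed = as.integer(master_seed)
  ), class = "cohort_spec")
}

# Smooth direction-dependent radius: sphere with a low-amplitude low-order
# perturbation, so the lung-window diameter stays well defined while the
# boundary is nontrivial for observer-noise experiments.
.radial_field <- function(ux, uy, uz, coef) {
  f <- coef$a[1] * ux + coef$a[2] * uy + coef$a[3] * uz +
    coef$b[1] * ux * uy + coef$b[2] * uy * uz + coef$b[3] * ux * uz +
    coef$c[1] * (ux^2 - uz^2) + coef$c[2] * (uy^2 - uz^2)
  coef$amp * tanh(f)
}

#' Generate one synthetic nodule
#'
#' Renders a `phantom_spec` into a CT volume and ground-truth mask. The
#' nodule is a smooth blob of approximately `diameter_mm` extent; in-mask
#' voxels are drawn from the class HU mixture (truncated below -160 HU so a
#' pure GGN has no solid-range voxel), the background is uniform aerated
#' lung near -900 HU, and an optional central solid core of
#' `solid_focus_mm` diameter has HU >= -160.
#'
#' @param spec a [phantom_spec()].
#' @param voxel_spacing_mm voxel spacing (dx, dy, dz) in mm.
#' @param margin_mm background margin around the nodule.
#' @return list with `volume` ([ct_volume()]), `mask` ([nodule_mask()]) and
#'   `meta`, a one-row data frame (nodule_id placeholder, class label,
#'   invasion extent, seed, true diameter and solid size).
#' @export
generate_nodule <- function(spec, voxel_spacing_mm = c(0.7, 0.7, 1.25),
                            margin_mm = 4) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- as.numeric(voxel_spacing_mm)
  stopifnot(length(sp) == 3, all(sp > 0))
  if (spec$diameter_mm < 2 * max(sp[1:2])) {
    stop("degenerate nodule: diameter smaller than 2 voxels in plane")
  }
  with_seed(spec$seed, {
    extent <- spec$diameter_mm * 1.12 + 2 * margin_mm
    dims <- pmax(ceiling(extent / sp), 5)
    centre <- (dims + 1) / 2
    # physical offsets from the centre, per axis
    cx <- (seq_len(dims[1]) - centre[1]) * sp[1]
    cy <- (seq_len(dims[2]) - centre[2]) * sp[2]
    cz <- (seq_len(dims[3]) - centre[3]) * sp[3]
    X <- array(cx, dims)
    Y <- array(rep(cy, each = dims[1]), dims)
    Z <- array(rep(cz, each = dims[1] * dims[2]), dims)
    r <- sqrt(X^2 + Y^2 + Z^2)
    coef <- list(a = stats::rnorm(3, 0, 0.8), b = stats::rnorm(3, 0, 0.8),
                 c = stats::rnorm(2, 0, 0.8), amp = 0.06)
    R0 <- spec$diameter_mm / 2
    # voxels strictly inside / outside the perturbation band are decided
    # without evaluating the radial field; only the shell needs it
    mask <- r <= R0 * (1 - coef$amp)
    shell <- which(r > R0 * (1 - coef$amp) & r <= R0 * (1 + coef$amp))
    if (length(shell)) {
      rs <- pmax(r[shell], 1e-9)
      radius <- R0 * (1 + .radial_field(X[shell] / rs, Y[shell] / rs,
                                        Z[shell] / rs, coef))
      mask[shell] <- r[shell] <= radius
    }
    if (sum(mask) < 2) stop("degenerate nodule: fewer than 2 mask voxels")

    hu <- array(0L, dims)
    n_bg <- sum(!mask)
    # bounds sit several SD out, so clamping plain normals is exact in
    # practice and much cheaper than inverse-CDF truncation
    hu[!mask] <- as.integer(round(pmin(pmax(stats::rnorm(n_bg, -900, 15),
                                            HU_MIN), -700)))
    # partial-volume rim just outside the nodule: intermediate attenuation,
    # so a slightly over-inclusive observer ROI samples transition voxels
    # rather than pure aerated lung
    midx <- which(mask, arr.ind = TRUE)
    blo <- pmax(1L, apply(midx, 2, min) - 2L)
    bhi <- pmin(dims, apply(midx, 2, max) + 2L)
    bxr <- blo[1]:bhi[1]; byr <- blo[2]:bhi[2]; bzr <- blo[3]:bhi[3]
    msub <- array(mask[bxr, byr, bzr], c(length(bxr), length(byr), length(bzr)))
    rim <- array(FALSE, dims)
    rim[bxr, byr, bzr] <- dilate26(msub) & !msub
    n_rim <- sum(rim)
    if (n_rim) {
      hu[rim] <- as.integer(round(pmin(pmax(stats::rnorm(n_rim, -865, 25),
                                            HU_MIN), -700)))
    }
    n_in <- sum(mask)
    # nodule-level histogram idiosyncrasies, drawn from the seed: the dense
    # component's exact offset/spread and a mild right-skew of the matrix
    # vary from nodule to nodule, as they do between real tumours
    # the dense component's offset and spread scale with the nodule's own
    # matrix SD (tail_shift_hu / tail_sd_hu are the values for a typical
    # 45-HU-SD matrix), keeping skewness/kurtosis roughly scale-free
    tail_shift <- spec$ggo_sd_hu *
      rnorm_trunc(1, spec$tail_shift_hu / 45, 0.9, 1.0, 6)
    tail_sd <- spec$ggo_sd_hu *
      rnorm_trunc(1, spec$tail_sd_hu / 45, 0.7, 0.7, 4.5)
    skew_r <- exp(stats::rnorm(1, 0.08, 0.15))
    # a narrow "spike" sub-population of near-identical voxels (collapsed or
    # homogeneous alveolar regions); concentrates histogram mass and so
    # drives uniformity up largely independently of overall spread
    spike_w <- stats::runif(1, 0.08, 0.22)
    spike_sd <- exp(stats::runif(1, log(1), log(15)))
    spike_mu <- spec$ggo_mean_hu + stats::rnorm(1, 0, 0.8) * spec$ggo_sd_hu
    # partial-volume voxels near the boundary sit close to aerated-lung
    # attenuation whatever the tumour class; they anchor the histogram's
    # left edge (low percentiles are nearly class-independent)
    left_w <- stats::runif(1, 0.02, 0.20)
    left_mu <- stats::rnorm(1, -855, 25)
    # the bulk matrix is itself a 1-3-mode mixture (single, flat-topped or
    # double-peaked histograms all occur in GGNs); multi-modality raises
    # entropy log-like while the percentile span grows only linearly, and
    # it flattens kurtosis
    k_modes <- sample.int(3L, 1L, prob = spec$mode_probs)
    mode_mu <- stats::rnorm(k_modes, 0, 1.25)
    mode_sd <- stats::runif(k_modes, 0.45, 0.9)
    if (k_modes == 1L) { mode_mu <- 0; mode_sd <- 1 }
    mode_w <- stats::runif(k_modes, 0.2, 1)
    mode_w <- mode_w / sum(mode_w)
    mode_mu <- mode_mu - sum(mode_w * mode_mu)  # keep the matrix mean fixed
    u <- stats::runif(n_in)
    left <- u < left_w
    tail <- !left & (u < left_w + spec$right_tail_weight)
    spike <- !left & !tail & (u < left_w + spec$right_tail_weight + spike_w)
    main <- !left & !tail & !spike
    vals <- numeric(n_in)
    n_m <- sum(main)
    z <- stats::rnorm(n_m)
    z <- ifelse(z < 0, z, skew_r * z)
    comp <- sample.int(k_modes, n_m, replace = TRUE, prob = mode_w)
    vals[main] <- spec$ggo_mean_hu +
      spec$ggo_sd_hu * (mode_mu[comp] + mode_sd[comp] * z)
    if (any(left)) vals[left] <- rnorm_trunc(sum(left), left_mu, 40,
                                             HU_MIN, GGO_HU_CEILING)
    if (any(spike)) vals[spike] <- stats::rnorm(sum(spike), spike_mu, spike_sd)
    if (any(tail)) {
      vals[tail] <- rnorm_trunc(sum(tail), spec$ggo_mean_hu + tail_shift,
                                tail_sd, HU_MIN, GGO_HU_CEILING)
    }
    vals <- pmin(pmax(vals, HU_MIN), GGO_HU_CEILING)
    hu[mask] <- as.integer(round(vals))

    if (spec$solid_focus_mm > 0) {
      solid <- (r <= spec$solid_focus_mm / 2) & mask
      if (!any(solid)) {
        # a core smaller than one voxel still occupies the centre voxel
        ctr <- array(FALSE, dims)
        ctr[round(centre[1]), round(centre[2]), round(centre[3])] <- TRUE
        solid <- ctr & mask
      }
      n_s <- sum(solid)
      hu[solid] <- as.integer(round(rnorm_trunc(n_s, -60, 50,
                                                SOLID_HU_THRESHOLD, 120)))
    }

    meta <- data.frame(
      nodule_id = NA_character_,
      class_label = spec$class_label,
      invasion_extent_mm = spec$invasion_extent_mm,
      diameter_mm = spec$diameter_mm,
      solid_focus_mm = spec$solid_focus_mm,
      seed = spec$seed,
      stringsAsFactors = FALSE
    )
    list(volume = ct_volume(hu, sp), mask = nodule_mask(mask), meta = meta)
  })
}

# Sample from a (mean, sd, lo, hi) truncated-normal preset row.
.sample_preset <- function(p, n = 1) rnorm_trunc(n, p[1], p[2], p[3], p[4])

.sample_invasion <- function(inv) {
  switch(inv$type,
    none = 0,
    uniform = stats::runif(1, inv$range[1], inv$range[2]),
    lognormal = {
      x <- stats::rlnorm(1, log(inv$median_mm), inv$sdlog)
      min(max(x, inv$range[1]), inv$range[2])
    },
    stop("unknown invasion sampler: ", inv$type)
  )
}

# Draw one phantom_spec from the class presets (RNG already seeded).
.draw_spec <- function(class_label, presets, seed) {
  p <- presets[[class_label]]
  solid <- if (stats::runif(1) < p$solid_prob) {
    stats::runif(1, p$solid_range_mm[1], p$solid_range_mm[2])
  } else 0
  # heterogeneity intensity, split at random over three expression
  # channels: denser right tail / bulk multi-modality / wider core
  lambda <- .sample_preset(p$lambda)
  w <- stats::runif(3)
  w <- w / sum(w)
  tail_w <- min(0.5, max(0, .sample_preset(p$tail_base) +
                           0.40 * lambda * w[1]))
  ggo_sd <- .sample_preset(p$ggo_sd_base) * (1 + 0.80 * lambda * w[3])
  m <- min(1, 1.6 * lambda * w[2])
  mode_probs <- (1 - m) * c(0.80, 0.15, 0.05) + m * c(0.05, 0.40, 0.55)
  phantom_spec(
    class_label = class_label,
    diameter_mm = .sample_preset(p$diameter),
    ggo_mean_hu = .sample_preset(p$ggo_mean),
    ggo_sd_hu = ggo_sd,
    right_tail_weight = tail_w,
    solid_focus_mm = solid,
    invasion_extent_mm = .sample_invasion(p$invasion),
    seed = seed,
    tail_shift_hu = p$tail_shift_hu, tail_sd_hu = p$tail_sd_hu,
    mode_probs = mode_probs
  )
}

#' Generate a synthetic GGN cohort
#'
#' Produces `n_ais + n_mia + n_inv` nodules. Per-nodule parameters are drawn
#' from the class presets using seeds derived deterministically from
#' `master_seed`, so the cohort is a pure function of its spec. All
#' generated solid cores are below 5 mm, so the whole cohort passes the
#' solid-component exclusion filter.
#'
#' @param cohort a [cohort_spec()].
#' @return list with `nodules` (list of `generate_nodule()` results) and
#'   `records`, a data frame (nodule_id, class_label, invasion_extent_mm,
#'   seed).
#' @export
generate_cohort <- function(cohort = cohort_spec()) {
  stopifnot(inherits(cohort, "cohort_spec"))
  classes <- rep(GGN_CLASSES, times = c(cohort$n_ais, cohort$n_mia, cohort$n_inv))
  n <- length(classes)
  nodules <- vector("list", n)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    seed_i <- derive_seed(cohort$master_seed, i)
    spec <- with_seed(seed_i, .draw_spec(classes[i], cohort$class_presets, seed_i))
    nod <- generate_nodule(spec, cohort$voxel_spacing_mm)
    nod$meta$nodule_id <- sprintf("GGN%03d", i)
    nodules[[i]] <- nod
    records[[i]] <- nod$meta
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  list(nodules = nodules, records = records)
}

#' Simulate two independent observers segmenting the same nodule
#'
#' Each observer's mask is obtained by independently perturbing the input
#' mask boundary: for `ceiling(noise)` rounds, inner boundary voxels are
#' removed and outer boundary voxels added, each with probability
#' `noise / ceiling(noise)`. The result is cleaned to its largest
#' 26-connected component. `noise = 0` returns two copies of the input, so
#' any downstream per-feature ICC is exactly 1.
#'
#' @param mask a [nodule_mask()].
#' @param noise boundary perturbation magnitude in voxels (>= 0).
#' @param seed integer seed; the pair is reproducible.
#' @return list of two `nodule_mask` objects.
#' @export
simulate_observers <- function(mask, noise, seed = 1L) {
  stopifnot(inherits(mask, "nodule_mask"), noise >= 0)
  if (noise == 0) return(list(obs1 = mask, obs2 = mask))
  with_seed(seed, {
    # work inside the mask bounding box (plus room for dilation)
    d <- dim(mask$voxels)
    idx <- which(mask$voxels, arr.ind = TRUE)
    margin <- ceiling(noise) + 1L
    lo <- pmax(1L, apply(idx, 2, min) - margin)
    hi <- pmin(d, apply(idx, 2, max) + margin)
    bx <- lo[1]:hi[1]; by <- lo[2]:hi[2]; bz <- lo[3]:hi[3]
    sub <- array(mask$voxels[bx, by, bz], c(length(bx), length(by), length(bz)))
    perturb <- function(m) {
      rounds <- ceiling(noise)
      # each boundary voxel flips with probability 0.5 per unit of noise,
      # so two observers genuinely disagree (a probability of 1 would flip
      # the whole shell deterministically for both)
      p <- 0.5 * noise / rounds
      for (r in seq_len(rounds)) {
        grown <- dilate26(m)
        shrunk <- !dilate26(!m)
        outer_shell <- grown & !m
        inner_shell <- m & !shrunk
        add <- outer_shell & (array(stats::runif(length(m)), dim(m)) < p)
        drop_ <- inner_shell & (array(stats::runif(length(m)), dim(m)) < p)
        m <- (m | add) & !drop_
      }
      if (!any(m)) stop("observer perturbation emptied the mask")
      full <- array(FALSE, d)
      full[bx, by, bz] <- largest_component(m)
      full
    }
    list(obs1 = nodule_mask(perturb(sub)),
         obs2 = nodule_mask(perturb(sub)))
  })
}

#' Write a generated cohort to disk
#'
#' Volumes and masks go to NIfTI files (`<id>.nii.gz`, `<id>_mask.nii.gz`;
#' observer masks, when requested, as `<id>_mask_obs1/_obs2`), metadata to
#' `cohort.csv` with columns nodule_id, class_label, invasion_extent_mm,
#' seed.
#'
#' @param cohort_data result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param observers if TRUE, also simulate and write two observer masks per
#'   nodule using `noise` voxels of boundary perturbation.
#' @param noise observer boundary noise in voxels.
#' @return the metadata data frame, invisibly.
#' @export
write_cohort <- function(cohort_data, dir, observers = FALSE, noise = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- cohort_data$records
  for (i in seq_along(cohort_data$nodules)) {
    nod <- cohort_data$nodules[[i]]
    id <- nod$meta$nodule_id
    write_volume(nod$volume, file.path(dir, paste0(id, ".nii.gz")))
    write_mask(nod$mask, file.path(dir, paste0(id, "_mask.nii.gz")),
               nod$volume$spacing_mm)
    if (observers) {
      obs <- simulate_observers(nod$mask, noise, seed = nod$meta$seed + 1L)
      write_mask(obs$obs1, file.path(dir, paste0(id, "_mask_obs1.nii.gz")),
                 nod$volume$spacing_mm)
      write_mask(obs$obs2, file.path(dir, paste0(id, "_mask_obs2.nii.gz")),
                 nod$volume$spacing_mm)
    }
  }
  cols <- c("nodule_id", "class_label", "invasion_extent_mm", "seed")
  utils::write.csv(recs[, cols], file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  invisible(recs)
}
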