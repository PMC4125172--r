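# Shared fixtures: tiny volumes/masks built in code, plus independent
# oracles used to cross-check the package's own implementations.

# A cuboid volume filled with the given HU values (recycled), 1 mm spacing.
tiny_volume <- function(values, dims = c(4, 4, 3), spacing = c(1, 1, 1)) {
  ct_volume(array(rep_len(values, prod(dims)), dims), spacing)
}

full_mask <- function(volume) {
  nodule_mask(array(TRUE, dim(volume$voxels)))
}

# Digital ball mask of the given diameter (voxels are 1 mm here).
ball_mask <- function(diameter_vox, dims = rep(diameter_vox + 4, 3)) {
  ctr <- (dims + 1) / 2
  idx <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                     z = seq_len(dims[3]))
  r <- sqrt((idx$x - ctr[1])^2 + (idx$y - ctr[2])^2 + (idx$z - ctr[3])^2)
  nodule_mask(array(r <= diameter_vox / 2, dims))
}

# Quick small phantom for feature-level tests.
quick_phantom <- function(seed, class_label = "MIA", diameter = 9,
                          ggo_mean = -650, ggo_sd = 45, tail_w = 0.1,
                          solid = 0, invasion = 2.5) {
  spec <- phantom_spec(class_label, diameter, ggo_mean, ggo_sd,
                       right_tail_weight = tail_w, solid_focus_mm = solid,
                       invasion_extent_mm = invasion, seed = seed)
  generate_nodule(spec)
}

# --- independent oracles -----------------------------------------------

# Sort-and-interpolate percentile (linear interpolation between order
# statistics), written from the definition.
oracle_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Pairwise-concordance AUC (Mann-Whitney with half credit for ties).
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Brute-force maximum in-plane Feret diameter (+ one pixel extent).
oracle_feret <- function(mask_arr, spacing) {
  px <- max(spacing[1:2])
  best <- 0
  for (z in seq_len(dim(mask_arr)[3])) {
    idx <- which(mask_arr[, , z], arr.ind = TRUE)
    if (nrow(idx) == 0) next
    pts <- cbind(idx[, 1] * spacing[1], idx[, 2] * spacing[2])
    d <- 0
    if (nrow(pts) > 1) {
      for (i in 1:(nrow(pts) - 1)) {
        di <- sqrt((pts[i, 1] - pts[-(1:i), 1])^2 +
                     (pts[i, 2] - pts[-(1:i), 2])^2)
        d <- max(d, di)
      }
    }
    best <- max(best, d + px)
  }
  best
}

# ICC(A,1) from an explicit two-way ANOVA decomposition via stats::aov,
# independent of the package's direct sum-of-squares route.
oracle_icc <- function(obs1, obs2) {
  n <- length(obs1)
  d <- data.frame(y = c(obs1, obs2),
                  subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
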