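# Internal helpers: reproducible RNG scoping, truncated sampling,
# 3D morphology (26-connectivity components) used by masks and solid cores.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-item seed derived from a master seed; kept below 2^31-1
# so it is a valid R integer seed.
derive_seed <- function(master_seed, index) {
  m <- as.numeric(master_seed) %% 2147483647
  s <- (m * 48271 + as.numeric(index) * 69621 + 12345) %% 2147483647
  as.integer(s)
}

# Truncated normal sampling by inverse-CDF; avoids the probability atoms that
# hard clamping would pile onto the bounds of the HU histogram.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (n == 0L) return(numeric(0))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  x <- stats::qnorm(u, mean, sd)
  pmin(pmax(x, lower), upper)
}

# Offsets of the 26-neighbourhood in 3D.
.offsets26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
})

# Shift a 3D logical array by (dx, dy, dz), padding with FALSE.
shift3d <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(FALSE, d)
  xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
  ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
  zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
  if (length(xs) == 0 || length(ys) == 0 || length(zs) == 0) return(out)
  out[xs, ys, zs] <- a[xs - dx, ys - dy, zs - dz]
  out
}

# One 26-connected dilation step.
dilate26 <- function(a) {
  out <- a
  for (i in seq_len(nrow(.offsets26))) {
    o <- .offsets26[i, ]
    out <- out | shift3d(a, o[1], o[2], o[3])
  }
  out
}

# Half of the 26-neighbourhood (the other half follows by symmetry when
# building an undirected adjacency graph).
.half_offsets26 <- .offsets26[1:13, , drop = FALSE]

# Label 26-connected components of a 3D logical array. Foreground voxels
# become graph vertices, adjacency edges are built vectorised over the 13
# half-offsets, and components come from igraph. Returns an integer array
# (0 = background) with attribute "sizes".
label_components <- function(mask) {
  labels <- array(0L, dim(mask))
  if (!any(mask)) {
    attr(labels, "sizes") <- integer(0)
    return(labels)
  }
  d <- dim(mask)
  lin <- which(mask)
  id_of <- array(0L, d)
  id_of[lin] <- seq_along(lin)
  pos <- arrayInd(lin, d)
  edges <- vector("list", nrow(.half_offsets26))
  for (i in seq_len(nrow(.half_offsets26))) {
    o <- .half_offsets26[i, ]
    nx <- pos[, 1] + o[1]; ny <- pos[, 2] + o[2]; nz <- pos[, 3] + o[3]
    ok <- nx >= 1 & nx <= d[1] & ny >= 1 & ny <= d[2] & nz >= 1 & nz <= d[3]
    if (!any(ok)) next
    nb <- id_of[cbind(nx[ok], ny[ok], nz[ok])]
    hit <- nb > 0L
    if (any(hit)) {
      edges[[i]] <- cbind(which(ok)[hit], nb[hit])
    }
  }
  em <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(if (is.null(em)) {
    matrix(integer(0), ncol = 2)
  } else em, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(lin) - igraph::vcount(g)))
  comp <- igraph::components(g)
  labels[lin] <- comp$membership
  attr(labels, "sizes") <- as.integer(comp$csize)
  labels
}

# Number of 26-connected components.
n_components <- function(mask) {
  length(attr(label_components(mask), "sizes"))
}

# Keep only the largest 26-connected component.
largest_component <- function(mask) {
  lab <- label_components(mask)
  sizes <- attr(lab, "sizes")
  if (length(sizes) <= 1L) return(mask)
  lab == which.max(sizes)
}
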