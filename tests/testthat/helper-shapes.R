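# Geometric fixtures built in code: analytic voxel shapes and histograms.

# sphere of radius r voxels on an integer-centered (odd) grid unless n given
sphere_mask <- function(r, n = 2 * (ceiling(r) + 4) + 1, voxel_size = 1) {
  ctr <- (n + 1) / 2
  co <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  m <- array(FALSE, c(n, n, n))
  m[co[rowSums(sweep(co, 2, rep(ctr, 3))^2) <= r^2, , drop = FALSE]] <- TRUE
  phase_mask(m, "pore", voxel_size)
}

# solid cylinder radius r, length L, along a chosen axis (1 = vertical);
# odd in-plane grid so the axis passes through voxel centers (degenerate
# even-centered axis-aligned tubes over-collapse under homotopic thinning,
# here as in the reference implementations of the algorithm family)
cylinder_mask <- function(r, L, axis = 1, pad = 6, voxel_size = 1) {
  nax <- ceiling(L) + 2 * pad
  ctr <- ceiling(r) + pad + 1
  nxy <- 2 * ctr - 1
  dims <- rep(nxy, 3); dims[axis] <- nax
  co <- as.matrix(expand.grid(1:dims[1], 1:dims[2], 1:dims[3]))
  perp <- setdiff(1:3, axis)
  inside <- (co[, perp[1]] - ctr)^2 + (co[, perp[2]] - ctr)^2 <= r^2 &
    co[, axis] > pad & co[, axis] <= pad + L
  m <- array(FALSE, dims)
  m[co[inside, , drop = FALSE]] <- TRUE
  phase_mask(m, "pore", voxel_size)
}

# three tubes of radius r meeting at the grid center ("Y")
y_mask <- function(r = 3, n = 60) {
  co <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  segdist <- function(P, a, b) {
    u <- b - a
    t <- pmin(pmax((sweep(P, 2, a) %*% u) / sum(u * u), 0), 1)
    sqrt(rowSums((sweep(P, 2, a) - t %*% t(u))^2))
  }
  cen <- rep(n / 2, 3)
  m <- array(FALSE, c(n, n, n))
  for (e in list(c(n / 2, n / 2, 5), c(10, n - 5, n * 0.75),
                 c(n - 5, 10, n * 0.75)))
    m[co[segdist(co, cen, e) <= r, , drop = FALSE]] <- TRUE
  phase_mask(m, "pore", 1)
}

# tube following a half-circle arc of radius R (in a plane), tube radius r
arc_mask <- function(R = 30, r = 3) {
  n1 <- ceiling(2 * r) + 10
  n2 <- ceiling(2 * R + 2 * r) + 12
  n3 <- ceiling(R + 2 * r) + 12
  m <- array(FALSE, c(n1, n2, n3))
  co <- as.matrix(expand.grid(1:n1, 1:n2, 1:n3))
  cen <- c((n1 + 1) / 2, n2 / 2, 6 + r)
  ang <- seq(0, pi, length.out = 400)
  pts <- cbind(cen[1], cen[2] + R * cos(ang), cen[3] + R * sin(ang))
  d2 <- matrix(Inf, nrow(co), 1)
  for (i in seq_len(nrow(pts)))
    d2 <- pmin(d2, rowSums(sweep(co, 2, pts[i, ])^2))
  m[co[d2 <= r^2, , drop = FALSE]] <- TRUE
  phase_mask(m, "pore", 1)
}

# analytic histogram of a Gaussian mixture on integer intensities
mixture_hist <- function(means, sds, weights = NULL, x = 0:255, scale = 1e5) {
  if (is.null(weights)) weights <- rep(1 / length(means), length(means))
  dens <- rowSums(mapply(function(m, s, w) w * dnorm(x, m, s),
                         means, sds, weights))
  list(mids = x, counts = round(scale * dens))
}

# independent naive 26-connected component count (recursive flood fill in R)
naive_component_count <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nc <- 0L
  idx <- which(mask, arr.ind = TRUE)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (s in seq_len(nrow(idx))) {
    p <- idx[s, ]
    if (lab[p[1], p[2], p[3]] > 0) next
    nc <- nc + 1L
    stack <- list(p)
    lab[p[1], p[2], p[3]] <- nc
    while (length(stack)) {
      q <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in seq_len(nrow(offs))) {
        w <- q + offs[o, ]
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0L) {
          lab[w[1], w[2], w[3]] <- nc
          stack[[length(stack) + 1L]] <- w
        }
      }
    }
  }
  nc
}

# independent D95 oracle: exhaustive prefix search over descending diameters
d95_oracle <- function(D, frac = 0.95) {
  ds <- sort(D, decreasing = TRUE)
  tot <- sum(ds^4)
  acc <- 0
  for (k in seq_along(ds)) {
    acc <- acc + ds[k]^4
    if (acc >= frac * tot) return(mean(ds[seq_len(k)]))
  }
}

# map each ground-truth primitive to the region that contains most of it
match_primitives_to_regions <- function(regions, phantom) {
  reg_lab <- attr(regions, "labels")
  occ <- which(phantom$labels > 0L)
  pl <- phantom$labels[occ]
  rl <- reg_lab[occ]
  keep <- rl > 0L
  tab <- table(pl[keep], rl[keep])
  vapply(rownames(tab), function(p)
    as.integer(colnames(tab)[which.max(tab[p, ])]), integer(1))
}
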