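# shared fixtures for the simulation tests

# deterministic dense ball of n beads on a cubic lattice (spacing 1.1 sigma),
# used as the condensed-start configuration for droplet-stability assays
ballPositions <- function(n, spacing = 1.1) {
  k <- ceiling((n * spacing^3 / (4 / 3 * pi))^(1 / 3)) + 2
  g <- as.matrix(expand.grid(x = -k:k, y = -k:k, z = -k:k)) * spacing
  g[order(rowSums(g^2)), ][seq_len(n), , drop = FALSE]
}

# a single-species free-bead state
freeBeadState <- function(n, Rc, positions = NULL, species = "F") {
  if (is.null(positions)) {
    positions <- ballPositions(n)
  }
  new("SystemState", positions = positions, species = rep(species, n),
      Rc = Rc, time = 0)
}

# random configuration inside a sphere, away from the wall
randomInSphere <- function(n, radius, seed = 1) {
  set.seed(seed)
  out <- matrix(NA_real_, n, 3)
  i <- 1L
  while (i <= n) {
    p <- stats::runif(3, -radius, radius)
    if (sum(p^2) <= radius^2) {
      out[i, ] <- p
      i <- i + 1L
    }
  }
  out
}

# brute-force single-linkage connected components (independent oracle)
bruteClusters <- function(positions, cutoff) {
  n <- nrow(positions)
  labels <- seq_len(n)
  d <- as.matrix(stats::dist(positions))
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      linked <- which(d[i, ] <= cutoff)
      m <- min(labels[linked])
      if (any(labels[linked] != m)) {
        labels[linked] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(labels, sort(unique(labels)))
}

# 3D rotation matrix from axis-angle (for invariance tests)
rotationMatrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c1 <- cos(angle); s1 <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + s1 * K + (1 - c1) * (K %*% K)
}
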