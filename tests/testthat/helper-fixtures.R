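# Shared fixtures, built in code.

two_atom_pdb <- function() {
  paste(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       2.000   2.000   3.000  1.00 10.00           C",
    sep = "\n")
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

rotation_xyz <- function(a, b, c) {
  # intrinsic z-y-x rotation from three angles in radians
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(c), sin(c), 0, -sin(c), cos(c)), 3, 3)
  Rz %*% Ry %*% Rx
}

# brute-force minimum RMSD over a fine rotational grid (independent oracle
# for the Kabsch fit); both sets are centred first, so only rotation matters
grid_search_rmsd <- function(ref, mob, coarse = 12, refine = 2) {
  ref <- sweep(ref, 2, colMeans(ref))
  mob <- sweep(mob, 2, colMeans(mob))
  rmsd_at <- function(a, b, c) {
    R <- rotation_xyz(a, b, c)
    sqrt(mean(rowSums((mob %*% t(R) - ref)^2)))
  }
  step <- 2 * pi / coarse
  angles <- seq(0, 2 * pi - step, by = step)
  grid <- as.matrix(expand.grid(a = angles, b = angles, c = angles))
  vals <- apply(grid, 1, function(g) rmsd_at(g[1], g[2], g[3]))
  # polish from the best few coarse cells by direct simplex minimisation
  best <- min(vals)
  for (i in order(vals)[1:refine]) {
    opt <- stats::optim(grid[i, ], function(g) rmsd_at(g[1], g[2], g[3]),
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 2000))
    best <- min(best, opt$value)
  }
  best
}

# exhaustive optimal 2-partition WCSS (oracle for k-means at k = 2)
exhaustive_wcss_k2 <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    g <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    if (!any(g) || all(g)) next
    w <- 0
    for (side in list(g, !g)) {
      sub <- X[side, , drop = FALSE]
      ctr <- colMeans(sub)
      w <- w + sum(sweep(sub, 2, ctr)^2)
    }
    best <- min(best, w)
  }
  best
}
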