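# Seeded synthetic generators: ideal-geometry helices (for dihedral and
# geometry QC round trips), perturbed structure pairs (for the pruning
# protocol), Gaussian-mixture descriptor sets (for clustering recovery) and
# two-population docking-score tables (for the statistics module). All
# generators are pure functions of their arguments: a fixed seed gives
# bitwise-identical output.

with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Natural-extension reference frame: place atom D given positions A, B, C,
# the C-D bond length, the B-C-D bond angle (deg) and the A-B-C-D torsion
# (deg).
nerf_place <- function(a, b, c, length, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  d_local <- c(-length * cos(ang),
               length * sin(ang) * cos(tor),
               length * sin(ang) * sin(tor))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma::cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cbind(bc, pracma::cross(n, bc), n)
  c + as.vector(m %*% d_local)
}

#' Build an ideal polypeptide backbone with prescribed dihedrals
#'
#' Constructs an N/CA/C/O backbone by sequential internal-to-Cartesian
#' placement using the ideal covalent geometry of [ideal_backbone_table()]
#' and the requested phi/psi/omega torsions (defaults: an alpha helix).
#' The carbonyl O is placed anti to the following amide N (torsion
#' N-CA-C-O = psi - 180). Deterministic: identical specs give
#' bitwise-identical coordinates.
#'
#' @param n_res Number of residues (>= 3).
#' @param phi,psi,omega Backbone torsions in degrees; scalars are recycled
#'   along the chain.
#' @param sequence Optional vector of three-letter residue names (recycled);
#'   default `"ALA"`.
#' @param chain Chain identifier.
#' @return A `structure_model` with 4 backbone atoms per residue.
#' @export
build_helix <- function(n_res, phi = -57, psi = -47, omega = 180,
                        sequence = "ALA", chain = "A") {
  if (n_res < 3) stop("n_res must be >= 3")
  tab <- ideal_backbone_table()
  bl <- stats::setNames(tab$bonds$mean, tab$bonds$name)
  ba <- stats::setNames(tab$angles$mean, tab$angles$name)
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)
  omega <- rep_len(omega, n_res)
  sequence <- rep_len(sequence, n_res)

  N <- matrix(0, n_res, 3); CA <- matrix(0, n_res, 3)
  C <- matrix(0, n_res, 3); O <- matrix(0, n_res, 3)
  # first residue in a canonical frame
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(bl["N-CA"], 0, 0)
  ang <- deg2rad(ba["N-CA-C"])
  C[1, ] <- CA[1, ] + bl["CA-C"] * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res - 1)) {
    N[i + 1, ] <- nerf_place(N[i, ], CA[i, ], C[i, ],
                             bl["C-N"], ba["CA-C-N"], psi[i])
    CA[i + 1, ] <- nerf_place(CA[i, ], C[i, ], N[i + 1, ],
                              bl["N-CA"], ba["C-N-CA"], omega[i])
    C[i + 1, ] <- nerf_place(C[i, ], N[i + 1, ], CA[i + 1, ],
                             bl["CA-C"], ba["N-CA-C"], phi[i + 1])
  }
  for (i in seq_len(n_res)) {
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ],
                         bl["C-O"], ba["CA-C-O"], psi[i] - 180)
  }

  per_res <- function(i) {
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    data.frame(
      serial = 0L, name = c("N", "CA", "C", "O"), altloc = "",
      resname = sequence[i], chain = chain, resseq = i, icode = "",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occupancy = 1, bfactor = 0,
      element = c("N", "C", "C", "O"), het = FALSE,
      stringsAsFactors = FALSE
    )
  }
  atoms <- do.call(rbind, lapply(seq_len(n_res), per_res))
  atoms$serial <- seq_len(nrow(atoms))
  new_structure_model(1L, atoms)
}

#' Perturb a structure into a known "core + outlier" partner
#'
#' Applies a rigid motion to every atom, adds seeded i.i.d. Gaussian
#' coordinate noise, then adds a fixed displacement vector to the atoms of a
#' chosen residue subset. The result is a fixture with a known structural
#' core and known outlier residues for testing the iterative-pruning RMSD
#' protocol.
#'
#' @param model A `structure_model`.
#' @param rotation 3x3 rotation matrix (default identity).
#' @param translation Length-3 translation (Angstrom).
#' @param noise_sd Per-axis Gaussian noise sd (Angstrom, >= 0).
#' @param displaced Integer vector of residue numbers (`resseq`) to displace.
#' @param displacement Length-3 displacement added to those residues.
#' @param seed Seed for the noise draw.
#' @return A new `structure_model`.
#' @export
perturb_structure <- function(model, rotation = diag(3),
                              translation = c(0, 0, 0), noise_sd = 0,
                              displaced = integer(0),
                              displacement = c(0, 0, 0), seed = 1) {
  stopifnot(noise_sd >= 0)
  a <- model$atoms
  if (length(displaced) > 0 && !all(displaced %in% a$resseq)) {
    stop("displaced residue subset not present in model")
  }
  xyz <- coords_of(a) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  if (noise_sd > 0) {
    xyz <- xyz + with_local_seed(seed,
      matrix(stats::rnorm(length(xyz), 0, noise_sd), ncol = 3))
  }
  hit <- a$resseq %in% displaced
  xyz[hit, ] <- sweep(xyz[hit, , drop = FALSE], 2, displacement, "+")
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  new_structure_model(model$model_id, a)
}

#' Sample a Gaussian-mixture descriptor matrix with known labels
#'
#' Emulates a clustered odorant descriptor space: `k_true` well-separated
#' Gaussian components. Defaults follow the package's reference study
#' conditions: 5 components in 2 dimensions, unit sigma, centres on a
#' pentagon of circumradius 10 (pairwise separation about 11.8 sigma), 30
#' points per component. Optional nuisance columns (an exact linear copy and
#' a near-copy with correlation about 0.96) exercise the correlation filter.
#'
#' @param k_true Number of mixture components.
#' @param dims Dimensionality.
#' @param centers Optional `k_true x dims` matrix of component centres; the
#'   default places them on a circle of radius `separation`.
#' @param sigma Component standard deviation (isotropic).
#' @param n_per_cluster Points per component.
#' @param separation Circumradius used for the default centres.
#' @param nuisance Add the correlated nuisance columns?
#' @param seed RNG seed.
#' @return List with `dm` (a `descriptor_matrix`) and `labels` (true
#'   component of each row, in 1..k_true).
#' @export
gen_mixture <- function(k_true = 5, dims = 2, centers = NULL, sigma = 1,
                        n_per_cluster = 30, separation = 10,
                        nuisance = FALSE, seed = 1) {
  stopifnot(sigma > 0, k_true >= 1, dims >= 1)
  if (is.null(centers)) {
    th <- 2 * pi * (seq_len(k_true) - 1) / k_true
    centers <- matrix(0, k_true, dims)
    centers[, 1] <- separation * cos(th)
    if (dims >= 2) centers[, 2] <- separation * sin(th)
  }
  stopifnot(nrow(centers) == k_true, ncol(centers) == dims)
  with_local_seed(seed, {
    labels <- rep(seq_len(k_true), each = n_per_cluster)
    n <- length(labels)
    X <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * dims, 0, sigma), n, dims)
    colnames(X) <- paste0("D", seq_len(dims))
    if (nuisance) {
      exact <- 2 * X[, 1]
      # near-copy: scale noise so cor(X1, near) is ~0.96
      s <- stats::sd(X[, 1])
      near <- X[, 1] + stats::rnorm(n, 0, s * sqrt(1 / 0.96^2 - 1))
      X <- cbind(X, D_copy = exact, D_near = near)
    }
    dm <- descriptor_matrix(X, ids = sprintf("mol%03d", seq_len(n)),
                            provenance = "synthetic Gaussian mixture")
    list(dm = dm, labels = labels)
  })
}

#' Simulate a docking-score table with known actives
#'
#' Per receptor, binding energies are drawn from a normal distribution
#' N(base + shift_r, sd^2); a fraction of ligands are "active" and their
#' energies are shifted by `-delta` (lower energy = stronger predicted
#' binding). Responsiveness labels are attached, giving ground truth for
#' ROC and group-comparison tests.
#'
#' @param receptors Character vector of receptor ids.
#' @param shifts Per-receptor location shift (kcal/mol), recycled.
#' @param base Baseline mean energy (kcal/mol).
#' @param sd Noise standard deviation (> 0).
#' @param n_ligands Ligands per receptor.
#' @param active_fraction Fraction of active ligands, in (0, 1).
#' @param delta Activity shift (kcal/mol): actives score `delta` lower.
#' @param engine Engine label for the table.
#' @param seed RNG seed.
#' @return A `score_table` data frame with columns receptor, ligand, engine,
#'   value, responsive.
#' @export
gen_scores <- function(receptors = c("OR1", "OR2"), shifts = 0, base = -6,
                       sd = 1, n_ligands = 50, active_fraction = 0.5,
                       delta = 1, engine = "vina", seed = 1) {
  stopifnot(sd > 0, active_fraction > 0, active_fraction < 1)
  shifts <- rep_len(shifts, length(receptors))
  with_local_seed(seed, {
    rows <- lapply(seq_along(receptors), function(r) {
      n_act <- round(n_ligands * active_fraction)
      responsive <- c(rep(TRUE, n_act), rep(FALSE, n_ligands - n_act))
      value <- base + shifts[r] + stats::rnorm(n_ligands, 0, sd) -
        delta * responsive
      data.frame(
        receptor = receptors[r],
        ligand = sprintf("%s_lig%04d", receptors[r], seq_len(n_ligands)),
        engine = engine, value = value, responsive = responsive,
        stringsAsFactors = FALSE
      )
    })
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    class(tab) <- c("score_table", "data.frame")
    tab
  })
}
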