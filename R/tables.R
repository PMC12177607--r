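# Versioned in-source data tables: ideal backbone geometry, van der Waals
# radii, atomic masses, amino-acid code maps and Ramachandran region polygons.

#' Ideal backbone bond-length and bond-angle table
#'
#' Mean values and standard deviations for the protein backbone covalent
#' geometry (Engh & Huber-style restraint set, backbone subset only). Bond
#' lengths are in Angstrom, angles in degrees. This is the reference table
#' used both by the helix builder ([build_helix()]) and by the geometry
#' deviation counter ([bond_angle_deviations()]), so an unperturbed synthetic
#' helix scores zero deviations by construction.
#'
#' @return A list with two data frames, `bonds` (columns `name`, `mean`,
#'   `sd`) and `angles` (columns `name`, `mean`, `sd`).
#' @export
ideal_backbone_table <- function() {
  bonds <- data.frame(
    name = c("N-CA", "CA-C", "C-O", "C-N"),
    mean = c(1.458, 1.525, 1.231, 1.329),
    sd   = c(0.019, 0.021, 0.020, 0.014),
    stringsAsFactors = FALSE
  )
  angles <- data.frame(
    name = c("N-CA-C", "CA-C-N", "C-N-CA", "CA-C-O"),
    mean = c(111.2, 116.2, 121.7, 120.8),
    sd   = c(2.8, 2.0, 1.8, 1.7),
    stringsAsFactors = FALSE
  )
  list(bonds = bonds, angles = angles)
}

#' Van der Waals radii by element
#'
#' Radii (Angstrom) used for clash detection and solvent-accessible surface
#' area. Unknown elements fall back to `default` with a warning at the call
#' site.
#'
#' @return Named numeric vector of radii, including a `default` entry.
#' @export
vdw_radii_table <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, default = 1.70)
}

# Atomic masses (unified amu) for mass-weighted radius of gyration.
atomic_masses <- function() {
  c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
    F = 18.998, CL = 35.45, BR = 79.904, I = 126.904, default = 12.011)
}

# The 20 standard amino acids (three-letter codes).
standard_aa3 <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

# Three-letter -> one-letter residue codes; unknown residues map to "X".
aa3_to_aa1 <- function(resnames) {
  map <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  out <- map[toupper(resnames)]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Ramachandran region polygons
#'
#' Simplified polygonal favored/allowed boundaries on the phi/psi torus for
#' the four residue classes (General, Gly, Pro, PrePro), in the spirit of the
#' published high-resolution contour conventions. Each class carries a list
#' of `favored` polygons and a list of `allowed` polygons (each polygon a
#' two-column matrix of phi/psi vertices in degrees); the allowed polygons
#' are supersets of the favored ones. The table is an explicit, swappable
#' asset: [classify_rama()] accepts any object with the same shape.
#'
#' @return Named list of classes, each with elements `favored` and `allowed`
#'   (lists of n x 2 matrices).
#' @export
rama_region_table <- function() {
  poly <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    colnames(m) <- c("phi", "psi")
    m
  }
  # General class: alpha-helical, beta/extended and left-handed-alpha basins.
  gen_fav <- list(
    alpha = poly(-160, -75, -160, 10, -45, 10, -45, -75),
    beta  = poly(-175, 80, -175, 180, -45, 180, -45, 80),
    alphaL = poly(40, 0, 40, 90, 95, 90, 95, 0)
  )
  gen_all <- list(
    alpha = poly(-180, -120, -180, 35, -35, 35, -35, -120),
    beta  = poly(-180, 60, -180, 180, -35, 180, -35, 60),
    # extended basin wraps through psi = -180 == +180
    beta_wrap = poly(-180, -180, -180, -150, -100, -150, -100, -180),
    alphaL = poly(30, -20, 30, 100, 105, 100, 105, -20)
  )
  # Glycine: no side chain, the plot is nearly symmetric about the origin.
  gly_fav <- c(gen_fav, list(
    alphaR_mirror = poly(45, -90, 45, 10, 180, 10, 180, -90),
    beta_mirror   = poly(45, 150, 45, 180, 180, 180, 180, 150)
  ))
  gly_all <- c(gen_all, list(
    alphaR_mirror = poly(35, -120, 35, 35, 180, 35, 180, -120),
    beta_mirror   = poly(35, 120, 35, 180, 180, 180, 180, 120),
    beta_mirror_wrap = poly(35, -180, 35, -150, 180, -150, 180, -180)
  ))
  # Proline: phi pinned near -60 by the pyrrolidine ring.
  pro_fav <- list(
    alpha = poly(-100, -60, -100, 0, -45, 0, -45, -60),
    beta  = poly(-100, 100, -100, 180, -45, 180, -45, 100)
  )
  pro_all <- list(
    alpha = poly(-120, -75, -120, 20, -35, 20, -35, -75),
    beta  = poly(-120, 60, -120, 180, -35, 180, -35, 60),
    beta_wrap = poly(-120, -180, -120, -160, -35, -160, -35, -180)
  )
  # Pre-proline: like General but with the psi ~ +120 basin favored wider
  # and the alpha basin slightly tightened.
  prepro_fav <- list(
    alpha = poly(-150, -70, -150, 0, -50, 0, -50, -70),
    beta  = poly(-175, 80, -175, 180, -50, 180, -50, 80),
    alphaL = poly(40, 20, 40, 90, 90, 90, 90, 20)
  )
  prepro_all <- gen_all
  list(
    General = list(favored = gen_fav, allowed = gen_all),
    Gly     = list(favored = gly_fav, allowed = gly_all),
    Pro     = list(favored = pro_fav, allowed = pro_all),
    PrePro  = list(favored = prepro_fav, allowed = prepro_all)
  )
}
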