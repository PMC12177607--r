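# Backbone dihedrals, Ramachandran classification, simplified covalent and
# steric geometry QC, and Shrake-Rupley solvent accessible surface area.

vnorm <- function(v) sqrt(sum(v^2))

#' Signed torsion angle of four points
#'
#' Standard atan2 formulation of the dihedral about the p2-p3 axis. The
#' result is in degrees in the half-open interval [-180, 180) (so the
#' trans arrangement reports -180).
#'
#' @param p1,p2,p3,p4 Length-3 numeric vectors (Angstrom).
#' @return Angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (vnorm(b2) < 1e-9) stop("undefined torsion: p2 == p3")
  n1 <- pracma::cross(b1, b2)
  n2 <- pracma::cross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) {
    stop("undefined torsion: collinear points")
  }
  m1 <- pracma::cross(n1, b2 / vnorm(b2))
  # IUPAC sign: clockwise rotation of p4 relative to p1 viewed along p2->p3
  ang <- -rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
  if (ang >= 180) ang <- ang - 360
  if (ang < -180) ang <- ang + 360
  if (ang == 180) ang <- -180
  ang
}

backbone_by_residue <- function(model) {
  a <- model$atoms
  prot <- !a$het & a$resname %in% standard_aa3()
  a <- a[prot & a$name %in% c("N", "CA", "C"), , drop = FALSE]
  keys <- unique(res_key(a$chain, a$resseq, a$icode))
  k <- res_key(a$chain, a$resseq, a$icode)
  res <- lapply(keys, function(kk) {
    sub <- a[k == kk, , drop = FALSE]
    pos <- function(nm) {
      i <- which(sub$name == nm)
      if (length(i) == 0) NULL else as.numeric(sub[i[1], c("x", "y", "z")])
    }
    list(key = kk, resname = sub$resname[1], chain = sub$chain[1],
         N = pos("N"), CA = pos("CA"), C = pos("C"))
  })
  res
}

#' Backbone phi/psi dihedrals of a model
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1).
#' A peptide-bond break (C(i-1)-N(i) distance > `break_cutoff`) is treated
#' as a chain terminus, leaving the adjacent phi/psi undefined. Residue
#' classes: `Gly` and `Pro` by residue name, `PrePro` when the successor is
#' a proline, otherwise `General`.
#'
#' @param model A `structure_model` with backbone N, CA, C atoms.
#' @param break_cutoff Peptide C-N distance (Angstrom) beyond which the
#'   chain is considered broken (default 2.5).
#' @return Data frame with columns `key`, `resname`, `class`, `phi`, `psi`
#'   (degrees, NA when undefined). Residues missing a backbone atom are
#'   skipped with a warning.
#' @export
phi_psi <- function(model, break_cutoff = 2.5) {
  res <- backbone_by_residue(model)
  ok <- vapply(res, function(r)
    !is.null(r$N) && !is.null(r$CA) && !is.null(r$C), logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " residue(s) missing backbone atoms skipped")
    res <- res[ok]
  }
  n <- length(res)
  if (n == 0) {
    return(data.frame(key = character(0), resname = character(0),
                      class = character(0), phi = numeric(0),
                      psi = numeric(0), stringsAsFactors = FALSE))
  }
  linked_prev <- c(FALSE, vapply(seq_len(n)[-1], function(i) {
    res[[i]]$chain == res[[i - 1]]$chain &&
      vnorm(res[[i]]$N - res[[i - 1]]$C) <= break_cutoff
  }, logical(1)))
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (linked_prev[i]) {
      phi[i] <- dihedral(res[[i - 1]]$C, res[[i]]$N, res[[i]]$CA, res[[i]]$C)
    }
    if (i < n && linked_prev[i + 1]) {
      psi[i] <- dihedral(res[[i]]$N, res[[i]]$CA, res[[i]]$C, res[[i + 1]]$N)
    }
  }
  resname <- vapply(res, `[[`, character(1), "resname")
  cls <- ifelse(resname == "GLY", "Gly",
         ifelse(resname == "PRO", "Pro", "General"))
  succ_pro <- c(resname[-1] == "PRO" & linked_prev[-1], FALSE)
  cls[succ_pro & cls == "General"] <- "PrePro"
  data.frame(key = vapply(res, `[[`, character(1), "key"),
             resname = resname, class = cls, phi = phi, psi = psi,
             stringsAsFactors = FALSE)
}

wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y
}

point_in_regions <- function(phi, psi, polys) {
  # torus wraparound: test the point and its +/-360 translates
  for (dx in c(-360, 0, 360)) for (dy in c(-360, 0, 360)) {
    for (p in polys) {
      if (pracma::inpolygon(phi + dx, psi + dy, p[, 1], p[, 2],
                            boundary = TRUE)) return(TRUE)
    }
  }
  FALSE
}

#' Classify phi/psi records into Ramachandran regions
#'
#' Each defined (phi, psi) pair is labelled `Favored`, `Allowed` or
#' `Outlier` by a point-in-polygon test against the per-class region table
#' (with torus wraparound); undefined dihedrals are labelled `Undefined`.
#' Glycine and proline residues are judged against their own region tables.
#'
#' @param records Data frame from [phi_psi()].
#' @param region_tables Region table (default [rama_region_table()]).
#' @return List with `records` (input plus a `region` column) and `summary`
#'   (`n_evaluated`, `favored_pct`, `allowed_pct`, `outlier_pct`, and a
#'   `degenerate` flag raised when no residue could be evaluated).
#' @export
classify_rama <- function(records, region_tables = rama_region_table()) {
  region <- rep("Undefined", nrow(records))
  for (i in seq_len(nrow(records))) {
    if (is.na(records$phi[i]) || is.na(records$psi[i])) next
    cls <- records$class[i]
    tab <- region_tables[[cls]]
    if (is.null(tab)) stop("configuration error: no region table for class ", cls)
    phi <- wrap180(records$phi[i]); psi <- wrap180(records$psi[i])
    region[i] <- if (point_in_regions(phi, psi, tab$favored)) "Favored"
      else if (point_in_regions(phi, psi, tab$allowed)) "Allowed"
      else "Outlier"
  }
  records$region <- region
  ev <- region != "Undefined"
  n_ev <- sum(ev)
  pct <- function(what) if (n_ev == 0) 0 else 100 * sum(region[ev] == what) / n_ev
  list(records = records,
       summary = list(n_evaluated = n_ev,
                      favored_pct = pct("Favored"),
                      allowed_pct = pct("Allowed"),
                      outlier_pct = pct("Outlier"),
                      degenerate = n_ev == 0))
}

bond_angle_observations <- function(model, break_cutoff = 2.5) {
  res <- backbone_by_residue(model)
  res <- Filter(function(r) !is.null(r$N) && !is.null(r$CA) && !is.null(r$C), res)
  n <- length(res)
  a <- model$atoms
  o_tab <- a[!a$het & a$name == "O", , drop = FALSE]
  o_key <- res_key(o_tab$chain, o_tab$resseq, o_tab$icode)
  Opos <- function(kk) {
    i <- which(o_key == kk)
    if (length(i) == 0) NULL else as.numeric(o_tab[i[1], c("x", "y", "z")])
  }
  angle <- function(p, q, r) {
    v1 <- p - q; v2 <- r - q
    rad2deg(acos(max(-1, min(1, sum(v1 * v2) / (vnorm(v1) * vnorm(v2))))))
  }
  bonds <- list(); angles <- list()
  add <- function(lst, name, value) { lst[[length(lst) + 1L]] <- list(name = name, value = value); lst }
  for (i in seq_len(n)) {
    r <- res[[i]]
    bonds <- add(bonds, "N-CA", vnorm(r$CA - r$N))
    bonds <- add(bonds, "CA-C", vnorm(r$C - r$CA))
    O <- Opos(r$key)
    if (!is.null(O)) {
      bonds <- add(bonds, "C-O", vnorm(O - r$C))
      angles <- add(angles, "CA-C-O", angle(r$CA, r$C, O))
    }
    angles <- add(angles, "N-CA-C", angle(r$N, r$CA, r$C))
    if (i < n) {
      nx <- res[[i + 1]]
      if (nx$chain == r$chain && vnorm(nx$N - r$C) <= break_cutoff) {
        bonds <- add(bonds, "C-N", vnorm(nx$N - r$C))
        angles <- add(angles, "CA-C-N", angle(r$CA, r$C, nx$N))
        angles <- add(angles, "C-N-CA", angle(r$C, nx$N, nx$CA))
      }
    }
  }
  list(
    bonds = data.frame(name = vapply(bonds, `[[`, character(1), "name"),
                       value = vapply(bonds, `[[`, numeric(1), "value"),
                       stringsAsFactors = FALSE),
    angles = data.frame(name = vapply(angles, `[[`, character(1), "name"),
                        value = vapply(angles, `[[`, numeric(1), "value"),
                        stringsAsFactors = FALSE)
  )
}

#' Count backbone bond-length and bond-angle deviations
#'
#' Each evaluated backbone bond (N-CA, CA-C, C-O, peptide C-N) and angle
#' (N-CA-C, CA-C-N, C-N-CA, CA-C-O) is flagged bad when its absolute
#' deviation from the ideal mean exceeds `z_threshold` standard deviations
#' of the ideal table.
#'
#' @param model A `structure_model`.
#' @param ideal_table Ideal geometry table (default
#'   [ideal_backbone_table()]).
#' @param z_threshold Deviation threshold in sigma units (default 4).
#' @return List with `bad_bonds`, `n_bonds`, `bond_fraction`, `bad_angles`,
#'   `n_angles`, `angle_fraction`.
#' @export
bond_angle_deviations <- function(model, ideal_table = ideal_backbone_table(),
                                  z_threshold = 4) {
  obs <- bond_angle_observations(model)
  flag <- function(df, ref) {
    if (nrow(df) == 0) return(c(bad = 0L, n = 0L))
    m <- ref$mean[match(df$name, ref$name)]
    s <- ref$sd[match(df$name, ref$name)]
    z <- abs(df$value - m) / s
    c(bad = sum(z > z_threshold), n = nrow(df))
  }
  b <- flag(obs$bonds, ideal_table$bonds)
  a <- flag(obs$angles, ideal_table$angles)
  list(bad_bonds = unname(b["bad"]), n_bonds = unname(b["n"]),
       bond_fraction = if (b["n"] > 0) unname(b["bad"] / b["n"]) else 0,
       bad_angles = unname(a["bad"]), n_angles = unname(a["n"]),
       angle_fraction = if (a["n"] > 0) unname(a["bad"] / a["n"]) else 0)
}

# Bond connectivity: backbone template bonds (N-CA, CA-C, C-O, CA-CB and
# the peptide C-N link) plus distance-based bonding (< 1.9 A) for all other
# heavy-atom pairs within a residue or between adjacent residues.
infer_bonds <- function(atoms) {
  n <- nrow(atoms)
  rk <- res_key(atoms$chain, atoms$resseq, atoms$icode)
  keys <- unique(rk)
  bonds <- list()
  add <- function(i, j) bonds[[length(bonds) + 1L]] <<- c(i, j)
  find <- function(kk, nm) {
    i <- which(rk == kk & atoms$name == nm)
    if (length(i) == 0) NA_integer_ else i[1]
  }
  xyz <- coords_of(atoms)
  for (qi in seq_along(keys)) {
    kk <- keys[qi]
    idx <- which(rk == kk)
    tmpl <- list(c("N", "CA"), c("CA", "C"), c("C", "O"), c("CA", "CB"))
    bonded <- matrix(FALSE, length(idx), length(idx))
    for (tp in tmpl) {
      i <- find(kk, tp[1]); j <- find(kk, tp[2])
      if (!is.na(i) && !is.na(j)) {
        add(i, j)
        bonded[match(i, idx), match(j, idx)] <- TRUE
        bonded[match(j, idx), match(i, idx)] <- TRUE
      }
    }
    # distance fallback for remaining pairs within the residue
    if (length(idx) > 1) {
      for (u in seq_along(idx)[-1]) for (v in seq_len(u - 1)) {
        if (!bonded[u, v] &&
            vnorm(xyz[idx[u], ] - xyz[idx[v], ]) < 1.9) add(idx[u], idx[v])
      }
    }
    if (qi < length(keys)) {
      i <- find(kk, "C"); j <- find(keys[qi + 1], "N")
      if (!is.na(i) && !is.na(j) && vnorm(xyz[i, ] - xyz[j, ]) < 2.5) add(i, j)
    }
  }
  bonds
}

# adjacency list -> matrix of graph distances up to maxd (sparse BFS)
graph_within <- function(n, bonds, maxd = 3) {
  adj <- vector("list", n)
  for (b in bonds) {
    adj[[b[1]]] <- c(adj[[b[1]]], b[2])
    adj[[b[2]]] <- c(adj[[b[2]]], b[1])
  }
  near <- vector("list", n)
  for (i in seq_len(n)) {
    dist <- c(i)
    frontier <- i
    seen <- i
    for (d in seq_len(maxd)) {
      frontier <- unique(unlist(adj[frontier], use.names = FALSE))
      frontier <- setdiff(frontier, seen)
      if (length(frontier) == 0) break
      seen <- c(seen, frontier)
    }
    near[[i]] <- seen
  }
  near
}

spatial_hash_pairs <- function(xyz, cutoff) {
  # O(n) neighbour candidate generation via grid hashing
  cell <- cutoff
  g <- floor(xyz / cell)
  key <- paste(g[, 1], g[, 2], g[, 3])
  buckets <- split(seq_len(nrow(xyz)), key)
  coord <- do.call(rbind, strsplit(names(buckets), " "))
  coord <- matrix(as.integer(coord), ncol = 3)
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(buckets)) assign(names(buckets)[i], buckets[[i]], envir = lookup)
  pairs <- list()
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  for (i in seq_along(buckets)) {
    ids <- buckets[[i]]
    if (length(ids) > 1) {
      cmb <- utils::combn(ids, 2)
      pairs[[length(pairs) + 1L]] <- t(cmb)
    }
    for (o in seq_len(nrow(offs))) {
      if (all(offs[o, ] == 0)) next
      nk <- paste(coord[i, 1] + offs[o, 1], coord[i, 2] + offs[o, 2],
                  coord[i, 3] + offs[o, 3])
      nb <- if (exists(nk, envir = lookup, inherits = FALSE))
        get(nk, envir = lookup) else NULL
      # visit each cell pair once
      if (!is.null(nb) && min(nb) > min(ids)) {
        pairs[[length(pairs) + 1L]] <- as.matrix(expand.grid(ids, nb))
      } else if (!is.null(nb) && length(ids) > 0 && length(nb) > 0 &&
                 min(nb) < min(ids)) {
        # handled from the other side
      }
    }
  }
  if (length(pairs) == 0) return(matrix(integer(0), 0, 2))
  out <- do.call(rbind, pairs)
  d2 <- rowSums((xyz[out[, 1], , drop = FALSE] - xyz[out[, 2], , drop = FALSE])^2)
  out[d2 <= cutoff^2, , drop = FALSE]
}

#' Steric clashscore
#'
#' Counts unordered heavy-atom pairs whose van der Waals spheres
#' interpenetrate by at least `overlap_cutoff` Angstrom, excluding pairs
#' within 3 covalent bonds of each other (connectivity inferred from
#' backbone templates plus distance-based bonding). The score is overlaps
#' per 1000 heavy atoms. Neighbour search uses spatial grid hashing.
#'
#' @param model A `structure_model`.
#' @param radii_table Named radii vector (default [vdw_radii_table()]).
#' @param overlap_cutoff Overlap threshold (default 0.4 A).
#' @return List with `clashes`, `n_atoms`, `clashscore`.
#' @export
clashscore <- function(model, radii_table = vdw_radii_table(),
                       overlap_cutoff = 0.4) {
  heavy <- model$atoms[model$atoms$element != "H", , drop = FALSE]
  n <- nrow(heavy)
  if (n == 0) return(list(clashes = 0L, n_atoms = 0L, clashscore = 0))
  r <- radii_table[heavy$element]
  if (anyNA(r)) {
    warning("unknown element(s) assigned default radius: ",
            paste(unique(heavy$element[is.na(r)]), collapse = ", "))
    r[is.na(r)] <- radii_table["default"]
  }
  r <- unname(r)
  xyz <- coords_of(heavy)
  near <- graph_within(n, infer_bonds(heavy), maxd = 3)
  cand <- spatial_hash_pairs(xyz, cutoff = 2 * max(r))
  clashes <- 0L
  if (nrow(cand) > 0) {
    for (p in seq_len(nrow(cand))) {
      i <- cand[p, 1]; j <- cand[p, 2]
      if (j %in% near[[i]]) next
      d <- vnorm(xyz[i, ] - xyz[j, ])
      if (r[i] + r[j] - d >= overlap_cutoff) clashes <- clashes + 1L
    }
  }
  list(clashes = clashes, n_atoms = n, clashscore = 1000 * clashes / n)
}

# Deterministic near-uniform spherical point set (Fibonacci lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Each heavy atom is covered with a deterministic spherical lattice of
#' `n_points` test points at radius r_i + probe; a point is accessible when
#' it lies outside every neighbouring atom's expanded sphere. Atom SASA is
#' the accessible fraction of 4 pi (r_i + probe)^2.
#'
#' @param model A `structure_model` (hydrogens ignored).
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Test points per atom (>= 32; default 960).
#' @param radii_table Named radii vector (default [vdw_radii_table()]).
#' @return List with `total` (Angstrom^2) and `per_residue` (named vector
#'   keyed by residue).
#' @export
sasa <- function(model, probe = 1.4, n_points = 960,
                 radii_table = vdw_radii_table()) {
  if (n_points < 32) stop("n_points must be >= 32")
  heavy <- model$atoms[model$atoms$element != "H", , drop = FALSE]
  n <- nrow(heavy)
  if (n == 0) return(list(total = 0, per_residue = numeric(0)))
  r <- radii_table[heavy$element]
  if (anyNA(r)) {
    warning("unknown element(s) assigned default radius")
    r[is.na(r)] <- radii_table["default"]
  }
  r <- unname(r) + probe
  xyz <- coords_of(heavy)
  pts <- sphere_points(n_points)
  cand <- spatial_hash_pairs(xyz, cutoff = 2 * max(r))
  neigh <- vector("list", n)
  if (nrow(cand) > 0) {
    for (p in seq_len(nrow(cand))) {
      i <- cand[p, 1]; j <- cand[p, 2]
      if (vnorm(xyz[i, ] - xyz[j, ]) < r[i] + r[j]) {
        neigh[[i]] <- c(neigh[[i]], j)
        neigh[[j]] <- c(neigh[[j]], i)
      }
    }
  }
  area <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in neigh[[i]]) {
      d2 <- rowSums(sweep(p, 2, xyz[j, ])^2)
      acc <- acc & d2 > r[j]^2
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * r[i]^2 * mean(acc)
  }
  rk <- res_key(heavy$chain, heavy$resseq, heavy$icode)
  list(total = sum(area),
       per_residue = vapply(split(area, factor(rk, levels = unique(rk))),
                            sum, numeric(1)))
}

#' Aggregate geometry quality report
#'
#' Combines Ramachandran classification, backbone bond/angle deviation
#' counts, clashscore and total SASA into a single deterministic report.
#'
#' @param model A `structure_model`.
#' @param z_threshold Deviation threshold for [bond_angle_deviations()].
#' @param overlap_cutoff Overlap threshold for [clashscore()].
#' @param probe,n_points SASA parameters.
#' @return A `geometry_report` list (also serialisable to JSON) with
#'   `n_residues`, `rama_favored_pct`, `rama_allowed_pct`,
#'   `rama_outlier_pct`, bond/angle counts and fractions, `clashscore` and
#'   `sasa_total`.
#' @export
quality_report <- function(model, z_threshold = 4, overlap_cutoff = 0.4,
                           probe = 1.4, n_points = 960) {
  pp <- phi_psi(model)
  rama <- classify_rama(pp)
  ba <- bond_angle_deviations(model, z_threshold = z_threshold)
  cs <- clashscore(model, overlap_cutoff = overlap_cutoff)
  sa <- sasa(model, probe = probe, n_points = n_points)
  structure(list(
    n_residues = nrow(pp),
    rama_evaluated = rama$summary$n_evaluated,
    rama_favored_pct = rama$summary$favored_pct,
    rama_allowed_pct = rama$summary$allowed_pct,
    rama_outlier_pct = rama$summary$outlier_pct,
    bad_bond_count = ba$bad_bonds, bad_bond_fraction = ba$bond_fraction,
    bad_angle_count = ba$bad_angles, bad_angle_fraction = ba$angle_fraction,
    clashscore = cs$clashscore,
    sasa_total = sa$total
  ), class = "geometry_report")
}

#' @export
print.geometry_report <- function(x, ...) {
  cat(sprintf(
    paste0("geometry report: %d residues | Ramachandran favored %.1f%% / ",
           "outliers %.1f%% | bad bonds %d (%.2f%%) | bad angles %d (%.2f%%) | ",
           "clashscore %.1f | SASA %.0f A^2\n"),
    x$n_residues, x$rama_favored_pct, x$rama_outlier_pct,
    x$bad_bond_count, 100 * x$bad_bond_fraction,
    x$bad_angle_count, 100 * x$bad_angle_fraction,
    x$clashscore, x$sasa_total))
  invisible(x)
}
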