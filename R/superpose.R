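# Rigid-body superposition (Kabsch), the iterative-pruning RMSD protocol,
# ensemble observables (RMSD series, RMSF, radius of gyration) and
# benchmark-table summarisation.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rotation/translation minimising the (optionally weighted) RMSD
#' between two paired coordinate sets. Reflections are excluded: the
#' rotation determinant is forced to +1 by the usual sign correction on the
#' smallest singular vector.
#'
#' @param ref_coords,mob_coords N x 3 matrices of paired coordinates
#'   (Angstrom), N >= 3.
#' @param weights Optional non-negative weights of length N.
#' @return List with `rotation` (3x3), `translation` (length 3; the fitted
#'   mobile coordinates are `mob %*% t(rotation) + translation`) and `rmsd`
#'   (Angstrom). Collinear inputs fit with a warning.
#' @export
kabsch <- function(ref_coords, mob_coords, weights = NULL) {
  ref_coords <- as.matrix(ref_coords); mob_coords <- as.matrix(mob_coords)
  n <- nrow(ref_coords)
  if (n < 3 || nrow(mob_coords) != n) stop("need >= 3 paired coordinates")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cr <- colSums(ref_coords * w)
  cm <- colSums(mob_coords * w)
  P <- sweep(mob_coords, 2, cm)   # mobile, centered
  Q <- sweep(ref_coords, 2, cr)
  H <- t(P * w) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (sum(sv$d > 1e-10) < 2) {
    warning("degenerate (collinear) input; fit returned")
  }
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)     # rotation: fitted = P %*% t(R)
  fitted <- P %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - Q)^2)))
  list(rotation = R, translation = as.vector(cr - (cm %*% t(R))), rmsd = rmsd)
}

apply_transform <- function(coords, tr) {
  sweep(as.matrix(coords) %*% t(tr$rotation), 2, tr$translation, "+")
}

#' Pair residues between two models
#'
#' `numbering` mode pairs residues sharing an identical (chain, resseq,
#' icode) key; `alignment` mode derives one-letter sequences from the
#' CA-bearing residues in file order and pairs the aligned non-gap columns
#' of a global Needleman-Wunsch alignment (BLOSUM62, affine gaps: open 10,
#' extend 0.5). Only residues possessing a CA atom are paired.
#'
#' @param ref,mob `structure_model`s with >= 3 CA-bearing residues.
#' @param mode `"numbering"` or `"alignment"`.
#' @param gap_open,gap_extend Affine gap penalties (alignment mode).
#' @return A `residue_pairing`: list with `pairs` (data frame of `ref_key`,
#'   `mob_key`), `source`, and `score` (alignment mode only). Fewer than 3
#'   pairs is an error.
#' @export
pair_residues <- function(ref, mob, mode = c("numbering", "alignment"),
                          gap_open = 10, gap_extend = 0.5) {
  mode <- match.arg(mode)
  ca_r <- select_atoms(ref, "CA")
  ca_m <- select_atoms(mob, "CA")
  if (nrow(ca_r) < 3 || nrow(ca_m) < 3) {
    stop("pairing error: need >= 3 CA-bearing residues in both models")
  }
  kr <- res_key(ca_r$chain, ca_r$resseq, ca_r$icode)
  km <- res_key(ca_m$chain, ca_m$resseq, ca_m$icode)
  score <- NA_real_
  if (mode == "numbering") {
    common <- intersect(kr, km)
    pairs <- data.frame(ref_key = common, mob_key = common,
                        stringsAsFactors = FALSE)
  } else {
    sr <- paste(aa3_to_aa1(ca_r$resname), collapse = "")
    sm <- paste(aa3_to_aa1(ca_m$resname), collapse = "")
    al <- Biostrings::pairwiseAlignment(
      sr, sm, type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = gap_open, gapExtension = gap_extend)
    score <- Biostrings::score(al)
    pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    ip <- cumsum(pa != "-")
    is <- cumsum(sa != "-")
    keep <- pa != "-" & sa != "-"
    pairs <- data.frame(ref_key = kr[ip[keep]], mob_key = km[is[keep]],
                        stringsAsFactors = FALSE)
  }
  if (nrow(pairs) < 3) stop("pairing error: fewer than 3 residue pairs")
  structure(list(pairs = pairs, source = mode, score = score),
            class = "residue_pairing")
}

ca_coords_by_key <- function(model, keys) {
  ca <- select_atoms(model, "CA")
  k <- res_key(ca$chain, ca$resseq, ca$icode)
  idx <- match(keys, k)
  if (anyNA(idx)) stop("paired residue lacks a CA atom")
  coords_of(ca[idx, , drop = FALSE])
}

#' Iterative-pruning RMSD between two structures
#'
#' Superposes the paired CA atoms by least squares, then iteratively removes
#' the worst-fitting pairs: at each cycle, with N current pairs and E of
#' them beyond `cutoff`, the `r = max(1, min(floor(frac_all * N),
#' floor(frac_exceed * |E|)))` farthest pairs are dropped (ties broken by
#' lower residue index) and the fit is recomputed, until no pair exceeds the
#' cutoff. This isolates the conserved structural core from flexible or
#' divergent regions. The result carries both the all-pair RMSD of the
#' initial fit and the final pruned RMSD.
#'
#' @param ref,mob `structure_model`s.
#' @param pairing A `residue_pairing` (default: numbering-mode pairing).
#' @param cutoff Distance cutoff in Angstrom (default 2.0).
#' @param frac_all Fraction of current pairs removable per cycle (0.10).
#' @param frac_exceed Fraction of cutoff-exceeding pairs removable (0.50).
#' @return A `superposition_result`: list with `transform`, `rmsd_all`,
#'   `n_all`, `rmsd_pruned`, `n_pruned`, `retained` (ref keys), `iterations`,
#'   `cutoff`, `converged`. Pruning stops (flagged non-converged) rather
#'   than leave fewer than 3 pairs.
#' @export
pruned_rmsd <- function(ref, mob, pairing = NULL, cutoff = 2.0,
                        frac_all = 0.10, frac_exceed = 0.50) {
  if (is.null(pairing)) pairing <- pair_residues(ref, mob, "numbering")
  pr <- pairing$pairs
  if (nrow(pr) < 3) stop("pairing error: fewer than 3 pairs")
  X <- ca_coords_by_key(ref, pr$ref_key)
  Y <- ca_coords_by_key(mob, pr$mob_key)
  keep <- seq_len(nrow(pr))
  it <- 0L
  rmsd_all <- NA_real_
  converged <- TRUE
  repeat {
    fit <- kabsch(X[keep, , drop = FALSE], Y[keep, , drop = FALSE])
    if (it == 0L) rmsd_all <- fit$rmsd
    d <- sqrt(rowSums((apply_transform(Y[keep, , drop = FALSE], fit) -
                         X[keep, , drop = FALSE])^2))
    exceed <- which(d > cutoff)
    if (length(exceed) == 0) break
    r <- max(1L, min(floor(frac_all * length(keep)),
                     floor(frac_exceed * length(exceed))))
    if (length(keep) - r < 3) { converged <- FALSE; break }
    # farthest r pairs; ties by lower residue index (stable order)
    drop_local <- order(-d, seq_along(d))[seq_len(r)]
    keep <- keep[-drop_local]
    it <- it + 1L
  }
  structure(list(
    transform = fit[c("rotation", "translation")],
    rmsd_all = rmsd_all, n_all = nrow(pr),
    rmsd_pruned = fit$rmsd, n_pruned = length(keep),
    retained = pr$ref_key[keep], iterations = it,
    cutoff = cutoff, converged = converged
  ), class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf(
    "superposition: RMSD %.3f A over %d pairs; pruned %.3f A over %d pairs (%d iterations, cutoff %.1f A)%s\n",
    x$rmsd_all, x$n_all, x$rmsd_pruned, x$n_pruned, x$iterations, x$cutoff,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

ensemble_selection_coords <- function(ens, selector) {
  lapply(ens$models, function(m) {
    sel <- select_atoms(m, selector)
    if (nrow(sel) == 0) stop("selection is empty")
    coords_of(sel)
  })
}

#' Per-model RMSD of an ensemble against a reference
#'
#' Each model is rigid-body fitted (Kabsch) to the reference on the chosen
#' selection and its RMSD recorded, emulating the RMSD-vs-time series of a
#' trajectory.
#'
#' @param ens An `ensemble`.
#' @param reference Model index (1-based) or a `structure_model`.
#' @param selector Atom selection (see [select_atoms()]).
#' @return Numeric vector of RMSDs (Angstrom), one per model.
#' @export
ensemble_rmsd <- function(ens, reference = 1, selector = "CA") {
  xs <- ensemble_selection_coords(ens, selector)
  ref <- if (inherits(reference, "structure_model")) {
    sel <- select_atoms(reference, selector)
    if (nrow(sel) == 0) stop("selection is empty")
    coords_of(sel)
  } else xs[[reference]]
  vapply(xs, function(x) kabsch(ref, x)$rmsd, numeric(1))
}

#' Per-atom root-mean-square fluctuation of an ensemble
#'
#' Models are superposed onto the ensemble mean structure, obtained by a
#' two-pass procedure (fit to model 1, average, refit to the average), and
#' RMSF_i is the root-mean-square deviation of atom i from its mean
#' position across models.
#'
#' @inheritParams ensemble_rmsd
#' @return Numeric vector, one value per selected atom (Angstrom).
#' @export
rmsf <- function(ens, selector = "CA") {
  if (length(ens$models) < 2) stop("RMSF requires >= 2 models")
  xs <- ensemble_selection_coords(ens, selector)
  fit_all <- function(ref) lapply(xs, function(x) {
    tr <- kabsch(ref, x); apply_transform(x, tr)
  })
  aligned <- fit_all(xs[[1]])
  mean_xyz <- Reduce(`+`, aligned) / length(aligned)
  aligned <- fit_all(mean_xyz)
  mean_xyz <- Reduce(`+`, aligned) / length(aligned)
  dev2 <- lapply(aligned, function(x) rowSums((x - mean_xyz)^2))
  sqrt(Reduce(`+`, dev2) / length(dev2))
}

#' Radius of gyration
#'
#' Rg = sqrt(sum_i w_i ||x_i - xbar||^2 / sum_i w_i) with the weighted
#' centroid xbar; a measure of overall compactness.
#'
#' @param model A `structure_model`.
#' @param weighting `"uniform"` or `"mass"` (atomic masses by element).
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(model, weighting = c("uniform", "mass")) {
  weighting <- match.arg(weighting)
  xyz <- coords_of(model$atoms)
  if (nrow(xyz) == 0) stop("model has no atoms")
  w <- if (weighting == "mass") {
    masses <- atomic_masses()
    m <- masses[model$atoms$element]
    m[is.na(m)] <- masses["default"]
    unname(m)
  } else rep(1, nrow(xyz))
  ctr <- colSums(xyz * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)) / sum(w))
}

#' Summarise a method x structure RMSD benchmark table
#'
#' Takes a rectangular table (rows = structures, columns = methods, values =
#' RMSD in Angstrom) and reports per-method mean, sd, min, max and the count
#' of cells used. Missing cells are skipped with a warning.
#'
#' @param table Data frame or matrix; non-numeric id columns are ignored.
#' @return Data frame with one row per method.
#' @export
summarize_rmsd_table <- function(table) {
  tab <- as.data.frame(table)
  num <- vapply(tab, is.numeric, logical(1))
  tab <- tab[, num, drop = FALSE]
  if (ncol(tab) == 0) stop("no numeric method columns in table")
  out <- lapply(names(tab), function(m) {
    v <- tab[[m]]
    if (all(is.na(v))) stop("empty method column: ", m)
    if (anyNA(v)) warning("missing cells skipped in method ", m)
    v <- v[!is.na(v)]
    data.frame(method = m, n = length(v), mean = mean(v), sd = stats::sd(v),
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
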