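# Fixed-column PDB v3.x coordinate I/O and the structure/ensemble data model
# shared by all downstream analyses. The reader is deliberately strict about
# column layout so that malformed records fail with a line number instead of
# propagating NA coordinates.

#' Residue key strings
#'
#' Canonical `chain|resseq|icode` identifiers used throughout to address
#' residues (an empty insertion code prints as `.`).
#'
#' @param chain,resseq,icode Vectors of chain ids, residue numbers and
#'   insertion codes.
#' @return Character vector of keys.
#' @export
res_key <- function(chain, resseq, icode) {
  paste(chain, resseq, ifelse(icode == "", ".", icode), sep = "|")
}

atom_key <- function(atoms) {
  paste(res_key(atoms$chain, atoms$resseq, atoms$icode), atoms$name, sep = "|")
}

#' Construct a structure model from an atom table
#'
#' @param model_id Integer model identifier.
#' @param atoms Atom data frame with the columns produced by [read_pdb()]
#'   (serial, name, altloc, resname, chain, resseq, icode, x, y, z,
#'   occupancy, bfactor, element, het).
#' @return A `structure_model`.
#' @export
new_structure_model <- function(model_id, atoms) {
  rownames(atoms) <- NULL
  m <- list(model_id = model_id, atoms = atoms)
  class(m) <- "structure_model"
  m
}

#' @export
print.structure_model <- function(x, ...) {
  nres <- length(unique(res_key(x$atoms$chain, x$atoms$resseq, x$atoms$icode)))
  cat(sprintf("structure_model: model %d, %d atoms, %d residues\n",
              x$model_id, nrow(x$atoms), nres))
  invisible(x)
}

#' Construct an ensemble from a list of structure models
#'
#' All models must share an identical atom-key topology (the fingerprint of
#' model 1); any deviation is an error.
#'
#' @param models List of `structure_model`s.
#' @return An `ensemble`.
#' @export
new_ensemble <- function(models) {
  topo <- atom_key(models[[1]]$atoms)
  for (i in seq_along(models)) {
    if (!identical(atom_key(models[[i]]$atoms), topo)) {
      stop("topology error: MODEL ", models[[i]]$model_id,
           " atom-key sequence differs from model 1")
    }
  }
  e <- list(models = models, topology = topo)
  class(e) <- "ensemble"
  e
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble: %d models, %d atoms each\n",
              length(x$models), length(x$topology)))
  invisible(x)
}

#' Number of models in an ensemble
#' @param ens An `ensemble`.
#' @return Integer model count.
#' @export
n_models <- function(ens) length(ens$models)

parse_pdb_field <- function(line, from, to) {
  n <- nchar(line)
  if (from > n) return("")
  trimws(substr(line, from, min(to, n)))
}

#' Read a PDB coordinate file or text into an ensemble
#'
#' Parses ATOM/HETATM records in PDB v3.x fixed-column format, honouring
#' MODEL/ENDMDL blocks (one `structure_model` per block; a single model if
#' none are present). Alternate locations are resolved per atom site:
#' the highest-occupancy altloc wins, ties go to the lexicographically
#' smallest altloc identifier. Hydrogens are retained; downstream selectors
#' can exclude them.
#'
#' @param source Path to a PDB file, or a character scalar/vector of PDB
#'   text (recognised as text when it contains a newline, a coordinate
#'   record, or has length > 1).
#' @param altloc_policy `"occupancy"` (default, as described above) or
#'   `"first"` (keep the first-seen altloc for each site).
#' @return An `ensemble`. All models must share an identical atom-key
#'   topology; a mismatch is an error.
#' @export
read_pdb <- function(source, altloc_policy = c("occupancy", "first")) {
  altloc_policy <- match.arg(altloc_policy)
  is_text <- length(source) > 1 ||
    grepl("\n", source) || grepl("^(ATOM|HETATM|MODEL)", source)
  lines <- if (is_text) {
    unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    readLines(source, warn = FALSE)
  }

  models <- list()
  cur <- NULL        # accumulating list of atom rows for the current model
  cur_id <- 1L
  in_model_block <- FALSE
  flush_model <- function(cur, cur_id) {
    if (is.null(cur) || length(cur) == 0) return(NULL)
    atoms <- do.call(rbind, cur)
    resolve_altlocs(atoms, altloc_policy)
  }

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    rec <- substr(line, 1, 6)
    if (startsWith(rec, "MODEL")) {
      if (in_model_block && length(cur) > 0) {
        models[[length(models) + 1L]] <- new_structure_model(cur_id, flush_model(cur, cur_id))
      }
      in_model_block <- TRUE
      id <- suppressWarnings(as.integer(parse_pdb_field(line, 7, 14)))
      cur_id <- if (is.na(id)) length(models) + 1L else id
      cur <- list()
    } else if (startsWith(rec, "ENDMDL")) {
      models[[length(models) + 1L]] <- new_structure_model(cur_id, flush_model(cur, cur_id))
      cur <- list()
      in_model_block <- FALSE
    } else if (rec == "ATOM  " || rec == "HETATM") {
      if (is.null(cur)) cur <- list()
      row <- parse_atom_line(line, i)
      cur[[length(cur) + 1L]] <- row
    }
    # TER / END / remarks ignored
  }
  if (length(cur) > 0) {
    models[[length(models) + 1L]] <- new_structure_model(
      if (length(models) == 0) 1L else cur_id, flush_model(cur, cur_id))
  }
  if (length(models) == 0) stop("parse error: no ATOM/HETATM records found")
  new_ensemble(models)
}

parse_atom_line <- function(line, lineno) {
  if (nchar(line) < 54) {
    stop("parse error at line ", lineno, ": record shorter than coordinate columns")
  }
  xyz <- suppressWarnings(as.numeric(c(
    substr(line, 31, 38), substr(line, 39, 46), substr(line, 47, 54))))
  serial <- suppressWarnings(as.integer(parse_pdb_field(line, 7, 11)))
  resseq <- suppressWarnings(as.integer(parse_pdb_field(line, 23, 26)))
  if (anyNA(xyz) || !all(is.finite(xyz)) || is.na(serial) || is.na(resseq)) {
    stop("parse error at line ", lineno, ": malformed fixed-column fields")
  }
  occ <- suppressWarnings(as.numeric(parse_pdb_field(line, 55, 60)))
  if (is.na(occ)) occ <- 1
  if (occ < 0 || occ > 1) {
    warning("occupancy ", occ, " at line ", lineno, " clamped to [0,1]")
    occ <- min(max(occ, 0), 1)
  }
  bf <- suppressWarnings(as.numeric(parse_pdb_field(line, 61, 66)))
  if (is.na(bf)) bf <- 0
  element <- toupper(parse_pdb_field(line, 77, 78))
  name <- parse_pdb_field(line, 13, 16)
  if (element == "") {
    # fall back to the first letter of the atom name (ignoring digits)
    element <- toupper(sub("^[0-9]*", "", name))
    element <- substr(element, 1, 1)
  }
  data.frame(
    serial = serial,
    name = name,
    altloc = parse_pdb_field(line, 17, 17),
    resname = parse_pdb_field(line, 18, 20),
    chain = parse_pdb_field(line, 22, 22),
    resseq = resseq,
    icode = parse_pdb_field(line, 27, 27),
    x = xyz[1], y = xyz[2], z = xyz[3],
    occupancy = occ, bfactor = bf,
    element = element,
    het = substr(line, 1, 6) == "HETATM",
    stringsAsFactors = FALSE
  )
}

resolve_altlocs <- function(atoms, policy) {
  if (all(atoms$altloc == "")) return(atoms)
  site <- atom_key(atoms)
  keep <- logical(nrow(atoms))
  for (s in unique(site)) {
    idx <- which(site == s)
    if (length(idx) == 1) {
      keep[idx] <- TRUE
    } else if (policy == "first") {
      keep[idx[1]] <- TRUE
    } else {
      occ <- atoms$occupancy[idx]
      best <- idx[occ == max(occ)]
      # occupancy tie: lexicographically smallest altloc wins
      keep[best[order(atoms$altloc[best])][1]] <- TRUE
    }
  }
  out <- atoms[keep, , drop = FALSE]
  out$altloc <- ""
  rownames(out) <- NULL
  out
}

#' Write an ensemble as PDB text
#'
#' Produces PDB v3.x fixed-column text; ensembles with more than one model
#' are wrapped in MODEL/ENDMDL blocks. Round-trip safe: re-reading the
#' output reproduces every atom key and coordinates to 3 decimals.
#'
#' @param ensemble An `ensemble` (or a single `structure_model`).
#' @param path Optional path; when given the text is also written to disk.
#' @return The PDB text, invisibly when `path` is given.
#' @export
write_pdb <- function(ensemble, path = NULL) {
  if (inherits(ensemble, "structure_model")) {
    ensemble <- new_ensemble(list(ensemble))
  }
  multi <- length(ensemble$models) > 1
  out <- character(0)
  for (m in ensemble$models) {
    a <- m$atoms
    if (any(abs(c(a$x, a$y, a$z)) >= 10000)) {
      stop("formatting error: coordinate exceeds PDB field width (|x| >= 10000)")
    }
    if (multi) out <- c(out, sprintf("MODEL     %4d", m$model_id))
    rec <- ifelse(a$het, "HETATM", "ATOM  ")
    # atom-name column convention: 1-3 char names start in column 14
    nm <- ifelse(nchar(a$name) >= 4, a$name, sprintf(" %-3s", a$name))
    out <- c(out, sprintf(
      "%s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, a$serial %% 100000L, nm, ifelse(a$altloc == "", " ", a$altloc),
      a$resname, a$chain, a$resseq, ifelse(a$icode == "", " ", a$icode),
      a$x, a$y, a$z, a$occupancy, a$bfactor, a$element))
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(txt))
  }
  txt
}

#' Select atoms from a structure model
#'
#' Protein selections (`CA`, `backbone`) are restricted to the 20 standard
#' amino-acid residue names and to ATOM records; HETATM ligands, waters and
#' ions are excluded from them. `heavy` drops hydrogens, `all` returns the
#' model unchanged.
#'
#' @param model A `structure_model`.
#' @param selector One of `"CA"`, `"backbone"`, `"heavy"`, `"all"`.
#' @return The atom data frame subset, in residue (file) order. A residue
#'   lacking a CA is skipped from the `CA` selection with a message.
#' @export
select_atoms <- function(model, selector = c("CA", "backbone", "heavy", "all")) {
  selector <- match.arg(selector)
  a <- model$atoms
  if (selector == "all") return(a)
  if (selector == "heavy") return(a[a$element != "H", , drop = FALSE])
  prot <- !a$het & a$resname %in% standard_aa3()
  if (selector == "backbone") {
    return(a[prot & a$name %in% c("N", "CA", "C", "O"), , drop = FALSE])
  }
  # CA: one atom per residue possessing a CA
  sel <- a[prot & a$name == "CA", , drop = FALSE]
  all_res <- unique(res_key(a$chain[prot], a$resseq[prot], a$icode[prot]))
  missing <- setdiff(all_res, res_key(sel$chain, sel$resseq, sel$icode))
  if (length(missing) > 0) {
    message(length(missing), " residue(s) lacking CA skipped from selection")
  }
  sel
}

#' Coordinate matrix of an atom table
#'
#' @param atoms Atom data frame (e.g. from [select_atoms()]).
#' @return Unnamed n x 3 matrix of x, y, z.
#' @export
coords_of <- function(atoms) {
  unname(as.matrix(atoms[, c("x", "y", "z"), drop = FALSE]))
}
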