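# Structure and SAXS-profile input/output, plus symmetry expansion of
# crystallographic assemblies.  Coordinates are Angstrom throughout and
# author residue numbering is the canonical addressing scheme.

ATOM_COLUMNS <- c("type", "eleno", "elety", "resid", "chain", "resno",
                  "insert", "x", "y", "z", "o", "b", "elesy")

#' Construct a structure model
#'
#' A `structure_model` is an ordered atom table (one row per atom) plus the
#' list of rigid-body operators that produced it (empty for models read
#' straight from a file).  Atom fields follow crystallographic conventions:
#' `chain`, `resno` (author numbering; insertion codes are appended to the
#' number as text in the `insert` column), `resid` (3-letter residue name),
#' `elety` (atom name), `elesy` (element symbol), `x`/`y`/`z` (Angstrom),
#' `o` (occupancy) and `b` (B-factor, Angstrom^2).
#'
#' @param atoms data.frame with at least `chain`, `resno`, `resid`, `elety`,
#'   `elesy`, `x`, `y`, `z`; missing bookkeeping columns are filled with
#'   defaults (`type = "ATOM"`, `o = 1`, `b = 0`).
#' @param assembly_ops List of 4x4 operators already applied to the model.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, assembly_ops = list()) {
  stopifnot(is.data.frame(atoms))
  required <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(atoms)) stop("atom table is empty", call. = FALSE)
  if (is.null(atoms$type)) atoms$type <- "ATOM"
  if (is.null(atoms$eleno)) atoms$eleno <- seq_len(nrow(atoms))
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  atoms$insert[is.na(atoms$insert)] <- ""
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates", call. = FALSE)
  if (any(!is.finite(atoms$o)) || any(atoms$o < 0 | atoms$o > 1)) {
    stop("occupancies must lie in [0, 1]", call. = FALSE)
  }
  if (any(!nzchar(atoms$elesy) | is.na(atoms$elesy))) {
    stop("every atom needs an element symbol", call. = FALSE)
  }
  atoms <- atoms[, intersect(ATOM_COLUMNS, names(atoms))]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, assembly_ops = assembly_ops),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, %d chain(s): %s\n",
              nrow(x$atoms), length(model_chains(x)),
              paste(model_chains(x), collapse = " ")))
  if (length(x$assembly_ops)) {
    cat(sprintf("  assembly of %d operator(s)\n", length(x$assembly_ops)))
  }
  invisible(x)
}

#' Chains and coordinates of a structure model
#'
#' @param model A `structure_model`.
#' @return `model_chains()`: character vector of chain identifiers in order
#'   of first appearance.  `model_coords()`: n x 3 coordinate matrix (Angstrom).
#' @export
model_chains <- function(model) unique(model$atoms$chain)

#' @rdname model_chains
#' @export
model_coords <- function(model) {
  m <- as.matrix(model$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

# Resolve highest-occupancy alternate conformers (ties: alphabetical altloc).
resolve_altloc <- function(atom) {
  if (is.null(atom$alt) || all(is.na(atom$alt))) return(atom)
  key <- paste(atom$chain, atom$resno, atom$insert, atom$resid, atom$elety,
               sep = "|")
  alt <- ifelse(is.na(atom$alt), "", atom$alt)
  ord <- order(key, -atom$o, alt)
  keep <- !duplicated(key[ord])
  atom[sort(ord[keep]), , drop = FALSE]
}

#' Read a macromolecular structure
#'
#' Reads PDB or mmCIF coordinates into a [structure_model()].  All ATOM and
#' HETATM records are retained (metal ions and waters included); author
#' residue numbers are preserved; alternate locations are reduced to the
#' highest-occupancy conformer (ties broken alphabetically by altloc).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return A `structure_model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  if (format == "pdb") validate_pdb_lines(path)
  parsed <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
    } else {
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE,
                                       rm.alt = FALSE))
    },
    error = function(e) {
      stop(sprintf("could not parse %s as %s: %s", path, format,
                   conditionMessage(e)), call. = FALSE)
    })
  atom <- resolve_altloc(parsed$atom)
  atom$insert <- ifelse(is.na(atom$insert), "", atom$insert)
  atom$elesy <- ifelse(is.na(atom$elesy) | !nzchar(atom$elesy),
                       guess_element(atom$elety), atom$elesy)
  atom$o[is.na(atom$o)] <- 1
  atom$b[is.na(atom$b)] <- 0
  structure_model(atom[, intersect(ATOM_COLUMNS, names(atom))])
}

# Cheap structural validation of PDB coordinate records so that a corrupt
# file is reported with its offending line number.
validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in idx) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (any(is.na(xyz))) {
      stop(sprintf("unparseable coordinate record at line %d of %s", i, path),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

guess_element <- function(elety) {
  e <- gsub("[^A-Za-z]", "", elety)
  two <- toupper(substr(e, 1, 2))
  known2 <- c("CO", "NI", "ZN", "FE", "CU", "MG", "MN", "CA", "NA", "CL", "CD")
  ifelse(two %in% known2 & nchar(e) == 2, two, toupper(substr(e, 1, 1)))
}

#' Write a structure model to PDB or mmCIF
#'
#' mmCIF output preserves arbitrary chain identifiers (for example the
#' `"A-2"` suffixes produced by [build_assembly()]); PDB output requires
#' single-character chains and remaps longer identifiers to letters with a
#' warning.
#'
#' @param model A `structure_model`.
#' @param path Output file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  a <- model$atoms
  if (format == "pdb") {
    chains <- a$chain
    if (any(nchar(chains) > 1)) {
      map <- stats::setNames(LETTERS[seq_along(unique(chains))], unique(chains))
      if (length(unique(chains)) > 26) {
        stop("too many chains for PDB output; use mmCIF", call. = FALSE)
      }
      warning("multi-character chain ids remapped to single letters for PDB",
              call. = FALSE)
      chains <- unname(map[chains])
    }
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     type = a$type, resno = a$resno, resid = a$resid,
                     eleno = seq_len(nrow(a)), elety = a$elety,
                     chain = chains, insert = ifelse(nzchar(a$insert), a$insert, NA),
                     o = a$o, b = a$b, elesy = a$elesy)
  } else {
    write_mmcif(a, path)
  }
  invisible(path)
}

# Minimal mmCIF atom_site writer (coordinates category only).
write_mmcif <- function(a, path) {
  hdr <- c("data_model", "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
                    "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")))
  label_asym <- make.names(a$chain)  # label ids must be plain tokens
  rows <- sprintf(
    "%-6s %d %s %s . %s %s 1 %d %s %.4f %.4f %.4f %.2f %.2f %d %s %s %s 1",
    a$type, seq_len(nrow(a)), a$elesy, a$elety, a$resid, label_asym,
    a$resno, ifelse(nzchar(a$insert), a$insert, "?"),
    a$x, a$y, a$z, a$o, a$b, a$resno, a$resid, a$chain, a$elety)
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}

#' Expand an asymmetric unit into an assembly
#'
#' Applies a list of rigid-body operators to a model and concatenates the
#' copies, e.g. to build the crystallographic dimer-of-dimers tetramer from
#' a two-chain asymmetric unit with the identity plus a twofold.  The first
#' operator keeps the original chain identifiers; the n-th operator (n > 1)
#' appends `"-n"`, so a 2-chain unit under `[identity, twofold]` yields
#' chains `A`, `B`, `A-2`, `B-2`.
#'
#' @param model A `structure_model`.
#' @param ops List of 4x4 rigid transforms (see [rigid_transform()]).
#' @return A `structure_model` with `atom count = input x length(ops)`.
#' @export
build_assembly <- function(model, ops) {
  if (!length(ops)) stop("need at least one operator", call. = FALSE)
  lapply(ops, check_rigid_op)
  pieces <- lapply(seq_along(ops), function(i) {
    a <- model$atoms
    a[, c("x", "y", "z")] <- apply_transform(as.matrix(a[, c("x", "y", "z")]),
                                             ops[[i]])
    if (i > 1L) a$chain <- paste0(a$chain, "-", i)
    a
  })
  out <- do.call(rbind, pieces)
  out$eleno <- seq_len(nrow(out))
  structure_model(out, assembly_ops = ops)
}

#' Construct a 1-D SAXS profile
#'
#' @param q Momentum transfer grid, Angstrom^-1, strictly increasing.
#' @param intensity Scattered intensity, arbitrary units.
#' @param sigma Optional 1-sigma uncertainties (positive); when absent the
#'   profile carries unit weights and `unit_weights` is set.
#' @return An object of class `saxs_profile`.
#' @export
saxs_profile <- function(q, intensity, sigma = NULL) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  stopifnot(length(q) == length(intensity))
  if (any(!is.finite(q)) || any(!is.finite(intensity))) {
    stop("q and intensity must be finite", call. = FALSE)
  }
  if (is.unsorted(q, strictly = TRUE)) {
    stop("q must be strictly increasing", call. = FALSE)
  }
  unit_weights <- is.null(sigma)
  if (unit_weights) {
    sigma <- rep(1, length(q))
  } else {
    sigma <- as.numeric(sigma)
    stopifnot(length(sigma) == length(q))
    if (any(!is.finite(sigma)) || any(sigma <= 0)) {
      stop("sigma must be finite and positive", call. = FALSE)
    }
  }
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 unit_weights = unit_weights),
            class = "saxs_profile")
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("<saxs_profile> %d points, q in [%.4g, %.4g] A^-1%s\n",
              length(x$q), min(x$q), max(x$q),
              if (x$unit_weights) ", unit weights" else ""))
  invisible(x)
}

#' Read a 3-column SAXS profile
#'
#' Reads the conventional whitespace-separated `.dat` dialect: columns
#' q, I and (optionally) sigma; `#` lines and non-numeric headers are
#' skipped; rows with non-finite values or non-positive sigma are dropped
#' with a message; points are sorted by q.
#'
#' @param path File path.
#' @return A [saxs_profile()].
#' @export
read_saxs_profile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "[,[:space:]]+")
  # a data row has >= 2 numeric-like leading fields; NaN/Inf rows count as
  # data (and are then dropped as invalid, with a message)
  numeric_like <- function(x) {
    !is.na(suppressWarnings(as.numeric(x))) |
      tolower(x) %in% c("nan", "inf", "-inf", "na")
  }
  numeric_rows <- vapply(fields, function(f) {
    length(f) >= 2L && all(numeric_like(f[1:2]))
  }, logical(1))
  fields <- fields[numeric_rows]
  if (!length(fields)) stop("no numeric data rows in ", path, call. = FALSE)
  ncol_ <- min(vapply(fields, length, integer(1)), 3L)
  m <- do.call(rbind, lapply(fields, function(f) {
    suppressWarnings(as.numeric(f[seq_len(ncol_)]))
  }))
  has_sigma <- ncol_ >= 3L
  ok <- is.finite(m[, 1]) & is.finite(m[, 2])
  if (has_sigma) ok <- ok & is.finite(m[, 3]) & m[, 3] > 0
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    message(sprintf("read_saxs_profile: dropped %d invalid row(s) from %s",
                    n_bad, basename(path)))
  }
  m <- m[ok, , drop = FALSE]
  m <- m[order(m[, 1]), , drop = FALSE]
  dup <- duplicated(m[, 1])
  if (any(dup)) {
    warning(sprintf("dropped %d duplicate q value(s)", sum(dup)), call. = FALSE)
    m <- m[!dup, , drop = FALSE]
  }
  if (nrow(m) < 5L) {
    stop("unusable profile: fewer than 5 valid rows in ", path, call. = FALSE)
  }
  saxs_profile(m[, 1], m[, 2], if (has_sigma) m[, 3] else NULL)
}

#' Write a SAXS profile in .dat format
#'
#' @param profile A [saxs_profile()].
#' @param path Output path.
#' @param header Optional character vector written as `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_saxs_profile <- function(profile, path, header = NULL) {
  lines <- c(
    paste0("# ", c("q(A^-1) I(a.u.) sigma", header %||% character())),
    sprintf("%.6e %.6e %.6e", profile$q, profile$intensity, profile$sigma))
  writeLines(lines, path)
  invisible(path)
}
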