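# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the caller's
#' RNG state afterwards, so seeded generators never perturb user randomness.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Build a 4x4 rigid-body transform
#'
#' @param rotation 3x3 rotation matrix (proper: `det = +1`).
#' @param translation Length-3 translation vector in Angstrom.
#' @return A 4x4 homogeneous transform matrix.
#' @export
#' @examples
#' op <- rigid_transform(rotation_z(pi), c(0, 0, 5))
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3L, 3L)),
            length(translation) == 3L)
  op <- diag(4)
  op[1:3, 1:3] <- rotation
  op[1:3, 4] <- translation
  op
}

#' Elementary rotation matrices
#'
#' @param theta Angle in radians.
#' @return 3x3 rotation matrix about the named axis.
#' @export
rotation_z <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

#' @rdname rotation_z
#' @export
rotation_x <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
}

#' @rdname rotation_z
#' @export
rotation_y <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}

# Check that a 4x4 transform encodes a proper rigid motion.
check_rigid_op <- function(op, tol = 1e-6) {
  if (!is.matrix(op) || !all(dim(op) == c(4L, 4L))) {
    stop("assembly operators must be 4x4 matrices", call. = FALSE)
  }
  R <- op[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > tol) {
    stop("assembly operator rotation block is not orthonormal", call. = FALSE)
  }
  if (abs(det(R) - 1) > tol) {
    stop("assembly operator is an improper rotation (det != +1)", call. = FALSE)
  }
  invisible(TRUE)
}

# Apply a 4x4 transform to an n x 3 coordinate matrix.
apply_transform <- function(xyz, op) {
  xyz <- as.matrix(xyz)
  sweep(xyz %*% t(op[1:3, 1:3]), 2, op[1:3, 4], `+`)
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Random unit vector(s) from the current RNG stream.
random_unit_vectors <- function(n = 1L) {
  m <- matrix(stats::rnorm(3L * n), ncol = 3L)
  m / sqrt(rowSums(m^2))
}

# sin(x)/x with the removable singularity filled in (dims preserved).
sinc <- function(x) {
  out <- x
  nz <- x != 0
  out[nz] <- sin(x[nz]) / x[nz]
  out[!nz] <- 1
  out
}

#' Average molecular mass of a protein sequence
#'
#' Computes the average (isotope-abundance weighted) molecular mass of an
#' unmodified polypeptide from its one-letter sequence, including one water
#' for the termini.
#'
#' @param sequence One-letter amino-acid string (case insensitive).
#' @return Mass in kilodalton.
#' @export
#' @examples
#' protein_mw("ETGHHHHHHWSHPQ")
protein_mw <- function(sequence) {
  residue_masses <- c(
    A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
  )
  aa <- strsplit(toupper(gsub("\\s", "", sequence)), "")[[1]]
  unknown <- setdiff(unique(aa), names(residue_masses))
  if (length(unknown)) {
    stop("unknown residue code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  (sum(residue_masses[aa]) + 18.01528) / 1000
}
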