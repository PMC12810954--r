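# Internal helpers: RNG scoping, vector geometry, amino-acid tables.

# Run `code` under set.seed(seed) without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180

# Natural extension of reference frame (NeRF): place atom D given positions of
# A, B, C, the C-D bond length, the B-C-D angle (degrees) and the A-B-C-D
# dihedral (degrees).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  theta <- deg2rad(angle)
  chi <- deg2rad(dihedral)
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  d2 <- c(-bond * cos(theta), bond * sin(theta) * cos(chi), bond * sin(theta) * sin(chi))
  as.numeric(c + m %*% d2)
}

# Signed dihedral A-B-C-D in degrees.
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Amino-acid code tables (20 standard residues; anything else maps to "X").
AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
AA_123 <- stats::setNames(names(AA_321), unname(AA_321))

# Residues whose side chains are predominantly apolar; used by the burial term
# of the fixed-backbone stand-in.
AA_HYDROPHOBIC <- c("A", "C", "F", "I", "L", "M", "V", "W", "Y")

aa_three_to_one <- function(resname) {
  out <- unname(AA_321[toupper(resname)])
  out[is.na(out)] <- "X"
  out
}

aa_one_to_three <- function(code) {
  out <- unname(AA_123[toupper(code)])
  if (anyNA(out)) {
    stop("unknown amino-acid code: ", paste(unique(code[is.na(out)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

is_standard_aa1 <- function(code) toupper(code) %in% names(AA_123)

`%||%` <- function(x, y) if (is.null(x)) y else x
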