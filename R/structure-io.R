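#' Read a PDB-format structure into an atom tibble
#'
#' Parses ATOM records (via bio3d) into the tidy atom table used throughout
#' the package: one row per heavy atom with columns `chain`, `resno`, `ins`,
#' `resname`, `atom`, `x`, `y`, `z`. HETATM records, waters and hydrogens are
#' dropped; for alternate locations the first-encountered altloc is kept (with
#' a warning). Author residue numbering is preserved verbatim.
#'
#' @param input Path to a PDB file, or a character vector of PDB-format lines
#'   (a single string containing newlines is also accepted).
#' @return A tibble of atoms, ordered by chain then (`resno`, `ins`).
#' @examples
#' pdb <- c(
#'   "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00",
#'   "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00",
#'   "END"
#' )
#' read_structure(pdb)
#' @export
read_structure <- function(input) {
  lines <- if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    readLines(input, warn = FALSE)
  } else {
    unlist(strsplit(input, "\n", fixed = TRUE))
  }
  atom_lines <- grep("^ATOM  ", lines)
  if (length(atom_lines) == 0L) stop("no atoms parsed", call. = FALSE)

  # Validate coordinate fields before handing off to the parser so the error
  # can name the offending line.
  for (i in atom_lines) {
    coords <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46), substr(lines[i], 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords)))) {
      stop("non-numeric coordinate field on line ", i, ": ", trimws(lines[i]), call. = FALSE)
    }
  }

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom

  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  elem <- ifelse(is.na(at$elesy) | at$elesy == "", gsub("[^A-Za-z].*$", "", trimws(at$elety)), trimws(at$elesy))
  at <- at[!(toupper(substr(elem, 1, 1)) %in% c("H", "D") & toupper(elem) %in% c("H", "D")), , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms parsed", call. = FALSE)

  s <- tibble::tibble(
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = as.integer(at$resno),
    ins = ifelse(is.na(at$insert) | at$insert == "", "", at$insert),
    resname = at$resid,
    atom = trimws(at$elety),
    x = at$x, y = at$y, z = at$z
  )

  # Altloc policy: keep the first-encountered altloc per atom.
  key <- paste(s$chain, s$resno, s$ins, s$atom, sep = "\r")
  if (anyDuplicated(key)) {
    warning("alternate locations found; keeping first-encountered altloc", call. = FALSE)
    s <- s[!duplicated(key), , drop = FALSE]
  }

  # Residue-identity invariant: one residue name per (chain, resno, ins).
  rid <- paste(s$chain, s$resno, s$ins, sep = "\r")
  nnames <- tapply(s$resname, rid, function(x) length(unique(x)))
  if (any(nnames > 1L)) {
    stop("duplicated residue identity with conflicting names: ",
         names(nnames)[which(nnames > 1L)[1]], call. = FALSE)
  }
  if (!all(is.finite(c(s$x, s$y, s$z)))) stop("non-finite coordinates in input", call. = FALSE)

  dplyr::arrange(s, .data$chain, .data$resno, .data$ins)
}

#' Write an atom tibble as PDB-format text
#'
#' Emits fixed-column ATOM records with coordinates rounded to 3 decimals, a
#' TER record per chain and a final END.
#'
#' @param s Atom tibble (as returned by [read_structure()]).
#' @param file Optional output path; when `NULL` the PDB lines are returned as
#'   a character vector.
#' @return Invisibly the lines written (or the lines themselves if
#'   `file = NULL`).
#' @export
write_structure <- function(s, file = NULL) {
  stopifnot(is.data.frame(s))
  if (nrow(s) == 0L) stop("cannot write an empty structure", call. = FALSE)
  if (any(nchar(s$atom) > 4L)) {
    stop("atom name longer than 4 characters: ", s$atom[which(nchar(s$atom) > 4L)[1]],
         call. = FALSE)
  }
  tmp <- file %||% tempfile(fileext = ".pdb")
  bio3d::write.pdb(
    file = tmp,
    xyz = as.numeric(t(as.matrix(s[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(s)),
    resno = s$resno,
    resid = s$resname,
    eleno = seq_len(nrow(s)),
    elety = s$atom,
    chain = s$chain,
    insert = ifelse(s$ins == "", NA, s$ins),
    chainter = TRUE
  )
  if (is.null(file)) {
    lines <- readLines(tmp, warn = FALSE)
    unlink(tmp)
    lines
  } else {
    invisible(readLines(tmp, warn = FALSE))
  }
}

#' Extract the one-letter sequence of a chain
#'
#' Residues are taken in (`resno`, `ins`) order; non-standard residue names
#' (e.g. MSE) map to `"X"`.
#'
#' @param s Atom tibble.
#' @param chain Chain identifier (default: the first chain present).
#' @return A single string, one letter per residue.
#' @export
extract_sequence <- function(s, chain = NULL) {
  chain <- chain %||% s$chain[1]
  res <- chain_residues(s, chain)
  paste(aa_three_to_one(res$resname), collapse = "")
}

# Residue-level view of one chain: tibble(resno, ins, resname) in order.
chain_residues <- function(s, chain) {
  cs <- s[s$chain == chain, , drop = FALSE]
  if (nrow(cs) == 0L) stop("unknown chain id: ", chain, call. = FALSE)
  dplyr::arrange(dplyr::distinct(cs, .data$resno, .data$ins, .data$resname),
                 .data$resno, .data$ins)
}

# Coordinates of one named atom for a (chain, resno) pair, or NULL if absent.
atom_xyz <- function(s, chain, resno, atom) {
  row <- s[s$chain == chain & s$resno == resno & s$atom == atom, , drop = FALSE]
  if (nrow(row) == 0L) return(NULL)
  as.numeric(row[1, c("x", "y", "z")])
}
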