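# Stabilization edits: disulfide-staple scanning, explicit mutation transfer,
# a steric/burial stand-in for fixed-backbone residue choice, and the
# N-terminal truncation control.

# Cbeta coordinates for one design position: the real CB atom when present,
# otherwise an ideal tetrahedral reconstruction from backbone N/CA/C.
cbeta_xyz <- function(s, resno) {
  cb <- atom_xyz(s, "A", resno, "CB")
  if (!is.null(cb)) return(cb)
  n <- atom_xyz(s, "A", resno, "N")
  ca <- atom_xyz(s, "A", resno, "CA")
  cc <- atom_xyz(s, "A", resno, "C")
  if (is.null(n) || is.null(ca) || is.null(cc)) {
    stop("cannot reconstruct CB at position ", resno, ": incomplete backbone",
         call. = FALSE)
  }
  b <- ca - n
  c_ <- cc - ca
  a <- cross3(b, c_)
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * c_ + ca
}

#' Scan for disulfide-staple candidate pairs between two regions
#'
#' Enumerates every cross-region position pair whose Cbeta-Cbeta distance
#' falls inside `cb_window` (ideal disulfide Cbeta separation is about
#' 4.0 Angstrom). Glycine (or any residue without a CB atom) is scanned via an
#' ideal tetrahedral Cbeta rebuilt from the backbone.
#'
#' @param m A `design_model`.
#' @param region_a,region_b Inclusive design-position ranges `c(start, end)`;
#'   must be disjoint.
#' @param cb_window Allowed Cbeta-Cbeta distance window (Angstrom).
#' @return Tibble (`pos_i`, `pos_j`, `cb_distance`, `geometry_score`) sorted
#'   by ascending `geometry_score` = |distance - 4.0|.
#' @export
scan_disulfide_sites <- function(m, region_a, region_b, cb_window = c(3.0, 5.0)) {
  a <- seq.int(region_a[1], region_a[2])
  b <- seq.int(region_b[1], region_b[2])
  if (length(intersect(a, b)) > 0L) stop("regions overlap", call. = FALSE)
  s <- m$structure
  cb_a <- lapply(a, function(p) cbeta_xyz(s, p))
  cb_b <- lapply(b, function(p) cbeta_xyz(s, p))
  rows <- list()
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      d <- vnorm(cb_a[[i]] - cb_b[[j]])
      if (d >= cb_window[1] && d <= cb_window[2]) {
        pi_ <- min(a[i], b[j]); pj <- max(a[i], b[j])
        rows[[length(rows) + 1L]] <- tibble::tibble(
          pos_i = pi_, pos_j = pj, cb_distance = d, geometry_score = abs(d - 4.0)
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(pos_i = integer(), pos_j = integer(),
                          cb_distance = numeric(), geometry_score = numeric()))
  }
  dplyr::arrange(out, .data$geometry_score, .data$pos_i, .data$pos_j)
}

#' Parse a compact mutation list
#'
#' Accepts notation like `"G4C,L96C"` (case-insensitive, whitespace ignored).
#'
#' @param text Mutation string.
#' @return Tibble (`position`, `wt_aa`, `mut_aa`).
#' @export
parse_mutations <- function(text) {
  parts <- trimws(unlist(strsplit(toupper(text), ",", fixed = TRUE)))
  parts <- parts[nzchar(parts)]
  m <- regmatches(parts, regexec("^([A-Z])([0-9]+)([A-Z])$", parts))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("cannot parse mutation: ", parts[bad][1], call. = FALSE)
  tibble::tibble(
    position = as.integer(vapply(m, `[`, character(1), 3L)),
    wt_aa = vapply(m, `[`, character(1), 2L),
    mut_aa = vapply(m, `[`, character(1), 4L)
  )
}

#' Apply point mutations to a design model
#'
#' Updates the sequence and residue names; backbone coordinates are never
#' touched. Side-chain atoms beyond Cbeta are dropped for mutated residues
#' (and Cbeta too when mutating to glycine).
#'
#' @param m A `design_model`.
#' @param muts Tibble (`position`, `wt_aa`, `mut_aa`) or a compact string
#'   accepted by [parse_mutations()].
#' @return The mutated `design_model`.
#' @export
apply_mutations <- function(m, muts) {
  if (is.character(muts)) muts <- parse_mutations(muts)
  if (nrow(muts) == 0L) return(m)
  seq_chars <- strsplit(m$sequence, "")[[1]]
  for (k in seq_len(nrow(muts))) {
    p <- muts$position[k]
    if (p < 1L || p > length(seq_chars)) {
      stop("mutation position ", p, " outside sequence (length ",
           length(seq_chars), ")", call. = FALSE)
    }
    if (muts$wt_aa[k] == muts$mut_aa[k]) {
      stop("mutation at position ", p, " does not change the residue", call. = FALSE)
    }
    if (seq_chars[p] != muts$wt_aa[k]) {
      stop("wild-type mismatch at position ", p, ": expected ", muts$wt_aa[k],
           ", found ", seq_chars[p], call. = FALSE)
    }
    seq_chars[p] <- muts$mut_aa[k]
    keep <- c("N", "CA", "C", "O", if (muts$mut_aa[k] != "G") "CB")
    at_res <- m$structure$resno == p
    m$structure <- m$structure[!at_res | m$structure$atom %in% keep, , drop = FALSE]
    m$structure$resname[m$structure$resno == p] <- aa_one_to_three(muts$mut_aa[k])
  }
  m$sequence <- paste(seq_chars, collapse = "")
  m
}

# Pseudo side-chain sphere radius (Angstrom) by residue class; a coarse
# stand-in for rotamer sterics.
PSEUDO_RADIUS <- c(
  G = 0, A = 1.0, S = 1.0, C = 1.1, T = 1.2, P = 1.3, V = 1.4, N = 1.4,
  D = 1.4, I = 1.6, L = 1.6, M = 1.7, E = 1.6, Q = 1.6, H = 1.7, K = 1.9,
  F = 1.9, R = 2.1, Y = 2.0, W = 2.2
)

#' Choose a residue at one position with a steric/burial stand-in energy
#'
#' Scores each candidate as `clash + burial_mismatch + helix_penalty`:
#' overlap of an idealized side-chain sphere centred on Cbeta with surrounding
#' heavy atoms; a unit penalty for a hydrophobic residue at an exposed site or
#' a polar residue at a buried site (burial proxy: Calpha neighbour count
#' within `burial_radius`); and a fixed penalty for proline anywhere in a
#' helix except its first two positions. Deterministic; ties break
#' alphabetically. This stand-in makes no claim of reproducing any external
#' design software's choices.
#'
#' @param m A `design_model`.
#' @param position Design position.
#' @param candidates Character vector of 1-letter codes.
#' @param burial_radius Calpha neighbour radius (Angstrom).
#' @param burial_threshold Neighbour count at or above which a site counts as
#'   buried.
#' @param proline_penalty Score increment for mid-helix proline.
#' @return A `mutation_decision`: list with `position`, `scores` tibble
#'   (`candidate`, `clash`, `burial`, `helix`, `score`) and `chosen`.
#' @export
choose_residue <- function(m, position, candidates, burial_radius = 10,
                           burial_threshold = 14L, proline_penalty = 10) {
  stopifnot(length(candidates) >= 1L)
  candidates <- toupper(candidates)
  if (!all(is_standard_aa1(candidates))) {
    stop("unknown amino-acid code: ",
         paste(candidates[!is_standard_aa1(candidates)], collapse = ", "), call. = FALSE)
  }
  s <- m$structure
  ca_here <- atom_xyz(s, "A", position, "CA")
  if (is.null(ca_here)) stop("no CA at position ", position, call. = FALSE)
  cb_here <- cbeta_xyz(s, position)

  # burial proxy: Calpha neighbours within burial_radius, excluding |i-j| <= 2
  ca_all <- s[s$atom == "CA" & abs(s$resno - position) > 2L, , drop = FALSE]
  dca <- sqrt(rowSums(sweep(as.matrix(ca_all[, c("x", "y", "z")]), 2, ca_here)^2))
  buried <- sum(dca <= burial_radius) >= burial_threshold

  # helix membership and offset from helix start (design numbering)
  prov <- m$provenance
  hid <- prov$helix_id[match(position, prov$design_pos)]
  in_helix_body <- FALSE
  if (!is.na(hid)) {
    helix_pos <- prov$design_pos[!is.na(prov$helix_id) & prov$helix_id == hid]
    in_helix_body <- (position - min(helix_pos) + 1L) > 2L
  }

  other <- s[abs(s$resno - position) >= 2L, , drop = FALSE]
  d_other <- sqrt(rowSums(sweep(as.matrix(other[, c("x", "y", "z")]), 2, cb_here)^2))

  score_one <- function(aa) {
    r <- PSEUDO_RADIUS[[aa]]
    clash <- sum(pmax(0, (r + 1.7) - d_other))
    burial <- as.numeric((aa %in% AA_HYDROPHOBIC) != buried)
    helix <- if (aa == "P" && in_helix_body) proline_penalty else 0
    c(clash = clash, burial = burial, helix = helix)
  }
  parts <- t(vapply(candidates, score_one, numeric(3)))
  scores <- tibble::tibble(
    candidate = candidates,
    clash = unname(parts[, "clash"]), burial = unname(parts[, "burial"]),
    helix = unname(parts[, "helix"]), score = unname(rowSums(parts))
  )
  scores <- dplyr::arrange(scores, .data$score, .data$candidate)
  structure(list(position = position, scores = scores, chosen = scores$candidate[1],
                 buried = buried), class = "mutation_decision")
}

#' @export
print.mutation_decision <- function(x, ...) {
  cat("<mutation_decision> position ", x$position, ": chose ", x$chosen,
      if (x$buried) " (buried site)\n" else " (exposed site)\n", sep = "")
  print(x$scores)
  invisible(x)
}

#' @method tidy mutation_decision
#' @export
tidy.mutation_decision <- function(x, ...) x$scores

#' Delete the first n residues (N-terminal truncation control)
#'
#' @param m A `design_model` or a 1-letter sequence string.
#' @param n Number of N-terminal residues to remove (`0 <= n < length`).
#' @return The truncated counterpart; design numbering re-based to 1.
#' @export
truncate_n_terminus <- function(m, n) {
  if (is.character(m)) {
    if (n >= nchar(m)) stop("cannot truncate ", n, " of ", nchar(m), " residues", call. = FALSE)
    return(substr(m, n + 1L, nchar(m)))
  }
  stopifnot(inherits(m, "design_model"))
  len <- nchar(m$sequence)
  if (n >= len) stop("cannot truncate ", n, " of ", len, " residues", call. = FALSE)
  if (n == 0L) return(m)
  keep <- m$structure$resno > n
  m$structure <- m$structure[keep, , drop = FALSE]
  m$structure$resno <- m$structure$resno - as.integer(n)
  m$sequence <- substr(m$sequence, n + 1L, len)
  m$provenance <- m$provenance[m$provenance$design_pos > n, , drop = FALSE]
  m$provenance$design_pos <- m$provenance$design_pos - as.integer(n)
  m
}

#' Count disulfide bridges in a design model
#'
#' A disulfide is a cysteine pair, at least 3 residues apart, whose
#' Cbeta-Cbeta distance (reconstructed where needed) lies in `cb_window`.
#'
#' @param m A `design_model`.
#' @param cb_window Cbeta-Cbeta distance window (Angstrom).
#' @return Integer count.
#' @export
count_disulfides <- function(m, cb_window = c(3.0, 5.0)) {
  cys <- which(strsplit(m$sequence, "")[[1]] == "C")
  if (length(cys) < 2L) return(0L)
  n <- 0L
  for (i in seq_along(cys)) {
    for (j in seq_along(cys)) {
      if (j <= i) next
      if (cys[j] - cys[i] < 3L) next
      d <- vnorm(cbeta_xyz(m$structure, cys[i]) - cbeta_xyz(m$structure, cys[j]))
      if (d >= cb_window[1] && d <= cb_window[2]) n <- n + 1L
    }
  }
  n
}
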