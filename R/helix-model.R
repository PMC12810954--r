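#' Extract helix segments from declared residue ranges
#'
#' Builds one helix record per `(start, end)` range (inclusive on both ends,
#' author numbering). Each record carries the segment sequence, the Calpha
#' anchors of its first and last residues, and a unit axis computed as the
#' principal direction of the segment's Calpha coordinates, oriented
#' N-terminus to C-terminus.
#'
#' @param s Atom tibble (see [read_structure()]).
#' @param chain Chain identifier holding the helices.
#' @param ranges List of two-element integer vectors `c(start, end)`.
#' @return A tibble with one row per helix (`helix_id` = H1..Hn in input
#'   order) and list-columns `n_anchor`, `c_anchor`, `axis`.
#' @export
extract_helices <- function(s, chain, ranges) {
  stopifnot(length(ranges) >= 1L)
  res <- chain_residues(s, chain)
  out <- purrr::imap(ranges, function(rg, i) {
    start <- rg[[1]]; end <- rg[[2]]
    if (start > end) stop("invalid helix range: start ", start, " > end ", end, call. = FALSE)
    want <- seq.int(start, end)
    ca <- matrix(NA_real_, length(want), 3)
    for (k in seq_along(want)) {
      xyz <- atom_xyz(s, chain, want[k], "CA")
      if (is.null(xyz)) {
        stop("incomplete helix: residue ", want[k], " of chain ", chain,
             " is missing or has no CA atom", call. = FALSE)
      }
      ca[k, ] <- xyz
    }
    seq1 <- paste(aa_three_to_one(res$resname[match(want, res$resno)]), collapse = "")
    axis <- if (nrow(ca) >= 2L) {
      helix_axis(ca)
    } else {
      nxt <- atom_xyz(s, chain, start + 1L, "CA")
      if (is.null(nxt)) stop("axis undefined for single-residue helix at ", start, call. = FALSE)
      unitv(nxt - ca[1, ])
    }
    tibble::tibble(
      helix_id = paste0("H", i), chain = chain,
      start_res = as.integer(start), end_res = as.integer(end),
      length = length(want), sequence = seq1,
      n_anchor = list(ca[1, ]), c_anchor = list(ca[nrow(ca), ]), axis = list(axis)
    )
  })
  dplyr::bind_rows(out)
}

# Unit principal direction of a Calpha trace, sign fixed to point N -> C.
helix_axis <- function(ca) {
  cen <- colMeans(ca)
  sv <- svd(sweep(ca, 2, cen))
  ax <- sv$v[, 1]
  if (sum(ax * (ca[nrow(ca), ] - ca[1, ])) < 0) ax <- -ax
  unitv(ax)
}

#' Assign helical ranges automatically from Calpha geometry
#'
#' Flags maximal runs of at least `min_run` consecutively numbered residues
#' whose Calpha(i) to Calpha(i+3) distance falls in `d13_window` (about
#' 5.0-5.5 Angstrom in an ideal alpha helix; an extended chain gives roughly
#' 10 Angstrom).
#'
#' @param s Atom tibble.
#' @param chain Chain identifier.
#' @param d13_window Allowed Calpha(i)-Calpha(i+3) distance window (Angstrom).
#' @param min_run Minimum run length in residues.
#' @return List of `c(start, end)` ranges (possibly empty).
#' @export
assign_helices_auto <- function(s, chain, d13_window = c(4.5, 6.0), min_run = 5L) {
  res <- chain_residues(s, chain)
  if (nrow(res) < min_run) return(list())
  ca <- lapply(res$resno, function(r) atom_xyz(s, chain, r, "CA"))
  ok <- !vapply(ca, is.null, logical(1))
  res <- res[ok, , drop = FALSE]
  ca <- ca[ok]
  n <- nrow(res)
  if (n < min_run) return(list())
  # helical[i]: quadruplet starting at i is consecutive in numbering and has
  # an i->i+3 distance inside the window
  helical <- logical(n)
  for (i in seq_len(n - 3L)) {
    if (res$resno[i + 3L] - res$resno[i] != 3L) next
    d <- vnorm(ca[[i + 3L]] - ca[[i]])
    helical[i] <- d >= d13_window[1] && d <= d13_window[2]
  }
  ranges <- list()
  i <- 1L
  while (i <= n - 3L) {
    if (!helical[i]) { i <- i + 1L; next }
    j <- i
    while (j + 1L <= n - 3L && helical[j + 1L] && res$resno[j + 1L] - res$resno[j] == 1L) j <- j + 1L
    end_idx <- j + 3L
    if (end_idx - i + 1L >= min_run) {
      ranges[[length(ranges) + 1L]] <- c(res$resno[i], res$resno[end_idx])
    }
    i <- end_idx + 1L
  }
  ranges
}

#' Inter-helix loop lengths from residue numbering
#'
#' For helices sorted by `start_res` on one chain, element `i` is
#' `start_res(i+1) - end_res(i) - 1`: the number of residues between
#' consecutive helices. Depends on numbering only, so it is invariant under
#' any rigid-body motion.
#'
#' @param helices Helix tibble (see [extract_helices()]), sorted by
#'   `start_res`.
#' @return Integer vector of length `nrow(helices) - 1`.
#' @export
loop_lengths <- function(helices) {
  stopifnot(nrow(helices) >= 2L)
  h <- dplyr::arrange(helices, .data$start_res)
  gaps <- h$start_res[-1] - h$end_res[-nrow(h)] - 1L
  if (any(gaps < 0L)) stop("overlapping helices", call. = FALSE)
  as.integer(gaps)
}

#' Classify helices as receptor-binding or structural
#'
#' A contact is a heavy-atom pair (one atom in the helix residues of the
#' cytokine chain, one in a receptor chain) at distance `contact_cutoff` or
#' less. A helix is `receptor_binding` when its contact count with any single
#' receptor chain reaches `min_contacts`.
#'
#' @param s Atom tibble containing cytokine and receptor chains.
#' @param helices Helix tibble on `cytokine_chain`.
#' @param cytokine_chain,receptor_chains Chain identifiers.
#' @param contact_cutoff Heavy-atom distance cutoff in Angstrom.
#' @param min_contacts Minimum contacts with one receptor chain.
#' @return Tibble: `helix_id`, one `contacts_<chain>` column per receptor
#'   chain, `role`.
#' @export
assign_roles <- function(s, helices, cytokine_chain, receptor_chains = character(),
                         contact_cutoff = 4.5, min_contacts = 5L) {
  for (rc in receptor_chains) {
    if (!rc %in% s$chain) stop("unknown chain id: ", rc, call. = FALSE)
  }
  counts <- matrix(0L, nrow(helices), max(1L, length(receptor_chains)))
  for (hi in seq_len(nrow(helices))) {
    hx <- s[s$chain == cytokine_chain &
              s$resno >= helices$start_res[hi] & s$resno <= helices$end_res[hi], , drop = FALSE]
    hm <- as.matrix(hx[, c("x", "y", "z")])
    for (ri in seq_along(receptor_chains)) {
      rm_ <- as.matrix(s[s$chain == receptor_chains[ri], c("x", "y", "z")])
      counts[hi, ri] <- count_close_pairs(hm, rm_, contact_cutoff)
    }
  }
  out <- tibble::tibble(helix_id = helices$helix_id)
  for (ri in seq_along(receptor_chains)) {
    out[[paste0("contacts_", receptor_chains[ri])]] <- counts[, ri]
  }
  binding <- if (length(receptor_chains)) {
    apply(counts[, seq_along(receptor_chains), drop = FALSE] >= min_contacts, 1, any)
  } else {
    rep(FALSE, nrow(helices))
  }
  out$role <- ifelse(binding, "receptor_binding", "structural")
  out
}

# Number of pairs (one row of a, one row of b) at distance <= cutoff.
count_close_pairs <- function(a, b, cutoff) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0L)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sum(d2 <= cutoff^2 + 1e-12)
}
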