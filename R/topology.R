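#' Distance a connector has to bridge
#'
#' Euclidean distance between the C-terminal Calpha anchor of the preceding
#' helix and the N-terminal Calpha anchor of the following helix.
#'
#' @param from,to Single-row helix records (or rows of a helix tibble).
#' @return Distance in Angstrom.
#' @export
connector_gap <- function(from, to) {
  vnorm(to$n_anchor[[1]] - from$c_anchor[[1]])
}

#' Geometric lower bound on connector length
#'
#' A loop of n residues can bridge at most about `n * span_per_residue`
#' (3.8 Angstrom is the Calpha-Calpha step of a fully extended chain);
#' `slack_residues` extra residues keep the connector closable with realistic,
#' non-extended geometry.
#'
#' @param gap Anchor-to-anchor distance in Angstrom.
#' @param span_per_residue Maximum span per residue (Angstrom).
#' @param slack_residues Extra residues beyond the extended-chain bound.
#' @return Integer connector length, `max(1, ceiling(gap / span)) + slack`.
#' @export
min_connector_length <- function(gap, span_per_residue = 3.8, slack_residues = 1L) {
  if (any(gap < 0)) stop("gap must be nonnegative", call. = FALSE)
  as.integer(pmax(1L, ceiling(gap / span_per_residue)) + slack_residues)
}

#' Enumerate candidate helix orders
#'
#' All permutations of the helix identifiers, optionally with a fixed
#' N-terminal helix. Helix internal N-to-C direction is never flipped: the
#' segments are native sequence and cannot be reversed.
#'
#' @param helices Helix tibble.
#' @param fix_first Optional helix_id pinned to the N-terminal position.
#' @return List of character vectors (helix-id orders).
#' @export
enumerate_topologies <- function(helices, fix_first = NULL) {
  ids <- helices$helix_id
  n <- length(ids)
  stopifnot(n >= 2L, n <= 8L)
  if (!is.null(fix_first) && !fix_first %in% ids) {
    stop("fix_first helix not found: ", fix_first, call. = FALSE)
  }
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  if (is.null(fix_first)) {
    perms(ids)
  } else {
    lapply(perms(setdiff(ids, fix_first)), function(p) c(fix_first, p))
  }
}

#' Design the connector-economy blueprint
#'
#' Scores every enumerated helix order by its economy: the total number of
#' new connector residues, each connector sized by [min_connector_length()]
#' on its anchor gap. Returns the order attaining minimal economy (ties broken
#' by lexicographic order of the helix-id sequence) as a `blueprint` object.
#' Template helix ranges are preserved unchanged.
#'
#' @param helices Helix tibble.
#' @param roles Optional role tibble from [assign_roles()] (recorded in the
#'   blueprint; not used in scoring).
#' @param fix_first Optional helix_id pinned to the N-terminus.
#' @inheritParams min_connector_length
#' @return A `blueprint`: list with `order`, `connectors` (tibble of
#'   from/to/gap/min_length/designed_length), `economy`, `preserved_ranges`,
#'   and (after [renumber_design()]) a `numbering` tibble.
#' @export
design_blueprint <- function(helices, roles = NULL, fix_first = NULL,
                             span_per_residue = 3.8, slack_residues = 1L) {
  stopifnot(nrow(helices) >= 2L)
  orders <- enumerate_topologies(helices, fix_first)
  score_order <- function(ord) {
    idx <- match(ord, helices$helix_id)
    gaps <- vapply(seq_len(length(ord) - 1L), function(i) {
      connector_gap(helices[idx[i], ], helices[idx[i + 1L], ])
    }, numeric(1))
    lens <- min_connector_length(gaps, span_per_residue, slack_residues)
    list(gaps = gaps, lens = lens, economy = sum(lens))
  }
  scored <- lapply(orders, score_order)
  economies <- vapply(scored, `[[`, numeric(1), "economy")
  keys <- vapply(orders, paste, character(1), collapse = ">")
  best <- order(economies, keys)[1]
  ord <- orders[[best]]
  sc <- scored[[best]]

  bp <- structure(list(
    order = ord,
    connectors = tibble::tibble(
      from_helix = ord[-length(ord)], to_helix = ord[-1],
      gap = sc$gaps, min_length = sc$lens, designed_length = sc$lens
    ),
    economy = sum(sc$lens),
    preserved_ranges = helices[match(ord, helices$helix_id),
                               c("helix_id", "chain", "start_res", "end_res", "length", "sequence")],
    roles = roles,
    span_per_residue = span_per_residue,
    slack_residues = slack_residues,
    numbering = NULL
  ), class = "blueprint")
  renumber_design(bp)
}

#' Assign contiguous design numbering to a blueprint
#'
#' Design positions 1..L run through the helices in blueprint order with the
#' designed connectors in between; helix positions map back to template
#' residues, connector positions are marked `"new"`.
#'
#' @param bp A `blueprint`.
#' @return The blueprint with its `numbering` tibble filled in
#'   (`design_pos`, `source`, `helix_id`, `template_chain`, `template_resno`).
#' @export
renumber_design <- function(bp) {
  stopifnot(inherits(bp, "blueprint"))
  rows <- list()
  pos <- 0L
  for (i in seq_along(bp$order)) {
    h <- bp$preserved_ranges[bp$preserved_ranges$helix_id == bp$order[i], ]
    tres <- seq.int(h$start_res, h$end_res)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      design_pos = pos + seq_along(tres), source = "template",
      helix_id = h$helix_id, template_chain = h$chain, template_resno = as.integer(tres)
    )
    pos <- pos + length(tres)
    if (i < length(bp$order)) {
      L <- bp$connectors$designed_length[i]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        design_pos = pos + seq_len(L), source = "new",
        helix_id = NA_character_, template_chain = NA_character_, template_resno = NA_integer_
      )
      pos <- pos + L
    }
  }
  bp$numbering <- dplyr::bind_rows(rows)
  stopifnot(identical(bp$numbering$design_pos, seq_len(pos)))
  bp
}

#' @export
print.blueprint <- function(x, ...) {
  cat("<blueprint> order:", paste(x$order, collapse = " > "),
      " economy:", x$economy, "residues\n")
  print(x$connectors)
  invisible(x)
}

#' @method tidy blueprint
#' @export
tidy.blueprint <- function(x, ...) x$connectors

#' @method glance blueprint
#' @export
glance.blueprint <- function(x, ...) {
  tibble::tibble(
    n_helices = length(x$order),
    order = paste(x$order, collapse = ">"),
    economy = x$economy,
    total_length = nrow(x$numbering)
  )
}
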