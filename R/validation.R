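#' Kabsch superposition of two point sets
#'
#' Least-squares proper rotation + translation mapping `moving` onto `fixed`;
#' reflections are excluded by the determinant sign correction, so chirality
#' is preserved.
#'
#' @param moving,fixed Numeric n x 3 matrices (n >= 3) in correspondence.
#' @return A `superposition`: list with `rotation` (3x3, det +1),
#'   `translation`, `rmsd` (Angstrom), and `transformed` (moving after the
#'   fit). The transform maps a moving point p to `rotation %*% p +
#'   translation`.
#' @export
kabsch_superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed)) stop("point sets differ in length", call. = FALSE)
  if (nrow(moving) < 3L) stop("need at least 3 points", call. = FALSE)
  cm <- colMeans(moving); cf <- colMeans(fixed)
  p <- sweep(moving, 2, cm)
  q <- sweep(fixed, 2, cf)
  sv <- svd(crossprod(p, q))          # H = P^T Q
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  transformed <- sweep(tcrossprod(p, rot), 2, cf, "+")
  rmsd <- sqrt(mean(rowSums((transformed - fixed)^2)))
  structure(list(
    rotation = rot,
    translation = as.numeric(cf - rot %*% cm),
    rmsd = rmsd,
    transformed = transformed
  ), class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> rmsd ", format(round(x$rmsd, 4), nsmall = 4), " A\n", sep = "")
  invisible(x)
}

#' Superposition-based design acceptance
#'
#' Pools the Calpha atoms of every helix position of the design (via its
#' provenance map), superposes them onto the corresponding template helix
#' Calpha atoms with a single Kabsch fit, and accepts when the pooled RMSD is
#' strictly below `threshold` (default 1.0 Angstrom). Per-helix RMSDs are
#' reported in the same pooled frame (no per-segment re-fit).
#'
#' @param m A `design_model`.
#' @param s_template Template atom tibble the helices came from.
#' @param threshold Acceptance RMSD in Angstrom (strict `<`).
#' @return A `design_validation`: list with `rmsd`, `per_segment_rmsd`
#'   (tibble), `accepted`, `threshold` and the underlying `superposition`.
#' @export
accept_design <- function(m, s_template, threshold = 1.0) {
  prov <- m$provenance[m$provenance$source == "template", , drop = FALSE]
  n <- nrow(prov)
  mov <- matrix(NA_real_, n, 3)
  fix <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    a <- atom_xyz(m$structure, "A", prov$design_pos[k], "CA")
    b <- atom_xyz(s_template, prov$template_chain[k], prov$template_resno[k], "CA")
    if (is.null(a) || is.null(b)) {
      stop("unmapped or incomplete residue: design position ", prov$design_pos[k],
           " / template ", prov$template_chain[k], ":", prov$template_resno[k],
           call. = FALSE)
    }
    mov[k, ] <- a
    fix[k, ] <- b
  }
  sup <- kabsch_superpose(mov, fix)
  dev2 <- rowSums((sup$transformed - fix)^2)
  per <- tibble::tibble(helix_id = prov$helix_id, dev2 = dev2)
  per <- dplyr::summarise(dplyr::group_by(per, .data$helix_id),
                          rmsd = sqrt(mean(.data$dev2)), n_res = dplyr::n(),
                          .groups = "drop")
  structure(list(
    rmsd = sup$rmsd,
    per_segment_rmsd = per,
    accepted = sup$rmsd < threshold,
    threshold = threshold,
    superposition = sup
  ), class = "design_validation")
}

#' @export
print.design_validation <- function(x, ...) {
  cat("<design_validation> rmsd ", format(round(x$rmsd, 4), nsmall = 4), " A — ",
      if (x$accepted) "ACCEPTED" else "REJECTED",
      " (threshold < ", x$threshold, " A)\n", sep = "")
  print(x$per_segment_rmsd)
  invisible(x)
}

#' @method tidy design_validation
#' @export
tidy.design_validation <- function(x, ...) x$per_segment_rmsd

#' @method glance design_validation
#' @export
glance.design_validation <- function(x, ...) {
  tibble::tibble(rmsd = x$rmsd, accepted = x$accepted, threshold = x$threshold)
}

#' @rdname autoplot_helpers
#' @method autoplot design_validation
#' @export
autoplot.design_validation <- function(object, ...) {
  ggplot2::ggplot(object$per_segment_rmsd,
                  ggplot2::aes(x = .data$helix_id, y = .data$rmsd)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "per-helix RMSD (Å)",
                  title = sprintf("Pooled helix-Cα RMSD %.3f Å (%s)",
                                  object$rmsd,
                                  if (object$accepted) "accepted" else "rejected"))
}
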