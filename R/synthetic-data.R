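# Parametric synthetic fixtures: idealized four-helix bundles with declared
# ground truth, receptor-contact probes, coordinate noise, and assay datasets.

# Cylindrical backbone parameters of an ideal alpha helix (radius, phase
# offset vs CA in degrees, axial offset vs CA in Angstrom), derived from an
# ideal-dihedral helix (phi -57.8, psi -47).
HELIX_CYL <- list(
  N = c(r = 1.5508, dph = -26.789, dz = -0.9118),
  CA = c(r = 2.282, dph = 0, dz = 0),
  C = c(r = 1.6807, dph = 26.655, dz = 1.0718),
  O = c(r = 2.6171, dph = 47.267, dz = 1.3461)
)

# Backbone atoms of one parametric helix: n residues, axis +z through the
# origin, residue i's CA at phase (i-1)*twist and height (i-1)*rise (then
# centred on z = 0). Returns a list of per-residue 4x3 matrices (N, CA, C, O).
parametric_helix <- function(n, rise, twist) {
  z_mid <- (n - 1) * rise / 2
  lapply(seq_len(n), function(i) {
    ph0 <- (i - 1) * twist
    z0 <- (i - 1) * rise - z_mid
    m <- t(vapply(HELIX_CYL, function(p) {
      a <- deg2rad(ph0 + p[["dph"]])
      c(p[["r"]] * cos(a), p[["r"]] * sin(a), z0 + p[["dz"]])
    }, numeric(3)))
    rownames(m) <- names(HELIX_CYL)
    m
  })
}

#' Generate an idealized antiparallel four-helix bundle with ground truth
#'
#' Traces ideal alpha-helical backbones (N, CA, C, O; poly-alanine) on the
#' corners of a regular polygon of side `inter_axis_spacing`, consecutive
#' helices antiparallel. Residue numbering embeds the declared native loop
#' lengths as numbering gaps (no loop coordinates by default), so
#' [loop_lengths()] and [assign_helices_auto()] have exact ground truth;
#' `include_loops = TRUE` additionally builds loop residues by CCD closure.
#'
#' @param n_helices Number of helices (default 4).
#' @param helix_lengths Residues per helix.
#' @param native_loops Declared inter-helix loop lengths (residues).
#' @param inter_axis_spacing Distance between adjacent helix axes (Angstrom).
#' @param rise_per_residue,twist_per_residue Helical parameters (Angstrom,
#'   degrees).
#' @param first_res Author number of the first helix residue.
#' @param include_loops Build native-style loop coordinates too.
#' @param seed Integer seed (used only for loop building).
#' @return List: `structure` (atom tibble, chain "A"), `ranges` (list of
#'   `c(start, end)`), `native_loops`, `helices` (via [extract_helices()]),
#'   and the generating parameters.
#' @export
make_ideal_bundle <- function(n_helices = 4L,
                              helix_lengths = c(20L, 16L, 19L, 23L),
                              native_loops = c(23L, 6L, 35L),
                              inter_axis_spacing = 10.5,
                              rise_per_residue = 1.5,
                              twist_per_residue = 100,
                              first_res = 8L,
                              include_loops = FALSE,
                              seed = 1L) {
  stopifnot(n_helices >= 2L, length(helix_lengths) == n_helices,
            length(native_loops) == n_helices - 1L, all(helix_lengths >= 5L),
            inter_axis_spacing > 2 * HELIX_CYL$CA[["r"]])

  # declared author-numbering ranges
  starts <- integer(n_helices); ends <- integer(n_helices)
  starts[1] <- first_res
  for (i in seq_len(n_helices)) {
    ends[i] <- starts[i] + helix_lengths[i] - 1L
    if (i < n_helices) starts[i + 1L] <- ends[i] + native_loops[i] + 1L
  }

  # axis lateral positions: regular n-gon with side = inter_axis_spacing
  circ <- inter_axis_spacing / (2 * sin(pi / n_helices))
  theta <- 2 * pi * (seq_len(n_helices) - 1L) / n_helices
  corners <- cbind(circ * cos(theta), circ * sin(theta))

  atoms <- list()
  for (h in seq_len(n_helices)) {
    res <- parametric_helix(helix_lengths[h], rise_per_residue, twist_per_residue)
    up <- h %% 2L == 1L
    for (i in seq_along(res)) {
      m <- res[[i]]
      if (!up) m <- m %*% diag(c(1, -1, -1))  # proper 180-degree flip about x
      atoms[[length(atoms) + 1L]] <- tibble::tibble(
        chain = "A", resno = starts[h] + i - 1L, ins = "", resname = "ALA",
        atom = rownames(m),
        x = unname(m[, 1]) + corners[h, 1], y = unname(m[, 2]) + corners[h, 2],
        z = unname(m[, 3])
      )
    }
  }
  s <- dplyr::arrange(dplyr::bind_rows(atoms), .data$resno)

  if (include_loops) {
    for (i in seq_len(n_helices - 1L)) {
      if (native_loops[i] == 0L) next
      frame_of <- function(resno) rbind(atom_xyz(s, "A", resno, "N"),
                                        atom_xyz(s, "A", resno, "CA"),
                                        atom_xyz(s, "A", resno, "C"))
      built <- build_connector(frame_of(ends[i]), frame_of(starts[i + 1L]),
                               length = native_loops[i], seed = seed + i,
                               tolerance = 0.75, max_iter = 500L)
      ba <- built$atoms
      for (j in seq_len(native_loops[i])) {
        sub <- ba[ba$res_index == j, ]
        s <- dplyr::bind_rows(s, tibble::tibble(
          chain = "A", resno = ends[i] + j, ins = "",
          resname = if (j %% 2L == 1L) "GLY" else "SER",
          atom = sub$atom, x = sub$x, y = sub$y, z = sub$z
        ))
      }
    }
    s <- dplyr::arrange(s, .data$resno)
  }

  ranges <- lapply(seq_len(n_helices), function(h) c(starts[h], ends[h]))
  list(
    structure = s,
    ranges = ranges,
    native_loops = as.integer(native_loops),
    helices = extract_helices(s, "A", ranges),
    inter_axis_spacing = inter_axis_spacing,
    rise_per_residue = rise_per_residue,
    twist_per_residue = twist_per_residue,
    seed = seed
  )
}

#' Add a rigid receptor probe chain contacting chosen helices
#'
#' Places a short rigid poly-alanine Calpha segment at `standoff` Angstrom
#' along the outward normal of each target helix, so that [assign_roles()]
#' with default settings labels exactly the targeted helices
#' `receptor_binding`.
#'
#' @param bundle A bundle from [make_ideal_bundle()].
#' @param target_helix_ids Helix ids (e.g. `c("H1", "H3")`); may be empty.
#' @param standoff Probe-to-helix atom distance (Angstrom), > 0.
#' @param probe_length Probe residues per target helix.
#' @param chain Probe chain id.
#' @return The bundle with `structure` extended by the probe chain.
#' @export
make_receptor_probe <- function(bundle, target_helix_ids, standoff = 4.0,
                                probe_length = 8L, chain = "R") {
  if (standoff <= 0) stop("standoff must be positive", call. = FALSE)
  if (length(target_helix_ids) == 0L) return(bundle)
  h <- bundle$helices
  unknown <- setdiff(target_helix_ids, h$helix_id)
  if (length(unknown)) stop("unknown helix id: ", unknown[1], call. = FALSE)
  s <- bundle$structure
  # bundle centre in the xy plane (mean of helix axis positions)
  axis_xy <- t(vapply(seq_len(nrow(h)), function(i) {
    ca <- s[s$chain == h$chain[i] & s$resno >= h$start_res[i] & s$resno <= h$end_res[i] &
              s$atom == "CA", c("x", "y")]
    colMeans(as.matrix(ca))
  }, numeric(2)))
  centre <- colMeans(axis_xy)
  probe <- list()
  resno <- 0L
  for (id in target_helix_ids) {
    i <- match(id, h$helix_id)
    outward <- unitv(c(axis_xy[i, ] - centre, 0))
    mid <- floor((h$start_res[i] + h$end_res[i]) / 2)
    span <- seq.int(mid - floor(probe_length / 2) + 1L, length.out = probe_length)
    span <- span[span >= h$start_res[i] & span <= h$end_res[i]]
    for (r in span) {
      ca <- atom_xyz(s, h$chain[i], r, "CA")
      resno <- resno + 1L
      probe[[length(probe) + 1L]] <- tibble::tibble(
        chain = chain, resno = resno, ins = "", resname = "ALA", atom = "CA",
        x = ca[1] + standoff * outward[1], y = ca[2] + standoff * outward[2],
        z = ca[3] + standoff * outward[3]
      )
    }
    resno <- resno + 10L  # numbering gap between probe segments
  }
  bundle$structure <- dplyr::bind_rows(s, dplyr::bind_rows(probe))
  bundle
}

#' Perturb atomic coordinates with i.i.d. Gaussian noise
#'
#' @param s Atom tibble (or a `design_model`, whose structure is perturbed).
#' @param sd Displacement standard deviation per coordinate (Angstrom);
#'   `sd = 0` is the identity.
#' @param seed Integer seed.
#' @return The perturbed counterpart.
#' @export
perturb_coordinates <- function(s, sd, seed = 1L) {
  if (sd < 0) stop("sd must be nonnegative", call. = FALSE)
  if (inherits(s, "design_model")) {
    s$structure <- perturb_coordinates(s$structure, sd, seed)
    return(s)
  }
  if (sd == 0) return(s)
  n <- nrow(s)
  noise <- with_seed(seed, matrix(stats::rnorm(3 * n, 0, sd), n, 3))
  s$x <- s$x + noise[, 1]
  s$y <- s$y + noise[, 2]
  s$z <- s$z + noise[, 3]
  s
}

#' Generate synthetic assay datasets with known ground truth
#'
#' Wraps [simulate_sensorgram()] and [simulate_melt_curve()] with defaults
#' mirroring the SPR protocol (180 s association, 600 s dissociation, 5-point
#' threefold dilution from 100 nM, Rmax 30 RU, 1%-Rmax noise) and the
#' thermal-shift assay (25-95 degC grid, 2%-amplitude noise). Kinetic rate
#' defaults are the double-mutant superkine constants; the melt default is the
#' single-mutant melting temperature.
#'
#' @param kinetics `NULL` to skip, or a list overriding any of: `ka`, `kd`,
#'   `rmax`, `top_conc` (M), `n_dilutions`, `dilution_factor`, `t_assoc`,
#'   `t_dissoc`, `dt`, `noise_frac` (fraction of Rmax).
#' @param melt `NULL` to skip, or a list overriding any of: `tm`, `slope`,
#'   `f_low`, `f_high`, `temperatures`, `noise_frac` (fraction of amplitude).
#' @param seed Integer master seed.
#' @return List with `sensorgrams` (stacked tibble with `series` ids, or
#'   `NULL`), `melt` (tibble or `NULL`), and `truth` (the generating
#'   parameters).
#' @export
make_assay_dataset <- function(kinetics = list(), melt = list(), seed = 1L) {
  # per-curve sub-seeds, kept inside the valid integer range for any master
  sub_seed <- function(k) as.integer((as.numeric(seed) * 1000 + k) %% 2147483647)
  out <- list(sensorgrams = NULL, melt = NULL, truth = list())
  if (!is.null(kinetics)) {
    k <- utils::modifyList(list(
      ka = 1.38e6, kd = 4.296e-3, rmax = 30, top_conc = 100e-9,
      n_dilutions = 5L, dilution_factor = 3, t_assoc = 180, t_dissoc = 600,
      dt = 1, noise_frac = 0.01
    ), kinetics)
    concs <- k$top_conc / k$dilution_factor^(seq_len(k$n_dilutions) - 1L)
    curves <- purrr::imap(concs, function(conc, i) {
      dplyr::mutate(
        simulate_sensorgram(k$ka, k$kd, k$rmax, conc, k$t_assoc, k$t_dissoc,
                            k$dt, noise_sd = k$noise_frac * k$rmax,
                            seed = if (k$noise_frac > 0) sub_seed(i) else NULL),
        series = i)
    })
    out$sensorgrams <- dplyr::bind_rows(curves)
    out$truth$kinetics <- k
    out$truth$kinetics$KD <- k$kd / k$ka
  }
  if (!is.null(melt)) {
    m <- utils::modifyList(list(
      tm = 71.12, slope = 2, f_low = 0, f_high = 1,
      temperatures = seq(25, 95, by = 0.5), noise_frac = 0.02
    ), melt)
    amp <- abs(m$f_high - m$f_low)
    out$melt <- simulate_melt_curve(
      m$tm, m$slope, m$f_low, m$f_high, m$temperatures,
      noise_sd = m$noise_frac * amp,
      seed = if (m$noise_frac > 0) sub_seed(999L) else NULL)
    out$truth$melt <- m
  }
  out
}
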