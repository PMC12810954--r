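# Shared fixtures (cached once per test run) and independent brute-force
# oracles used to cross-check the package's optimized implementations.

.fixtures <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- expr
  .fixtures[[name]]
}

default_bundle <- function() {
  cached_fixture("bundle", make_ideal_bundle())
}

default_blueprint <- function() {
  cached_fixture("blueprint", design_blueprint(default_bundle()$helices, fix_first = "H1"))
}

default_model <- function() {
  cached_fixture("model", assemble_model(
    default_bundle()$structure, default_bundle()$helices, default_blueprint(),
    seed = 1L
  ))
}

# Fixed-column PDB ATOM line writer for hand-built fixtures.
pdb_line <- function(serial, name, resn, chain, resno, x, y, z, ins = "") {
  name_field <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, name_field, resn, chain, resno,
          if (nzchar(ins)) ins else " ", x, y, z, 1.00, 0.00)
}

# Two-residue glycine/cysteine dipeptide with full backbone, roughly ideal
# geometry (coordinates only need to be self-consistent, not physical).
tiny_pdb_lines <- function() {
  c(
    pdb_line(1, "N",  "GLY", "A", 1, 0.000, 0.000, 0.000),
    pdb_line(2, "CA", "GLY", "A", 1, 1.458, 0.000, 0.000),
    pdb_line(3, "C",  "GLY", "A", 1, 2.009, 1.420, 0.000),
    pdb_line(4, "O",  "GLY", "A", 1, 1.251, 2.390, 0.000),
    pdb_line(5, "N",  "CYS", "A", 2, 3.332, 1.536, 0.000),
    pdb_line(6, "CA", "CYS", "A", 2, 3.988, 2.839, 0.000),
    pdb_line(7, "C",  "CYS", "A", 2, 5.504, 2.693, 0.000),
    pdb_line(8, "O",  "CYS", "A", 2, 6.030, 1.581, 0.000),
    pdb_line(9, "CB", "CYS", "A", 2, 3.534, 3.668, 1.203),
    "END"
  )
}

# Oracle: O(n^2) count of inter-group atom pairs within cutoff.
bf_count_contacts <- function(s, chain_a, chain_b, cutoff) {
  a <- s[s$chain == chain_a, c("x", "y", "z")]
  b <- s[s$chain == chain_b, c("x", "y", "z")]
  n <- 0L
  for (i in seq_len(nrow(a))) {
    d <- sqrt((b$x - a$x[i])^2 + (b$y - a$y[i])^2 + (b$z - a$z[i])^2)
    n <- n + sum(d <= cutoff)
  }
  n
}

# Oracle: O(n^2) scan for clashing atom pairs across all residues.
bf_clash_pairs <- function(s, threshold, min_sep) {
  pairs <- 0L
  n <- nrow(s)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (abs(s$resno[j] - s$resno[i]) < min_sep) next
      d <- sqrt((s$x[j] - s$x[i])^2 + (s$y[j] - s$y[i])^2 + (s$z[j] - s$z[i])^2)
      if (d < threshold) pairs <- pairs + 1L
    }
  }
  pairs
}

# Oracle: exhaustive scoring of every helix order by summed connector length.
bf_best_economy <- function(helices, fix_first = NULL,
                            span_per_residue = 3.8, slack_residues = 1L) {
  orders <- enumerate_topologies(helices, fix_first)
  best <- Inf
  for (ord in orders) {
    idx <- match(ord, helices$helix_id)
    total <- 0L
    for (i in seq_len(length(ord) - 1L)) {
      gap <- connector_gap(helices[idx[i], ], helices[idx[i + 1L], ])
      total <- total + min_connector_length(gap, span_per_residue, slack_residues)
    }
    best <- min(best, total)
  }
  best
}

# Oracle: coarse exhaustive search over proper rotations (z-y-z Euler grid,
# 5 degree spacing) for the minimal superposition RMSD of small point sets.
bf_min_rmsd <- function(moving, fixed, step_deg = 5) {
  cm <- colMeans(moving); cf <- colMeans(fixed)
  p <- sweep(moving, 2, cm); q <- sweep(fixed, 2, cf)
  rotz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  roty <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3)
  grid <- seq(0, 2 * pi - 1e-9, by = step_deg * pi / 180)
  grid_b <- seq(0, pi, by = step_deg * pi / 180)
  best <- Inf
  for (a in grid) {
    ra <- rotz(a)
    for (b in grid_b) {
      rab <- ra %*% roty(b)
      for (g in grid) {
        r <- rab %*% rotz(g)
        d <- p %*% t(r) - q
        rmsd <- sqrt(mean(rowSums(d^2)))
        if (rmsd < best) best <- rmsd
      }
    }
  }
  best
}

# Oracle: O(n^2) scan of CYS CB pairs inside the disulfide window.
bf_disulfide_pairs <- function(s, window = c(3.0, 5.0), min_sep = 3L) {
  cys <- unique(s$resno[s$resname == "CYS"])
  count <- 0L
  if (length(cys) < 2L) return(count)
  for (i in seq_len(length(cys) - 1L)) {
    for (j in seq.int(i + 1L, length(cys))) {
      if (abs(cys[j] - cys[i]) < min_sep) next
      a <- helixforge:::cbeta_xyz(s, cys[i])
      b <- helixforge:::cbeta_xyz(s, cys[j])
      d <- sqrt(sum((a - b)^2))
      if (d >= window[1] && d <= window[2]) count <- count + 1L
    }
  }
  count
}

# Oracle: forward-Euler integration of the 1:1 binding ODE
#   dR/dt = ka * C * (Rmax - R) - kd * R  (association; C = 0 afterwards).
bf_euler_sensorgram <- function(ka, kd, rmax, conc, t_assoc, t_dissoc,
                                times, dt = 0.01) {
  steps <- seq(0, t_assoc + t_dissoc, by = dt)
  r <- numeric(length(steps))
  for (i in seq_len(length(steps) - 1L)) {
    c_now <- if (steps[i] < t_assoc) conc else 0
    r[i + 1L] <- r[i] + dt * (ka * c_now * (rmax - r[i]) - kd * r[i])
  }
  approx(steps, r, xout = times)$y
}
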