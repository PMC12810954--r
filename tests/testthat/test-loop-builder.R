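# Anchor frames taken from the default bundle: residue 27 (end of H1) and
# residue 51 (start of H2), gap about 7.6 A.
anchor_frames <- function() {
  s <- default_bundle()$structure
  frame_of <- function(resno) rbind(atom_xyz(s, "A", resno, "N"),
                                    atom_xyz(s, "A", resno, "CA"),
                                    atom_xyz(s, "A", resno, "C"))
  list(c_frame = frame_of(27L), n_frame = frame_of(51L))
}

test_that("build_connector closes a feasible gap within tolerance", {
  fr <- anchor_frames()
  out <- build_connector(fr$c_frame, fr$n_frame, length = 4L, seed = 7L)
  expect_lte(out$closure_error, 0.5)
  expect_equal(nrow(out$atoms), 4L * 4L)  # N, CA, C, O per residue
  expect_setequal(unique(out$atoms$atom), c("N", "CA", "C", "O"))
})

test_that("built connectors have ideal bond lengths", {
  fr <- anchor_frames()
  out <- build_connector(fr$c_frame, fr$n_frame, length = 4L, seed = 7L)
  a <- out$atoms
  for (i in 1:4) {
    n <- as.numeric(a[a$res_index == i & a$atom == "N", c("x", "y", "z")])
    ca <- as.numeric(a[a$res_index == i & a$atom == "CA", c("x", "y", "z")])
    cc <- as.numeric(a[a$res_index == i & a$atom == "C", c("x", "y", "z")])
    o <- as.numeric(a[a$res_index == i & a$atom == "O", c("x", "y", "z")])
    expect_equal(sqrt(sum((ca - n)^2)), 1.458, tolerance = 1e-6)
    expect_equal(sqrt(sum((cc - ca)^2)), 1.525, tolerance = 1e-6)
    expect_equal(sqrt(sum((o - cc)^2)), 1.231, tolerance = 1e-6)
  }
  # peptide bonds between consecutive connector residues
  for (i in 1:3) {
    cc <- as.numeric(a[a$res_index == i & a$atom == "C", c("x", "y", "z")])
    n2 <- as.numeric(a[a$res_index == i + 1L & a$atom == "N", c("x", "y", "z")])
    expect_equal(sqrt(sum((n2 - cc)^2)), 1.329, tolerance = 1e-6)
  }
})

test_that("the winning trajectory's error trace is monotone non-increasing", {
  fr <- anchor_frames()
  out <- build_connector(fr$c_frame, fr$n_frame, length = 4L, seed = 7L)
  expect_true(all(diff(out$error_trace) <= 1e-9))
  expect_equal(out$error_trace[length(out$error_trace)], out$closure_error)
})

test_that("build_connector is deterministic under a fixed seed", {
  fr <- anchor_frames()
  a <- build_connector(fr$c_frame, fr$n_frame, length = 4L, seed = 11L)
  b <- build_connector(fr$c_frame, fr$n_frame, length = 4L, seed = 11L)
  expect_identical(a, b)
  c <- build_connector(fr$c_frame, fr$n_frame, length = 4L, seed = 12L)
  expect_false(identical(a$atoms, c$atoms))
})

test_that("build_connector does not disturb the caller's RNG stream", {
  fr <- anchor_frames()
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(build_connector(fr$c_frame, fr$n_frame, length = 4L, seed = 7L))
  expect_identical(runif(1), before)
})

test_that("an unbridgeable gap is rejected as infeasible", {
  fr <- anchor_frames()
  far <- fr$n_frame + 40
  expect_error(build_connector(fr$c_frame, far, length = 2L, seed = 1L),
               "infeasible")
})

test_that("assemble_model copies helix coordinates bit-for-bit", {
  b <- default_bundle()
  m <- default_model()
  num <- m$provenance
  for (k in which(num$source == "template")[c(1, 25, 60)]) {
    tmpl <- b$structure[b$structure$resno == num$template_resno[k], ]
    got <- m$structure[m$structure$resno == num$design_pos[k], ]
    expect_identical(got$x, tmpl$x)
    expect_identical(got$y, tmpl$y)
    expect_identical(got$z, tmpl$z)
    expect_identical(got$resname, tmpl$resname)
  }
})

test_that("assembled model has blueprint length and closed connectors", {
  m <- default_model()
  bp <- default_blueprint()
  expect_equal(nchar(m$sequence), nrow(bp$numbering))
  expect_equal(length(m$closure_errors), nrow(bp$connectors))
  expect_true(all(m$closure_errors <= 0.5))
  expect_equal(sort(unique(m$structure$resno)), seq_len(nrow(bp$numbering)))
})

test_that("connector residues alternate glycine and serine", {
  m <- default_model()
  new_pos <- m$provenance$design_pos[m$provenance$source == "new"]
  chars <- strsplit(m$sequence, "")[[1]][new_pos]
  expect_true(all(chars %in% c("G", "S")))
  expect_true(any(chars == "G") && any(chars == "S"))
})

test_that("assemble_model is deterministic and seed-sensitive", {
  b <- default_bundle()
  bp <- default_blueprint()
  m1 <- assemble_model(b$structure, b$helices, bp, seed = 5L)
  m2 <- assemble_model(b$structure, b$helices, bp, seed = 5L)
  expect_identical(m1$structure, m2$structure)
  m3 <- assemble_model(b$structure, b$helices, bp, seed = 6L)
  expect_false(identical(m1$structure, m3$structure))
})

test_that("detect_clashes matches a brute-force all-pairs scan", {
  m <- default_model()
  rep0 <- detect_clashes(m)
  expect_equal(nrow(rep0$pairs), bf_clash_pairs(m$structure, 2.6, 3L))

  # Perturbed copy with guaranteed clashes.
  pert <- perturb_coordinates(m, sd = 1.2, seed = 3L)
  rep1 <- detect_clashes(pert, threshold = 3.2)
  expect_equal(nrow(rep1$pairs), bf_clash_pairs(pert$structure, 3.2, 3L))
  expect_gt(nrow(rep1$pairs), 0L)
  expect_true(all(rep1$pairs$distance < 3.2))
  expect_true(all(abs(rep1$pairs$pos_j - rep1$pairs$pos_i) >= 3L))
})

test_that("detect_clashes flags an engineered close pair and spares bonded ones", {
  s <- tibble::tibble(
    chain = "A", resno = c(1L, 2L, 10L), ins = "", resname = "ALA",
    atom = "CA", x = c(0, 3.8, 0), y = c(0, 0, 2.0), z = 0
  )
  # residues 1-2 are sequence neighbours (exempt even if close);
  # residues 1 and 10 are 2.0 A apart and far in sequence: one clash.
  rep <- detect_clashes(s, threshold = 2.6, min_sequence_separation = 3L)
  expect_equal(nrow(rep$pairs), 1L)
  expect_equal(rep$pairs$pos_i, 1L)
  expect_equal(rep$pairs$pos_j, 10L)
  expect_equal(rep$pairs$distance, 2.0)
})
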