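test_that("reconstructed virtual Cbeta has ideal local geometry", {
  m <- default_model()
  s <- m$structure
  # pick a helix residue (no CB present in the poly-alanine backbone template)
  p <- m$provenance$design_pos[m$provenance$source == "template"][10]
  cb <- helixforge:::cbeta_xyz(s, p)
  ca <- atom_xyz(s, "A", p, "CA")
  n <- atom_xyz(s, "A", p, "N")
  cc <- atom_xyz(s, "A", p, "C")
  expect_equal(sqrt(sum((cb - ca)^2)), 1.53, tolerance = 0.03)
  ang <- function(a, b, c) {
    u <- a - b; v <- c - b
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  }
  expect_equal(ang(n, ca, cb), 110, tolerance = 3)
  expect_equal(ang(cc, ca, cb), 110, tolerance = 3)
})

test_that("a real CB atom is preferred over reconstruction", {
  s <- read_structure(tiny_pdb_lines())
  cb <- helixforge:::cbeta_xyz(s, 2L)
  expect_equal(cb, as.numeric(s[s$resno == 2L & s$atom == "CB", c("x", "y", "z")]))
})

test_that("scan_disulfide_sites reports sorted in-window pairs across regions", {
  m <- default_model()
  hits <- scan_disulfide_sites(m, c(1L, 20L), c(68L, 90L))
  expect_gt(nrow(hits), 0L)
  expect_true(all(diff(hits$geometry_score) >= 0))
  expect_true(all(hits$cb_distance >= 3.0 & hits$cb_distance <= 5.0))
  expect_equal(hits$geometry_score, abs(hits$cb_distance - 4.0))
  # every reported pair has one side in each region
  expect_true(all(hits$pos_i <= 20L & hits$pos_j >= 68L))
})

test_that("scan_disulfide_sites matches a brute-force scan and rejects overlap", {
  m <- default_model()
  hits <- scan_disulfide_sites(m, c(1L, 20L), c(68L, 90L))
  # O(n^2) oracle over the same regions
  count <- 0L
  for (i in 1:20) {
    for (j in 68:90) {
      d <- sqrt(sum((helixforge:::cbeta_xyz(m$structure, i) -
                       helixforge:::cbeta_xyz(m$structure, j))^2))
      if (d >= 3.0 && d <= 5.0) count <- count + 1L
    }
  }
  expect_equal(nrow(hits), count)
  expect_error(scan_disulfide_sites(m, c(1L, 20L), c(15L, 30L)), "overlap")
})

test_that("parse_mutations handles the compact notation", {
  muts <- parse_mutations("G4C, l96c")
  expect_equal(muts$position, c(4L, 96L))
  expect_equal(muts$wt_aa, c("G", "L"))
  expect_equal(muts$mut_aa, c("C", "C"))
  expect_error(parse_mutations("Q6"), "cannot parse")
  expect_error(parse_mutations("6P"), "cannot parse")
})

test_that("apply_mutations edits sequence and resnames, never the backbone", {
  m <- default_model()
  p <- m$provenance$design_pos[m$provenance$source == "template"][5]
  wt <- substr(m$sequence, p, p)
  m2 <- apply_mutations(m, sprintf("%s%dC", wt, p))
  expect_equal(substr(m2$sequence, p, p), "C")
  expect_equal(unique(m2$structure$resname[m2$structure$resno == p]), "CYS")
  bb <- function(mm) mm$structure[mm$structure$resno == p &
                                    mm$structure$atom %in% c("N", "CA", "C", "O"), ]
  expect_identical(bb(m2)[, c("x", "y", "z")], bb(m)[, c("x", "y", "z")])
  # rest of the structure untouched
  expect_identical(m2$structure[m2$structure$resno != p, ],
                   m$structure[m$structure$resno != p, ])
})

test_that("apply_mutations enforces the wild-type identity", {
  m <- default_model()
  p <- m$provenance$design_pos[m$provenance$source == "template"][5]
  wt <- substr(m$sequence, p, p)
  bad <- setdiff(c("W", "Y"), wt)[1]
  expect_error(apply_mutations(m, sprintf("%s%dC", bad, p)),
               "wild-type mismatch")
  expect_error(apply_mutations(m, sprintf("%s%d%s", wt, p, wt)), "does not change")
})

test_that("choose_residue prefers hydrophobic buried, polar exposed", {
  m <- default_model()
  ca <- m$structure[m$structure$atom == "CA", ]
  counts <- vapply(ca$resno, function(p) {
    here <- as.numeric(ca[ca$resno == p, c("x", "y", "z")])
    oth <- ca[abs(ca$resno - p) > 2L, ]
    sum(sqrt((oth$x - here[1])^2 + (oth$y - here[2])^2 + (oth$z - here[3])^2) <= 10)
  }, integer(1))
  buried_pos <- ca$resno[which.max(counts)]
  exposed_pos <- ca$resno[which.min(counts)]
  db <- choose_residue(m, buried_pos, c("I", "T"))
  de <- choose_residue(m, exposed_pos, c("I", "T"))
  expect_true(db$buried)
  expect_false(de$buried)
  expect_equal(db$chosen, "I")
  expect_equal(de$chosen, "T")
})

test_that("choose_residue penalizes mid-helix proline and is deterministic", {
  m <- default_model()
  mid <- choose_residue(m, 15L, c("P", "A"))
  expect_equal(mid$chosen, "A")
  expect_equal(mid$scores$helix[mid$scores$candidate == "P"], 10)
  first <- choose_residue(m, 1L, c("P", "A"))
  expect_equal(first$scores$helix[first$scores$candidate == "P"], 0)
  expect_identical(choose_residue(m, 15L, c("P", "A")),
                   choose_residue(m, 15L, c("P", "A")))
  expect_error(choose_residue(m, 15L, "B"), "unknown amino-acid")
})

test_that("truncate_n_terminus drops residues and re-bases numbering", {
  seq152 <- paste(rep("A", 152), collapse = "")
  expect_equal(nchar(truncate_n_terminus(seq152, 7L)), 145L)
  m <- default_model()
  len <- nchar(m$sequence)
  m2 <- truncate_n_terminus(m, 5L)
  expect_equal(nchar(m2$sequence), len - 5L)
  expect_equal(min(m2$structure$resno), 1L)
  expect_equal(m2$sequence, substr(m$sequence, 6L, len))
  expect_identical(truncate_n_terminus(m, 0L), m)
  expect_error(truncate_n_terminus(m, len), "cannot truncate")
})

test_that("count_disulfides matches the brute-force pair scan", {
  m <- default_model()
  expect_equal(count_disulfides(m), 0L)
  hits <- scan_disulfide_sites(m, c(1L, 20L), c(68L, 90L))
  best <- hits[1, ]
  wt_i <- substr(m$sequence, best$pos_i, best$pos_i)
  wt_j <- substr(m$sequence, best$pos_j, best$pos_j)
  m2 <- apply_mutations(m, sprintf("%s%dC,%s%dC", wt_i, best$pos_i, wt_j, best$pos_j))
  expect_equal(count_disulfides(m2), 1L)
  expect_equal(count_disulfides(m2), bf_disulfide_pairs(m2$structure))
})
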