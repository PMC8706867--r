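# Constructed coordinates with known answers plus file-format
# round-trips through text PDB/SDF written on the fly.

.toy_protein <- data.frame(
  chain = "A",
  resno = rep(1:3, each = 2),
  resname = rep(c("ALA", "VAL", "GLY"), each = 2),
  elety = rep(c("CA", "CB"), 3),
  element = "C",
  x = c(0, 1, 10, 11, 20, 21), y = 0, z = 0,
  stringsAsFactors = FALSE)

test_that("contact_residues: boundary inclusive, empty ligand errors", {
  # ligand atom exactly 5.0 A from residue 1's CB at x=1
  lig <- cbind(x = 6, y = 0, z = 0)
  cr <- contact_residues(.toy_protein, lig, cutoff = 5)
  expect_true(1L %in% cr$resno)            # 5.0 <= 5.0: included
  expect_true(2L %in% cr$resno)            # 4.0 from x=10
  expect_false(3L %in% cr$resno)
  far <- cbind(x = 1000, y = 0, z = 0)
  expect_equal(nrow(contact_residues(.toy_protein, far, cutoff = 5)), 0L)
  expect_error(contact_residues(.toy_protein,
                                matrix(numeric(0), 0, 3), cutoff = 5),
               "empty")
  expect_error(contact_residues(.toy_protein, lig, cutoff = 0), "cutoff")
})

test_that("single residue in range is found by both engines", {
  lig <- cbind(x = 10.5, y = 3, z = 0)   # 3.04 A from residue 2 only
  for (m in c("naive", "grid")) {
    cr <- contact_residues(.toy_protein, lig, cutoff = 5, method = m)
    expect_equal(cr$resno, 2L, info = m)
  }
})

test_that("contact_frequencies follows the counting contract", {
  # ligand 1 contacts residue 1 only; ligand 2 contacts residues 1 and 2
  ps <- pose_set(.toy_protein,
                 list(l1 = cbind(x = 2, y = 2, z = 0),
                      l2 = rbind(c(1, 3, 0), c(10, 3, 0))))
  prof <- contact_frequencies(ps, cutoff = 5)
  f <- setNames(prof$frequency, prof$resno)
  expect_equal(f[["1"]], 1.0)
  expect_equal(f[["2"]], 0.5)
  expect_equal(f[["3"]], 0.0)
  expect_equal(attr(prof, "n_ligands"), 2L)
  # conservation: frequency * n_ligands is an integer count
  expect_equal(prof$frequency * 2, round(prof$frequency * 2))
})

test_that("frequencies are invariant under rigid motion", {
  ps <- gen_complex(6L, data.frame(residue = c(2L, 5L, 5L),
                                   distance = c(3, 4, 4.8)), seed = 13L)
  prof <- contact_frequencies(ps, cutoff = 5)
  # rotate 90 degrees about z and translate everything
  rot <- function(m) {
    cbind(x = -m[, 2] + 7, y = m[, 1] - 3, z = m[, 3] + 11)
  }
  prot2 <- ps$protein
  xyz2 <- rot(as.matrix(prot2[, c("x", "y", "z")]))
  prot2$x <- xyz2[, 1]; prot2$y <- xyz2[, 2]; prot2$z <- xyz2[, 3]
  ps2 <- pose_set(prot2, lapply(ps$ligands, rot))
  prof2 <- contact_frequencies(ps2, cutoff = 5)
  expect_equal(prof$frequency, prof2$frequency)
})

test_that("grid engine matches naive oracle on 100 random pose sets", {
  set.seed(77)
  for (i in 1:100) {
    prot <- data.frame(chain = "A", resno = rep(1:4, each = 3),
                       resname = "GLY", elety = "CA", element = "C",
                       x = runif(12, 0, 25), y = runif(12, 0, 25),
                       z = runif(12, 0, 25), stringsAsFactors = FALSE)
    ligs <- lapply(1:3, function(j) {
      cbind(x = runif(4, 0, 25), y = runif(4, 0, 25), z = runif(4, 0, 25))
    })
    ps <- pose_set(prot, ligs)
    pn <- contact_frequencies(ps, cutoff = 5, method = "naive")
    pg <- contact_frequencies(ps, cutoff = 5, method = "grid")
    expect_identical(pn$frequency, pg$frequency)
  }
})

test_that("toy complex reproduces its ground-truth profile at 5 A", {
  ps <- gen_complex(8L, data.frame(residue = c(2L, 2L, 6L, 6L, 6L),
                                   distance = c(3, 4.5, 2.5, 4, 7)),
                    seed = 31L)
  prof <- contact_frequencies(ps, cutoff = 5)
  gt <- attr(ps, "ground_truth")
  for (r in seq_len(8L)) {
    expected <- mean(vapply(gt, function(g) g[[as.character(r)]] <= 5,
                            logical(1)))
    expect_equal(prof$frequency[prof$resno == r], expected,
                 info = paste("residue", r))
  }
})

test_that("hotspot filter is strict and sorted", {
  ps <- pose_set(.toy_protein,
                 list(l1 = cbind(x = 2, y = 2, z = 0),
                      l2 = rbind(c(1, 3, 0), c(10, 3, 0))))
  prof <- contact_frequencies(ps, cutoff = 5)
  hs <- hotspot_filter(prof, 0.5)
  expect_equal(hs$resno, 1L)   # 0.5 itself excluded (strict >)
  all_hit <- hotspot_filter(prof, 0)
  expect_equal(all_hit$resno, c(1L, 2L))   # sorted by frequency desc
  expect_true(all(diff(all_hit$frequency) <= 0))
  expect_equal(nrow(hotspot_filter(prof, 1)), 0L)
})

test_that("profile similarity is Pearson over the residue union", {
  ps <- gen_complex(6L, data.frame(residue = c(2L, 5L), distance = c(3, 3)),
                    seed = 17L)
  prof <- contact_frequencies(ps, cutoff = 5)
  expect_equal(profile_similarity(prof, prof), 1)
})

test_that("PDB/SDF files round-trip through the readers", {
  # write a small PDB by hand
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1L, 1L, 0, 0, 0),
    sprintf("ATOM  %5d  CB  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            2L, 1L, 1.5, 0, 0),
    sprintf("ATOM  %5d  CA  VAL A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            3L, 2L, 8, 0, 0),
    "END"), pdb)
  prot <- read_protein_pdb(pdb)
  expect_equal(nrow(prot), 3L)
  expect_equal(unique(prot$resname), c("ALA", "VAL"))

  # two-pose SDF with one hydrogen that must be dropped
  sdf <- tempfile(fileext = ".sdf")
  atom <- function(x, y, z, el) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            x, y, z, el)
  }
  writeLines(c(
    "poseA", "  made-up", "",
    "  2  1  0  0  0  0  0  0  0  0999 V2000",
    atom(0.5, 0, 0, "C"), atom(1.9, 0, 0, "H"),
    "  1  2  1  0", "M  END", "$$$$",
    "poseB", "  made-up", "",
    "  1  0  0  0  0  0  0  0  0  0999 V2000",
    atom(8.2, 0.5, 0, "N"), "M  END", "$$$$"), sdf)
  poses <- read_poses(sdf)
  expect_named(poses, c("poseA", "poseB"))
  expect_equal(nrow(poses$poseA), 1L)   # H removed
  expect_equal(unname(poses$poseB[1, "x"]), 8.2)

  ps <- pose_set(prot, poses)
  prof <- contact_frequencies(ps, cutoff = 5)
  expect_equal(prof$frequency[prof$resno == 1], 0.5)  # only poseA near ALA
  expect_equal(prof$frequency[prof$resno == 2], 0.5)  # only poseB near VAL
  unlink(c(pdb, sdf))
})

test_that("profiles write to CSV and JSON", {
  ps <- pose_set(.toy_protein, list(l1 = cbind(x = 2, y = 2, z = 0)))
  prof <- contact_frequencies(ps, cutoff = 5)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_contact_profile(prof, csv, js)
  back <- utils::read.csv(csv)
  expect_equal(back$frequency, prof$frequency)
  j <- jsonlite::read_json(js)
  expect_equal(j$cutoff, 5)
  expect_equal(j$n_ligands, 1L)
  unlink(c(csv, js))
})
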