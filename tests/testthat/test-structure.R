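toy_pdb_lines <- function() {
  c("ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00",
    "ATOM      3  CA  SER A   3       7.600   0.000   0.000  1.00  0.00",
    "END")
}

test_that("a minimal PDB parses into one residue per C-alpha", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(toy_pdb_lines(), f)
  s <- read_pdb(f, chain = "A")
  expect_s3_class(s, "cg_structure")
  expect_equal(nrow(s), 3L)
  expect_equal(s$resid, c("ALA", "GLY", "SER"))
  expect_equal(s$x, c(0, 3.8, 7.6))
  expect_error(read_pdb(f, chain = "B"), "\\{A\\}")
})

test_that("multi-model files honor the model argument", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    toy_pdb_lines()[1:3],
    "ENDMDL",
    "MODEL        2",
    sub("0.000   0.000   0.000", "9.000   9.000   9.000", toy_pdb_lines()[1]),
    toy_pdb_lines()[2:3],
    "ENDMDL",
    "END"), f)
  expect_equal(read_pdb(f, chain = "A", model = 1)$x[1], 0)
  expect_equal(read_pdb(f, chain = "A", model = 2)$x[1], 9)
  expect_error(read_pdb(f, chain = "A", model = 3), "has 2")
})

test_that("altloc picks highest occupancy and MSE is treated as MET", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60  0.00",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00",
    "HETATM    4  CA  MSE A   3       7.600   0.000   0.000  1.00  0.00",
    "HETATM    5 SE   MSE A   3       8.600   1.000   0.000  1.00  0.00",
    "HETATM    6  O   HOH A 101      20.000  20.000  20.000  1.00  0.00",
    "END"), f)
  s <- read_pdb(f, chain = "A")
  expect_equal(nrow(s), 3L)               # water skipped
  expect_equal(s$x[1], 1)                 # occupancy 0.60 altloc B wins
  expect_equal(s$resid[3], "MET")
  expect_equal(rownames(s$sidechain[[3]]), "SE")
})

test_that("C-alpha records round-trip through PDB text", {
  for (seed in c(1, 7)) {
    s <- make_structure("compact_random", n = 12, seed = seed,
                        sidechain = "cb")
    f <- withr::local_tempfile(fileext = ".pdb")
    write_pdb(s, f)
    back <- read_pdb(f, chain = "A")
    expect_lt(max(abs(cbind(s$x, s$y, s$z) - cbind(back$x, back$y, back$z))),
              1e-3)
    expect_equal(back$sidechain[[1]][1, ], s$sidechain[[1]][1, ],
                 tolerance = 1e-3)
  }
})

test_that("helical C-alpha traces are labeled non-loop in the interior", {
  h <- make_structure("helix", n = 15)
  h <- assign_secondary_structure(h)
  expect_true(all(h$ss[4:12] == "non-loop"))
})

test_that("extended or tiny chains fall back to all-loop", {
  line <- assign_secondary_structure(make_structure("path", n = 12))
  expect_true(all(line$ss == "loop"))
  tiny <- assign_secondary_structure(k3_structure())
  expect_true(all(tiny$ss == "loop"))
})

test_that("backbone hydrogen bonds drive the full assignment when available", {
  helix <- synthetic_backbone(n = 14, phi = -57, psi = -47)
  helix <- assign_secondary_structure(helix)
  expect_true(all(helix$ss[5:10] == "non-loop"))
  # a single extended strand has no hydrogen-bond partner: everything loop
  strand <- synthetic_backbone(n = 14, phi = -139, psi = 135)
  strand <- assign_secondary_structure(strand)
  expect_true(all(strand$ss == "loop"))
})

test_that("segment resolution maps keys to contiguous indices", {
  s <- assign_secondary_structure(make_structure("compact_random", n = 50,
                                                 seed = 13))
  seg <- resolve_segment(s, "A", 10, 12)
  expect_equal(seg$n_AA, 3L)
  expect_equal(seg$residue_indices[[1]], 10:12)

  # inclusive-range arithmetic holds across the chain
  for (first in c(2, 17, 30)) {
    for (len in c(2, 5, 11)) {
      seg <- resolve_segment(s, "A", first, first + len - 1)
      expect_equal(seg$n_AA, len)
    }
  }

  expect_warning(seg1 <- resolve_segment(s, "A", 10, 10), "outside")
  expect_equal(seg1$n_AA, 1L)
  expect_error(resolve_segment(s, "A", 1, 4), "terminus")
  expect_error(resolve_segment(s, "A", 45, 50), "terminus")
  expect_error(resolve_segment(s, "A", 10, 999), "not found")
  expect_error(resolve_segment(s, "B", 10, 12), "available")
  expect_error(resolve_segment(s, "A", 12, 10), "chain order")
})

test_that("segment region is loop only when every residue is loop", {
  s <- assign_secondary_structure(make_structure("compact_random", n = 30,
                                                 seed = 23))
  s$ss <- rep("loop", 30)
  s$ss[15] <- "non-loop"
  expect_equal(resolve_segment(s, "A", 5, 8)$region, "loop")
  expect_equal(resolve_segment(s, "A", 14, 16)$region, "non-loop")
  # externally supplied label overrides the computed one
  expect_equal(resolve_segment(s, "A", 5, 8, region = "non-loop")$region,
               "non-loop")
})

test_that("segment tables validate their schema on read", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("source_id,chain,first_res,last_res,region,label",
               "toy,A,5,8,loop,positive",
               "toy,A,10,14,non-loop,unlabeled"), f)
  tab <- read_segment_table(f)
  expect_equal(nrow(tab), 2L)
  writeLines(c("source_id,chain,first_res", "toy,A,5"), f)
  expect_error(read_segment_table(f), "missing columns")
  writeLines(c("source_id,chain,first_res,last_res,label",
               "toy,A,5,8,bogus"), f)
  expect_error(read_segment_table(f), "positive or unlabeled")
})
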