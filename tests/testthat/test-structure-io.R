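test_that("hand-written PDB parses to matching atoms and waters are dropped", {
  p <- writeTinyPDB(tempfile(fileext = ".pdb"), tinyPDBLines)
  s <- readPDB(p)
  a <- atoms(s)
  expect_equal(nrow(a), 3)
  expect_equal(a$name, c("N", "CA", "C"))
  expect_equal(a$x, c(1.0, 2.5, 3.8), tolerance = 1e-9)
  expect_equal(a$element, c("N", "C", "C"))

  pw <- writeTinyPDB(tempfile(fileext = ".pdb"), watersPDBLines)
  sw <- readPDB(pw)
  expect_equal(nrow(atoms(sw)), 5)
  expect_false(any(atoms(sw)$resname == "HOH"))

  expect_error(readPDB(tempfile(fileext = ".pdb")), "not found")
})

test_that("write/read round trip preserves atoms to PDB field precision", {
  s <- makeToyStructure(nResidues = 12L, seed = 42L)
  p <- tempfile(fileext = ".pdb")
  writePDB(s, p)
  s2 <- readPDB(p)
  a1 <- atoms(s); a2 <- atoms(s2)
  expect_equal(nrow(a1), nrow(a2))
  expect_equal(a1$name, a2$name)
  expect_equal(a1$resname, a2$resname)
  expect_equal(a1$x, a2$x, tolerance = 1.1e-3)
  expect_equal(a1$y, a2$y, tolerance = 1.1e-3)
  expect_equal(a1$z, a2$z, tolerance = 1.1e-3)
})

test_that("charge assignment reproduces formal charges per residue", {
  s <- makeToyStructure(nResidues = 20L, seed = 3L,
                        patches = list(list(center = c(0, 0, 1),
                                            angularRadius = 35,
                                            resname = "ASP")))
  # convert two scaffold residues by hand to get a Lys as well
  a <- s@atoms
  s <- assignParameters(s)
  a <- atoms(s)
  byRes <- split(a, paste(a$chain, a$resno))
  for (res in byRes) {
    expect_equal(sum(res$charge),
                 espvisc:::residueFormalCharge(res$resname[1]),
                 tolerance = 1e-6)
  }
  asp <- a[a$resname == "ASP", ]
  expect_true(nrow(asp) > 0)
  side <- asp[asp$name %in% c("CG", "OD1", "OD2"), ]
  nAsp <- length(unique(paste(asp$chain, asp$resno)))
  expect_equal(sum(side$charge), -1 * nAsp, tolerance = 1e-6)
  # total structure charge equals the sum of residue formal charges
  formal <- sum(vapply(byRes, function(r)
    espvisc:::residueFormalCharge(r$resname[1]), 1.0))
  expect_equal(sum(a$charge), formal, tolerance = 1e-6)
})

test_that("lysine and arginine groups carry +1 and His/termini are configurable", {
  s <- makeToyStructure(nResidues = 16L, seed = 8L,
                        patches = list(list(center = c(1, 0, 0),
                                            angularRadius = 25,
                                            resname = "LYS"),
                                       list(center = c(-1, 0, 0),
                                            angularRadius = 25,
                                            resname = "ARG")))
  a <- atoms(assignParameters(s))
  expect_equal(unique(a$charge[a$name == "NZ"]), 1)
  arg <- a[a$resname == "ARG" & a$name %in% c("CZ", "NH1", "NH2"), ]
  argRes <- split(arg, paste(arg$chain, arg$resno))
  for (r in argRes) expect_equal(sum(r$charge), 1, tolerance = 1e-6)
  expect_error(
    assignParameters(barStructure(rbind(c(0, 0, 0)), resnames = "XYZ"),
                     fallback = FALSE),
    "unknown residue")
})

test_that("canonicalization centers the center of mass and is idempotent", {
  s1 <- barStructure(rbind(c(3, 0, 0)))
  expect_equal(unlist(atoms(canonicalize(s1))[, c("x", "y", "z")]),
               c(x = 0, y = 0, z = 0), tolerance = 1e-12)
  s2 <- barStructure(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(atoms(canonicalize(s2))$x, c(-1, 1), tolerance = 1e-12)

  s3 <- canonicalize(assignParameters(makeToyStructure(seed = 5L)))
  a <- atoms(s3)
  com <- colSums(a[, c("x", "y", "z")] * a$mass) / sum(a$mass)
  expect_lt(sqrt(sum(com^2)), 1e-6)
  s4 <- canonicalize(s3)
  expect_equal(atoms(s4)$x, a$x, tolerance = 1e-9)
})

test_that("segment annotation follows the bundled Chothia ranges", {
  s <- makeToyStructure(nResidues = 10L, seed = 2L)
  segNone <- annotateSegments(s, "none")
  expect_true(all(segNone@table$segment == "unknown"))

  res <- unique(atoms(s)[, c("chain", "resno", "insert")])
  numbering <- data.frame(chain = res$chain, resno = res$resno,
                          insert = res$insert,
                          chothia = ifelse(res$chain == "L",
                                           23 + res$resno,  # L resno 1 -> 24
                                           10 + res$resno)) # heavy: framework
  seg <- annotateSegments(s, numbering)
  tab <- seg@table
  lightIn <- tab$chain == "L" & (23 + tab$resno) >= 24 & (23 + tab$resno) <= 34
  expect_true(all(tab$segment[lightIn] == "CDR-L1"))
  expect_true(all(tab$segment[tab$chain == "H"] == "framework"))

  expect_error(annotateSegments(s, numbering[-1, ]), "does not cover")
})
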