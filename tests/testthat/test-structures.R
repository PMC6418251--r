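test_that("parsePDB reads hand-written ATOM records back exactly", {
  models <- parsePDB(text = twoAtomPDB())
  expect_length(models, 1)
  m <- models[[1]]
  expect_equal(nAtoms(m), 2L)
  expect_equal(coords(m)[1, ], c(11.104, 6.134, -6.504))
  expect_equal(atomTable(m)$name, c("N", "CA"))
  expect_equal(atomTable(m)$chainId, c("A", "A"))
})

test_that("parsePDB splits MODEL blocks into equal-sized models", {
  body <- sub("\nEND$", "", twoAtomPDB())
  text <- paste(
    "MODEL        1", body, "ENDMDL",
    "MODEL        2", body, "ENDMDL",
    "MODEL        3", body, "ENDMDL", "END", sep = "\n")
  models <- parsePDB(text = text)
  expect_length(models, 3)
  expect_true(all(vapply(models, nAtoms, integer(1)) == 2L))
})

test_that("parsePDB rejects files without ATOM records and malformed coordinates", {
  expect_error(parsePDB(text = "HEADER  NOTHING\nEND"), "no ATOM records")
  bad <- paste(
    "ATOM      1  N   ALA A   1      11.104   6.13x  -6.504  1.00  0.00           N",
    "END", sep = "\n")
  expect_error(parsePDB(text = bad), "line 1")
})

test_that("alt-loc resolution keeps the highest-occupancy record", {
  text <- paste(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  N   ALA A   1       1.000   0.000   0.000  1.00  0.00           N",
    "END", sep = "\n")
  m <- parsePDB(text = text)[[1]]
  ca <- coords(m)[atomTable(m)$name == "CA", ]
  expect_equal(as.numeric(ca), c(5, 0, 0))  # B has the higher occupancy
})

test_that("write-then-parse round trip preserves coordinates at PDB precision", {
  toy <- makeToyComplex(8, 8, list(list(basic = "LYS", acidic = "ASP",
                                        distance = 3.6)))
  f <- withr::local_tempfile(fileext = ".pdb")
  writePDB(toy$model, f)
  m2 <- parsePDB(f)[[1]]
  expect_lt(max(abs(coords(m2) - coords(toy$model))), 1e-3)
  # idempotence: a second round trip reproduces the first exactly
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writePDB(m2, f2)
  m3 <- parsePDB(f2)[[1]]
  expect_identical(coords(m3), coords(m2))
})

test_that("representative distance is the Euclidean rep-atom distance", {
  toy <- makeToyComplex(4, 4, list(list(basic = "LYS", acidic = "ASP",
                                        distance = 3.6)))
  expect_equal(representativeDistance(toy$model, "A:1", "B:1"), 3.6)
  # symmetric
  expect_identical(representativeDistance(toy$model, "A:1", "B:1"),
                   representativeDistance(toy$model, "B:1", "A:1"))
  expect_error(representativeDistance(toy$model, "A:99", "B:1"), "A:99")
})

test_that("group minimum distance finds the planted minimum and rejects same polarity", {
  toy <- makeToyComplex(4, 4, list(list(basic = "ARG", acidic = "GLU",
                                        distance = 5.0)))
  m <- toy$model
  gm <- groupMinDistance(m, "A:1", "B:1")
  # brute force over all group atom pairs
  a <- atomTable(m); x <- coords(m)
  gi <- which(a$chainId == "A" & a$resSeq == 1 &
              a$name %in% c("NE", "NH1", "NH2"))
  gj <- which(a$chainId == "B" & a$resSeq == 1 & a$name %in% c("OE1", "OE2"))
  brute <- min(as.matrix(dist(rbind(x[gi, ], x[gj, ])))[
    seq_along(gi), length(gi) + seq_along(gj)])
  expect_equal(gm, brute, tolerance = 1e-12)
  expect_lte(gm, representativeDistance(m, "A:1", "B:1") + 1.33 + 1.25)
  toy2 <- makeToyComplex(4, 4, list(
    list(basic = "LYS", acidic = "ASP", distance = 3),
    list(basic = "ARG", acidic = "GLU", distance = 3)))
  expect_error(groupMinDistance(toy2$model, "A:1", "A:2"), "both basic")
})

test_that("distances are invariant under global rigid motion", {
  m <- makeReferenceInterface()
  set.seed(42)
  for (i in 1:5) {
    m2 <- rigidMove(m, randomRotation(), rnorm(3, 0, 20))
    expect_equal(representativeDistance(m2, "I:52", "H:54"),
                 representativeDistance(m, "I:52", "H:54"), tolerance = 1e-9)
    expect_equal(groupMinDistance(m2, "I:84", "I:45"),
                 groupMinDistance(m, "I:84", "I:45"), tolerance = 1e-9)
  }
})

test_that("findSaltBridges matches an exhaustive pairwise scan", {
  toy <- makeToyComplex(6, 6, list(
    list(basic = "LYS", acidic = "ASP", distance = 3.0),
    list(basic = "ARG", acidic = "GLU", distance = 3.5)), decoys = 4)
  m <- toy$model
  found <- findSaltBridges(m, "A", "B", cutoff = 4.5)
  # brute force: every basic-acidic residue pair across the chains
  a <- atomTable(m)
  spec <- chargedGroups()
  resOf <- function(ch) {
    rows <- which(a$chainId == ch & a$resName %in% names(spec))
    unique(paste0(ch, ":", a$resSeq[rows]))
  }
  brute <- 0L
  for (ra in resOf("A")) for (rb in resOf("B")) {
    rna <- a$resName[match(TRUE, a$chainId == "A" &
                           a$resSeq == as.integer(sub(".*:", "", ra)))]
    rnb <- a$resName[match(TRUE, a$chainId == "B" &
                           a$resSeq == as.integer(sub(".*:", "", rb)))]
    if (spec[[rna]]$polarity == spec[[rnb]]$polarity) next
    if (groupMinDistance(m, ra, rb) <= 4.5) brute <- brute + 1L
  }
  expect_equal(nrow(found), brute)
  expect_equal(nrow(found), 2L)          # exactly the planted pairs
  expect_false(is.unsorted(found$group_min_A))
  # tight cutoff excludes everything
  expect_equal(nrow(findSaltBridges(m, "A", "B", cutoff = 2.0)), 0L)
  expect_error(findSaltBridges(m, character(), "B"), "empty chain")
  expect_error(findSaltBridges(m, "A", "A"), "disjoint")
})

test_that("caMask drops terminal residues per chain and errors on short chains", {
  toy <- makeToyComplex(20, 12)
  m <- toy$model
  mask <- caMask(m, "A", terminalExclude = 5)
  expect_length(mask, 10)
  expect_equal(atomTable(m)$resSeq[mask], 6:15)
  expect_length(caMask(m, "A", terminalExclude = 0), 20)
  both <- caMask(m, c("A", "B"), terminalExclude = 5)
  expect_length(both, 10 + 2)
  expect_error(caMask(m, "B", terminalExclude = 6), "too short")
})

test_that("the synthetic interface reference reproduces its planted crystal geometry", {
  m <- makeReferenceInterface()
  expect_equal(representativeDistance(m, "I:52", "H:54"), 3.6, tolerance = 1e-9)
  expect_equal(representativeDistance(m, "I:52", "H:56"), 3.5, tolerance = 1e-9)
  expect_equal(representativeDistance(m, "I:84", "I:45"), 4.3, tolerance = 1e-9)
  expect_equal(representativeDistance(m, "L:27", "I:98"), 8.0, tolerance = 1e-9)
  expect_equal(groupMinDistance(m, "I:84", "I:45"), 2.9, tolerance = 1e-9)
  expect_equal(groupMinDistance(m, "I:52", "H:54"), 2.8, tolerance = 1e-9)
  expect_equal(groupMinDistance(m, "I:84", "L:27"), 3.7, tolerance = 1e-9)
  expect_equal(groupMinDistance(m, "I:98", "L:28"), 4.3, tolerance = 1e-9)
})
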