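# In-silico digestion, peptide masses against an independent oracle,
# inverted-index queries vs. linear scans, and hyperscore ranking.

test_that("tryptic digestion of a small protein matches hand enumeration", {
  # MKPEPTIDERAK: K2 blocked by P3, cleave after R10; K12 is the C-terminus
  d <- digestProtein("MKPEPTIDERAK", missedCleavages = 1)
  expect_setequal(as.character(d), c("MKPEPTIDER", "AK", "MKPEPTIDERAK"))
  d0 <- digestProtein("MKPEPTIDERAK", missedCleavages = 0)
  expect_setequal(as.character(d0), c("MKPEPTIDER", "AK"))
})

test_that("precursor m/z agrees with an independent mass calculator", {
  # expected values frozen from pyteomics mass.calculate_mass
  expect_equal(peptideMz("PEPTIDEK", 2), 464.734740, tolerance = 1e-4)
  expect_equal(peptideMz("SAMPLER", 1), 803.408000, tolerance = 1e-4)
  expect_equal(peptideMz("MKPEPTIDER", 2), 608.305538, tolerance = 1e-4)
  expect_equal(peptideMz("LVNELTEFAK", 2), 582.318971, tolerance = 1e-4)
  expect_equal(peptideMz("ACDEFGHIK", 2, modMass = 57.021464),
               538.745116, tolerance = 1e-4)
  expect_true(is.na(peptideMass("PEPTIDEX")))
})

test_that("b/y fragment ladders agree with the frozen ion oracle", {
  fr <- fragmentIons("PEPTIDEK")
  b <- fr$mz[fr$type == "b"][order(fr$pos[fr$type == "b"])]
  y <- fr$mz[fr$type == "y"][order(fr$pos[fr$type == "y"])]
  expect_equal(b[1:3], c(98.06004, 227.10263, 324.15540), tolerance = 1e-4)
  expect_equal(y[1:3], c(147.11280, 276.15540, 391.18234), tolerance = 1e-4)
  expect_length(fr$mz, 14L)  # 7 b + 7 y
  expect_true(all(diff(fr$mz) >= 0))
})

test_that("peptide masses are additive across concatenation", {
  # mass(AB) = mass(A) + mass(B) - water, for random peptides
  set.seed(14)
  res <- names(DIAdeconv:::.RESIDUE_MASS)
  water <- 18.0105646863
  for (i in 1:50) {
    a <- paste(sample(res, sample(3:10, 1), TRUE), collapse = "")
    b <- paste(sample(res, sample(3:10, 1), TRUE), collapse = "")
    expect_equal(peptideMass(paste0(a, b)),
                 peptideMass(a) + peptideMass(b) - water,
                 tolerance = 1e-9)
  }
  # fragment ladders are consistent with the precursor mass:
  # b_i + y_(n-i) = M + water + 2 * proton
  for (i in 1:20) {
    s <- paste(sample(res, 9, TRUE), collapse = "")
    fr <- fragmentIons(s)
    M <- peptideMass(s)
    b <- fr[fr$type == "b", ]; y <- fr[fr$type == "y", ]
    for (p in 1:8) {
      expect_equal(b$mz[b$pos == p] + y$mz[y$pos == 9 - p],
                   M + 2 * 1.00727646688, tolerance = 1e-9)
    }
  }
})

test_that("digesting an empty database yields an empty entry list", {
  expect_equal(nrow(digestFasta(character())), 0L)
})

test_that("digestion enumerates modifications and charges deterministically", {
  e1 <- digestFasta(c(p = "MKPEPTIDERAKLVNELTEFAK"), charges = 2:3)
  e2 <- digestFasta(c(p = "MKPEPTIDERAKLVNELTEFAK"), charges = 2:3)
  expect_identical(e1, e2)
  expect_true(all(c("", "Oxidation@M1", "Acetyl@Nterm") %in%
                    e1$mods[e1$sequence == "MKPEPTIDER"]))
  # precursor invariant: (M + z * proton) / z
  for (i in seq_len(nrow(e1))) {
    z <- e1$charge[i]
    mass <- e1$precursorMz[i] * z - z * 1.00727646688
    expect_gt(mass, 0)
  }
  # fragment lists are nonempty and sorted
  expect_true(all(vapply(e1$fragMz, length, integer(1)) > 0))
  expect_true(all(vapply(e1$fragMz, function(x)
    all(diff(x) >= 0), logical(1))))
})

test_that("the inverted tables cover every entry and rebuild exactly", {
  e <- digestFasta(randomProteins(4, seed = 17), charges = 2)
  idx <- buildInvertedIndex(e)
  # one entry with >= 3 fragments: its fragment bins all map back to it
  k <- e$index[1]
  bins <- unique(floor(e$fragMz[[1]] * 30))
  for (b in bins[1:3])
    expect_true(k %in% idx@fragmentTable[[as.character(b)]])
  # brute-force table reconstruction
  for (b in sample(ls(idx@fragmentTable), 25)) {
    binLo <- as.numeric(b) / 30
    oracle <- e$index[vapply(e$fragMz, function(f)
      any(floor(f * 30) %in% (as.numeric(b) + (-1:1))), logical(1))]
    expect_setequal(idx@fragmentTable[[b]], oracle)
  }
})

test_that("two peptides sharing a fragment m/z share the bin's index set", {
  e <- digestFasta(c(a = "AAAPEPTIDEKGGGR", b = "VVVPEPTIDEKSSSR"),
                   charges = 2, variableMods = FALSE)
  idx <- buildInvertedIndex(e)
  # y ions of the shared PEPTIDEK... suffix coincide
  shared <- intersect(round(e$fragMz[[1]], 4), round(e$fragMz[[2]], 4))
  expect_gt(length(shared), 0)
  got <- queryFragment(idx, shared[1])
  expect_true(all(e$index[1:2] %in% got))
})

test_that("inverted queries equal linear scans on a random digest", {
  e <- digestFasta(randomProteins(6, seed = 23), charges = 2:3)
  idx <- buildInvertedIndex(e)
  set.seed(99)
  # precursor queries: exact hits, misses, and random m/z
  probes <- rbind(
    data.frame(mz = e$precursorMz[sample(nrow(e), 40)],
               z = e$charge[sample(nrow(e), 40)]),
    data.frame(mz = runif(60, 300, 1200), z = sample(2:3, 60, TRUE)))
  for (i in seq_len(nrow(probes))) {
    mz <- probes$mz[i]; z <- probes$z[i]
    tol <- 20e-6 * mz
    oracle <- sort(e$index[abs(e$precursorMz - mz) <= tol & e$charge == z])
    expect_equal(queryPrecursor(idx, mz, z), oracle)
  }
  # an entry's exact precursor is found; +1 Th is not
  expect_true(e$index[5] %in%
                queryPrecursor(idx, e$precursorMz[5], e$charge[5]))
  expect_false(e$index[5] %in%
                 queryPrecursor(idx, e$precursorMz[5] + 1, e$charge[5]))
  # fragment queries vs. linear scan
  fmz <- c(vapply(sample(nrow(e), 40), function(i)
    sample(e$fragMz[[i]], 1), numeric(1)), runif(60, 150, 1500))
  for (mz in fmz) {
    oracle <- sort(e$index[vapply(e$fragMz, function(f)
      min(abs(f - mz)) <= 0.03, logical(1))])
    expect_equal(queryFragment(idx, mz), oracle)
  }
  expect_length(queryFragment(idx, 9999), 0L)
})

test_that("hyperscore follows the X!Tandem form", {
  expect_equal(hyperscore(c(60, 40), 2, 2), log10(2 * 2 * 100),
               tolerance = 1e-12)
  expect_equal(hyperscore(numeric(), 0, 0), 0)
  # adding a matched ion never lowers the score
  set.seed(6)
  for (i in 1:20) {
    ints <- rlnorm(5, 3, 1)
    nb <- sample(0:3, 1); ny <- 5 - nb
    base <- hyperscore(ints, nb, ny)
    expect_gte(hyperscore(c(ints, rlnorm(1, 3, 1)), nb + 1, ny), base)
  }
})

test_that("cluster matching ranks the true peptide first", {
  set.seed(41)
  e <- digestFasta(c(a = "GGGLVNELTEFAKDDDR", b = "SSSFEQLHSTVKPPPR"),
                   charges = 2, variableMods = FALSE)
  idx <- buildInvertedIndex(e)
  target <- e[e$sequence == "GGGLVNELTEFAK", ]
  frags <- lapply(sample(target$fragMz[[1]], 6), function(m)
    list(mz = m, xic = c(rep(0, 5), 1, 5, 20, 5, 1, rep(0, 10)) * 50))
  prec <- list(mz = target$precursorMz, charge = 2L)
  m <- matchCluster(idx, prec, frags)
  expect_gt(nrow(m), 0)
  expect_equal(m$sequence[1], "GGGLVNELTEFAK")
  expect_equal(m$Nb[1] + m$Ny[1], length(m$matchedFrag[[1]]))
  # ranking equals brute-force scoring over every digest entry
  apex <- vapply(frags, function(f) max(f$xic), numeric(1))
  bf <- vapply(seq_len(nrow(e)), function(i) {
    if (abs(e$precursorMz[i] - prec$mz) > 20e-6 * prec$mz) return(-1)
    theo <- e$fragMz[[i]]; type <- e$fragType[[i]]
    nearest <- vapply(vapply(frags, `[[`, numeric(1), "mz"), function(mm) {
      d <- abs(theo - mm); j <- which.min(d)
      if (d[j] <= 0.03) j else NA_integer_
    }, integer(1))
    ok <- which(!is.na(nearest))
    if (!length(ok)) return(-1)
    keep <- ok[!duplicated(nearest[ok])]
    hyperscore(apex[keep], sum(type[nearest[keep]] == "b"),
               sum(type[nearest[keep]] == "y"))
  }, numeric(1))
  expect_equal(m$index[1], e$index[which.max(bf)])
  expect_equal(m$hyperscore[1], max(bf), tolerance = 1e-10)
  # a precursor matching nothing gives an empty result
  m0 <- matchCluster(idx, list(mz = 1111.111, charge = 2L), frags)
  expect_equal(nrow(m0), 0L)
})
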