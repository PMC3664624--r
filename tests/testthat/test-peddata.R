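test_that("PED parsing maps fields, codes and missing genotypes", {
    d <- withr::local_tempdir()
    writeLines("1 s1 10.0 51197000", file.path(d, "a.map"))
    writeLines(c("F1 P1 0 0 1 2 1 2",
                 "F1 P2 0 0 2 1 0 0"), file.path(d, "a.ped"))
    gt <- readPed(file.path(d, "a.ped"), file.path(d, "a.map"))
    p <- pedTable(pedigree(gt))
    expect_identical(p$id, c("P1", "P2"))
    expect_true(all(is.na(p$father)))
    expect_identical(p$sex, c(1L, 2L))
    expect_identical(p$affection, c(2L, 1L))        # 2 = affected
    g <- genoMatrix(gt)
    expect_identical(g[1, "F1:P1"], 1L)             # het {1,2}
    expect_true(is.na(g[1, "F1:P2"]))               # 0 0 -> missing
    expect_equal(unname(callRates(gt)), 0.5)
})

test_that("base-letter alleles are recoded lexically and errors are raised", {
    d <- withr::local_tempdir()
    writeLines(c("1 s1 1.0 100", "1 s2 2.0 200"), file.path(d, "b.map"))
    writeLines(c("F1 P1 0 0 1 2 A C G G",
                 "F1 P2 0 0 2 1 C C 0 0"), file.path(d, "b.ped"))
    gt <- readPed(file.path(d, "b.ped"), file.path(d, "b.map"))
    g <- genoMatrix(gt)
    expect_identical(g["s1", "F1:P1"], 1L)  # A/C -> 1/2
    expect_identical(g["s1", "F1:P2"], 2L)  # C/C -> 2/2
    expect_identical(g["s2", "F1:P1"], 0L)  # G is the only allele -> 1/1
    # odd allele columns
    writeLines("F1 P1 0 0 1 2 1", file.path(d, "c.ped"))
    expect_error(readPed(file.path(d, "c.ped"), file.path(d, "b.map")),
                 "even number")
    # unknown sex code
    writeLines(c("F1 P1 0 0 3 2 1 2 1 1"), file.path(d, "d.ped"))
    expect_error(readPed(file.path(d, "d.ped"), file.path(d, "b.map")), "sex")
})

test_that("MAP reading sorts by position, rejects missing cM, is order-invariant", {
    d <- withr::local_tempdir()
    writeLines(c("18 s2 10.5 51500000",
                 "18 s1 10.0 51197000",
                 "18 s3 NA 51800000"), file.path(d, "a.map"))
    m <- readMap(file.path(d, "a.map"))
    expect_identical(mapTable(m)$marker, c("s1", "s2"))
    expect_identical(m@rejected$marker, "s3")
    expect_identical(m@rejected$reason, "no_position")
    writeLines(c("18 s1 10.0 51197000", "18 s2 10.5 51500000"),
               file.path(d, "b.map"))
    expect_identical(mapTable(readMap(file.path(d, "b.map"))), mapTable(m))
    # non-monotone genetic positions are a hard error, naming the pair
    writeLines(c("18 s1 12.0 51197000", "18 s2 10.5 51500000"),
               file.path(d, "c.map"))
    expect_error(readMap(file.path(d, "c.map")), "s1.*s2")
})

test_that("write/read round-trips a full synthetic study bit-identically", {
    set.seed(1)
    for (seed in c(11L, 12L)) {
        sim <- simulateStudy(studyConfig(seed = seed, missingRate = 0.05))
        d <- withr::local_tempdir()
        writePed(sim$gt, file.path(d, "s.ped"))
        writeMap(sim$gt, file.path(d, "s.map"))
        gt2 <- readPed(file.path(d, "s.ped"), file.path(d, "s.map"))
        expect_identical(genoMatrix(sim$gt), genoMatrix(gt2))
        expect_identical(pedTable(pedigree(sim$gt))[, 1:6],
                         pedTable(pedigree(gt2)))
        expect_identical(mapTable(markerMap(sim$gt)), mapTable(markerMap(gt2)))
        writePed(gt2, file.path(d, "s2.ped"))
        expect_identical(readLines(file.path(d, "s.ped")),
                         readLines(file.path(d, "s2.ped")))
    }
})

test_that("founders and meioses partition each family", {
    sim <- simulateStudy(studyConfig(seed = 3))
    ped <- pedigree(sim$gt)
    p <- pedTable(ped)
    fo <- founders(ped)
    counts <- meiosisCount(ped)
    for (fam in familyNames(ped)) {
        inFam <- p$family == fam
        expect_equal(sum(fo[inFam]) + sum(!fo[inFam]), sum(inFam))
        expect_equal(unname(counts[fam]), 2L * sum(!fo[inFam]))
    }
})

test_that("structural validation reports cycles, sex conflicts and orphans", {
    # individual its own ancestor
    bad <- data.frame(family = "F", id = c("1", "2", "3"),
                      father = c("3", NA, "1"), mother = c("2", NA, "2"),
                      sex = c(1L, 2L, 1L), affection = 0L)
    rep <- validatePedigrees(bad)
    expect_true(any(rep$issue == "cycle"))
    # father id referencing a female
    bad2 <- data.frame(family = "F", id = c("1", "2", "3"),
                       father = c(NA, NA, "2"), mother = c(NA, NA, "1"),
                       sex = c(1L, 2L, 1L), affection = 0L)
    rep2 <- validatePedigrees(bad2)
    expect_true(any(rep2$issue == "father_is_female"))
    expect_true(any(rep2$issue == "mother_is_male"))
    # one-parent individual
    bad3 <- data.frame(family = "F", id = c("1", "2"),
                       father = c(NA, "1"), mother = c(NA, NA),
                       sex = c(1L, 2L), affection = 0L)
    expect_true(any(validatePedigrees(bad3)$issue == "one_parent"))
    # generator output is clean, including the 13-member template
    sim <- simulateStudy(studyConfig(seed = 8))
    expect_identical(nrow(validatePedigrees(pedigree(sim$gt))), 0L)
})
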