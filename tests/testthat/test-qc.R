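test_that("genotype elimination handles the canonical hand cases", {
    ped <- PedigreeSet(data.frame(
        family = "F", id = c("1", "2", "3"),
        father = c(NA, NA, "1"), mother = c(NA, NA, "2"),
        sex = c(1L, 2L, 1L), affection = 1L))
    # parents 1/1 x 1/1, child 1/2 -> incompatible
    r <- genotypeElimination(ped, c(0L, 0L, 1L))
    expect_true(r$incompatible)
    expect_true(all(lengths(r$sets) == 0L))
    # all missing -> every genotype possible
    r2 <- genotypeElimination(ped, c(NA, NA, NA))
    expect_false(r2$incompatible)
    expect_true(all(vapply(r2$sets, identical, logical(1), c(0L, 1L, 2L))))
    # father 1/2, mother missing, children 1/1 and 2/2 -> mother must be 1/2
    ped2 <- PedigreeSet(data.frame(
        family = "F", id = c("1", "2", "3", "4"),
        father = c(NA, NA, "1", "1"), mother = c(NA, NA, "2", "2"),
        sex = c(1L, 2L, 1L, 2L), affection = 1L))
    r3 <- genotypeElimination(ped2, c(1L, NA, 0L, 2L))
    expect_false(r3$incompatible)
    expect_identical(r3$sets[["2"]], 1L)
})

test_that("genotype elimination equals exhaustive enumeration (loop-free)", {
    set.seed(19)
    for (it in 1:30) {
        ped <- randomPedigree(sample(4:8, 1))
        st <- modlink:::.famStruct(ped, "F")
        geno <- sample(c(NA, 0:2), st$n, replace = TRUE)
        a <- genotypeElimination(st, geno)
        b <- bruteGenotypeSets(st, geno)
        expect_identical(lapply(a$sets, as.integer), b$sets)
        expect_identical(a$incompatible, b$incompatible)
    }
})

test_that("mendelCheck clears incompatible family x marker data and no more", {
    sim <- simulateStudy(studyConfig(seed = 41))
    clean <- mendelCheck(sim$gt)
    expect_identical(nrow(clean$errors), 0L)
    inj <- injectErrors(sim$gt, sim$truth, nMendel = 20L, seed = 5)
    mc <- mendelCheck(inj$gt)
    evTruth <- unique(paste(inj$truth$errors$family, inj$truth$errors$marker))
    evFound <- paste(mc$errors$family, mc$errors$marker)
    expect_true(all(evFound %in% evTruth))       # no false events
    expect_gte(sum(evTruth %in% evFound), 19L)   # essentially all detected
    # cleared family x marker cells are gone
    for (k in seq_len(nrow(mc$errors))) {
        fam <- mc$errors$family[k]
        keys <- paste(fam, pedTable(pedigree(sim$gt))$id[
            pedTable(pedigree(sim$gt))$family == fam], sep = ":")
        expect_true(all(is.na(genoMatrix(mc$gt)[mc$errors$marker[k], keys])))
    }
})

test_that("marker filters assign one primary reason each and are idempotent", {
    ped <- do.call(rbind, lapply(1:24, function(k)
        data.frame(family = paste0("F", k), id = c("1", "2"),
                   father = NA_character_, mother = NA_character_,
                   sex = c(1L, 2L), affection = 0L)))
    n <- 48
    g <- rbind(
        lowcall = c(rep(0L, 45), rep(NA_integer_, 3)),   # 45/48 = 0.9375
        mono    = rep(0L, n),
        fine    = rep(c(0L, 1L, 2L), 16))
    gt <- handGT(ped, g, freq = NA_real_)
    fl <- filterMarkers(gt, minCallRate = 0.95)
    expect_identical(fl$removed$reason[fl$removed$marker == "lowcall"], "call_rate")
    expect_identical(fl$removed$reason[fl$removed$marker == "mono"], "monomorphic")
    expect_equal(fl$survivingFraction, 1 / 3)
    expect_false(anyDuplicated(fl$removed$marker) > 0)
    again <- filterMarkers(fl$gt, minCallRate = 0.95)
    expect_identical(nrow(again$removed), 0L)
    expect_equal(again$survivingFraction, 1)
})

test_that("a constructed 1000-marker set with 60 failures survives at 0.94", {
    ped <- do.call(rbind, lapply(1:10, function(k)
        data.frame(family = paste0("F", k), id = c("1", "2"),
                   father = NA_character_, mother = NA_character_,
                   sex = c(1L, 2L), affection = 0L)))
    set.seed(4)
    g <- matrix(sample(0:2, 1000 * 20, replace = TRUE), 1000, 20)
    g[1:30, ] <- 0L                                   # monomorphic
    g[31:60, sample(20, 2)] <- NA_integer_            # call rate 18/20 = 0.9
    rownames(g) <- sprintf("m%04d", 1:1000)
    gt <- handGT(ped, g, freq = NA_real_)
    fl <- filterMarkers(gt, minCallRate = 0.95)
    expect_equal(fl$survivingFraction, 0.94)
})

test_that("founder allele frequencies are counted correctly with fallback", {
    ped <- data.frame(family = "F", id = c("1", "2", "3"),
                      father = c(NA, NA, "1"), mother = c(NA, NA, "2"),
                      sex = c(1L, 2L, 1L), affection = 1L)
    g <- rbind(m1 = c(1L, 0L, 1L),    # founders carry 3 of 4 allele 1
               m2 = c(NA, NA, 1L))    # no typed founder
    expect_warning(gt <- estimateAlleleFreqs(handGT(ped, g, freq = NA_real_)),
                   "no typed founder")
    f <- alleleFreqs(gt)
    expect_equal(unname(f["m1"]), 0.75)
    expect_equal(unname(f["m2"]), 0.5)   # fallback: the child's genotype
    # estimation accuracy under founder missingness
    set.seed(9)
    nF <- 200
    truth <- 0.3
    gf <- matrix(rbinom(500 * 2 * nF, 1L, 1 - truth), 500)  # allele-2 draws
    geno <- gf[, seq(1, 2 * nF, 2)] + gf[, seq(2, 2 * nF, 2)]
    geno[matrix(runif(length(geno)) < 0.3, nrow(geno))] <- NA_integer_
    est <- 1 - rowSums(geno, na.rm = TRUE) / (2 * rowSums(!is.na(geno)))
    expect_lt(abs(mean(est) - truth), 0.03)
})

test_that("estimated frequencies are local likelihood maxima", {
    set.seed(10)
    sim <- simulateStudy(studyConfig(seed = 10))
    gt <- estimateAlleleFreqs(filterMarkers(sim$gt)$gt)
    fo <- founders(pedigree(gt))
    g <- genoMatrix(gt)[, fo, drop = FALSE]
    ll <- function(p, x) {
        x <- x[!is.na(x)]
        sum(x == 0L) * 2 * log(p) + sum(x == 1L) * log(2 * p * (1 - p)) +
            sum(x == 2L) * 2 * log(1 - p)
    }
    picks <- sample(nrow(g), 20)
    for (m in picks) {
        p <- alleleFreqs(gt)[m]
        if (is.na(p) || p < 0.02 || p > 0.98) next
        expect_gte(ll(p, g[m, ]), ll(p - 0.01, g[m, ]))
        expect_gte(ll(p, g[m, ]), ll(p + 0.01, g[m, ]))
    }
})

test_that("sex consistency check flags heterozygous males, skips untestable", {
    nInd <- 6
    ped <- data.frame(family = "F", id = as.character(1:nInd),
                      father = NA_character_, mother = NA_character_,
                      sex = c(1L, 1L, 2L, 2L, 1L, 1L), affection = 0L)
    set.seed(11)
    M <- 80
    p <- runif(M, 0.3, 0.7)
    hemi <- matrix(rbinom(M * nInd, 1L, 1 - p) * 2L, M)   # hemizygous-style
    dip <- matrix(rbinom(M * nInd, 1L, 1 - p) +
                  rbinom(M * nInd, 1L, 1 - p), M)
    g <- hemi
    g[, 3] <- dip[, 3]; g[, 4] <- dip[, 4]   # true females
    g[, 5] <- dip[, 5]                       # declared male, female-like X
    g[, 6] <- NA_integer_                    # untyped
    rownames(g) <- sprintf("x%d", 1:M)
    map <- MarkerMap(data.frame(chrom = "X", marker = rownames(g),
                                cm = seq_len(M), bp = seq_len(M)))
    colnames(g) <- paste("F", ped$id, sep = ":")
    gt <- GenotypeTable(g, PedigreeSet(ped), map)
    res <- sexConsistencyCheck(gt, minMarkers = 50L)
    expect_false(res$flagged[1])                     # clean male
    expect_true(res$flagged[5])                      # het male flagged
    expect_false(any(res$flagged[3:4]))              # true females pass
    expect_true(res$untestable[6])
    expect_false(res$flagged[6])
    # no X markers: skipped with a warning
    rowData(gt)$chrom <- "1"
    expect_warning(out <- sexConsistencyCheck(gt), "skipped")
    expect_identical(nrow(out), 0L)
})

test_that("IBS check flags duplicates and substituted individuals", {
    cfg <- studyConfig(nFamilies = 1L, nTrios = 0L, nMarkers = 400L,
                       spacingCm = 0.5, traitPosCm = NA, missingRate = 0.01,
                       seed = 61)
    sim <- simulateStudy(cfg)
    gt <- estimateAlleleFreqs(filterMarkers(sim$gt)$gt)
    g <- genoMatrix(gt)
    # duplicate sample claimed as sibs
    g2 <- g; g2[, "F1:4"] <- g2[, "F1:3"]
    SummarizedExperiment::assay(gt, "geno") <- g2
    rep <- ibsRelationshipCheck(gt, seed = 1)
    dup <- rep[rep$id1 == "3" & rep$id2 == "4", ]
    expect_true(dup$flagged)
    expect_identical(dup$assigned, "duplicate")
    # parent-offspring pairs share an allele at every fully typed marker
    po <- rep[rep$claimed == "parent-offspring" & !rep$untestable, ]
    expect_true(all(po$ibs0[!po$flagged] <= 0.005))
    # substituted unrelated individual
    g3 <- g
    set.seed(2)
    g3[, "F1:3"] <- rbinom(nrow(g), 2L, 1 - alleleFreqs(gt))
    SummarizedExperiment::assay(gt, "geno") <- g3
    rep3 <- ibsRelationshipCheck(gt, seed = 1)
    hit <- rep3$id1 == "3" | rep3$id2 == "3"
    expect_true(all(rep3$flagged[hit]))
    expect_false(any(rep3$flagged[!hit]))
    # too few markers -> untestable, not flagged
    rep4 <- ibsRelationshipCheck(gt[1:50, ], seed = 1)
    expect_true(all(rep4$untestable))
    expect_false(any(rep4$flagged))
})

test_that("wiped unlikely genotypes do not re-flag (fixpoint)", {
    cfg <- studyConfig(nTrios = 0L, nMarkers = 40L, spacingCm = 0.05,
                       mafRange = c(0.3, 0.5), traitPosCm = NA,
                       missingRate = 0, seed = 62)
    sim <- simulateStudy(cfg)
    gt <- estimateAlleleFreqs(filterMarkers(sim$gt)$gt)
    inj <- suppressWarnings(injectErrors(gt, sim$truth, nFlips = 4L, seed = 3))
    fams <- unique(inj$truth$errors$family)
    fl <- detectUnlikelyGenotypes(inj$gt, threshold = 4, families = fams)
    if (nrow(fl)) {
        gt2 <- wipeGenotypes(inj$gt, fl)
        fl2 <- detectUnlikelyGenotypes(gt2, threshold = 4, families = fams)
        expect_false(any(paste(fl2$family, fl2$id, fl2$marker) %in%
                         paste(fl$family, fl$id, fl$marker)))
    }
    succeed()
})
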