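test_that("the generator is bit-reproducible and matches the design", {
    a <- simulateStudy(studyConfig(seed = 121))
    b <- simulateStudy(studyConfig(seed = 121))
    expect_identical(genoMatrix(a$gt), genoMatrix(b$gt))
    expect_identical(pedTable(pedigree(a$gt)), pedTable(pedigree(b$gt)))
    p <- pedTable(pedigree(a$gt))
    fams <- p[p$role == "family", ]
    trios <- p[p$role == "trio", ]
    expect_identical(length(unique(fams$family)), 6L)
    expect_identical(nrow(fams), 48L)                      # 6 families
    expect_identical(length(unique(trios$family)), 7L)
    expect_true(all(range(table(fams$family)) == c(4L, 13L)))
    # every family is multiplex, every trio child affected
    expect_true(all(tapply(fams$affection == 2L, fams$family, sum) >= 2))
    kids <- trios[!is.na(trios$father), ]
    expect_true(all(kids$affection == 2L))
})

test_that("full penetrance means every affected carries two disease alleles", {
    sim <- simulateStudy(studyConfig(
        model = traitModel(q = 0.1, f0 = 0, f1 = 0, f2 = 1), seed = 122))
    p <- pedTable(pedigree(sim$gt))
    tg <- sim$truth$traitGeno
    aff <- merge(p[p$affection == 2L, c("family", "id")], tg)
    expect_true(all(aff$patD == 1L & aff$matD == 1L))
})

test_that("an unlinked flat-penetrance trait is independent of the markers", {
    cfg <- studyConfig(nFamilies = 60L, nTrios = 0L, nMarkers = 4L,
                       traitPosCm = NA, missingRate = 0,
                       model = traitModel(q = 0.2, f0 = 0.3, f1 = 0.3, f2 = 0.3),
                       ascertainMinAffected = 0L, seed = 123)
    sim <- simulateStudy(cfg)
    aff <- pedTable(pedigree(sim$gt))$affection
    g <- genoMatrix(sim$gt)
    for (m in 1:2) {
        tab <- table(aff, g[m, ])
        expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 0.001)
    }
})

test_that("familial aggregation: sib recurrence exceeds prevalence", {
    set.seed(124)
    cfg <- studyConfig(nFamilies = 800L, nTrios = 0L, nMarkers = 1L,
                       traitPosCm = NA, ascertainMinAffected = 0L, seed = 124)
    sim <- simulateStudy(cfg)
    p <- pedTable(pedigree(sim$gt))
    kids <- p[!is.na(p$father), ]
    prev <- mean(p$affection == 2L)
    sibAff <- c()
    for (fam in unique(kids$family)) {
        q <- kids[kids$family == fam, ]
        cp <- paste(q$father, q$mother)
        for (cc in unique(cp)) {
            s <- q[cp == cc, ]
            i <- which(s$affection == 2L)[1]
            if (nrow(s) >= 2 && !is.na(i))
                sibAff <- c(sibAff, s$affection[-i] == 2L)
        }
    }
    expect_gt(mean(sibAff), prev)
})

test_that("the weak-penetrance stress scenario still ascertains", {
    cfg <- studyConfig(nFamilies = 2L, nTrios = 1L, nMarkers = 5L,
                       model = traitModel(q = 0.1, f0 = 0, f1 = 0, f2 = 0.27),
                       seed = 129)
    sim <- simulateStudy(cfg)
    p <- pedTable(pedigree(sim$gt))
    fams <- p[p$role == "family", ]
    expect_true(all(tapply(fams$affection == 2L, fams$family, sum) >= 2))
    # incomplete penetrance: affected individuals still carry two copies
    tg <- merge(fams[fams$affection == 2L, c("family", "id")],
                sim$truth$traitGeno)
    expect_true(all(tg$patD == 1L & tg$matD == 1L))
})

test_that("clean generated data carry no Mendelian inconsistencies", {
    for (s in c(125L, 126L)) {
        sim <- simulateStudy(studyConfig(seed = s))
        expect_identical(nrow(mendelCheck(sim$gt)$errors), 0L)
    }
})

test_that("error injection is registered exactly and detected downstream", {
    sim <- simulateStudy(studyConfig(seed = 127))
    # rate zero is the identity
    same <- injectErrors(sim$gt, sim$truth, nMendel = 0L, nFlips = 0L, seed = 1)
    expect_identical(genoMatrix(same$gt), genoMatrix(sim$gt))
    inj <- injectErrors(sim$gt, sim$truth, nMendel = 25L, seed = 2)
    reg <- inj$truth$errors
    expect_identical(nrow(reg), 25L)
    # the registry lists exactly the corrupted cells
    diffs <- which(genoMatrix(inj$gt) != genoMatrix(sim$gt), arr.ind = TRUE)
    expect_identical(nrow(diffs), 25L)
    cells <- paste(rownames(genoMatrix(sim$gt))[diffs[, 1]],
                   colnames(genoMatrix(sim$gt))[diffs[, 2]])
    expect_setequal(cells, paste(reg$marker, paste(reg$family, reg$id, sep = ":")))
    # detection
    mc <- mendelCheck(inj$gt)
    ev <- unique(paste(reg$family, reg$marker))
    expect_gte(sum(ev %in% paste(mc$errors$family, mc$errors$marker)),
               ceiling(0.95 * length(ev)))
})

test_that("injected double-recombinant flips are recalled by the screen", {
    key <- function(d) paste(d$family, d$id, d$marker)
    injected <- recalled <- 0
    for (s in 1:3) {
        cfg <- studyConfig(nTrios = 0L, nMarkers = 60L, spacingCm = 0.05,
                           mafRange = c(0.3, 0.5), traitPosCm = NA,
                           missingRate = 0, seed = 700 + s)
        sim <- simulateStudy(cfg)
        gt <- modlink:::.preparedMarkers(sim$gt)
        inj <- suppressWarnings(injectErrors(gt, sim$truth, nFlips = 10L,
                                             seed = s))
        fl <- inj$truth$errors[inj$truth$errors$kind == "flip", ]
        found <- detectUnlikelyGenotypes(inj$gt, threshold = 4,
                                         families = unique(fl$family))
        injected <- injected + nrow(fl)
        recalled <- recalled + sum(key(fl) %in% key(found))
    }
    expect_gte(injected, 6)
    expect_gte(recalled / injected, 0.8)
    # no false flags on clean data
    cfg <- studyConfig(nTrios = 0L, nMarkers = 40L, spacingCm = 0.1,
                       traitPosCm = NA, missingRate = 0, seed = 128)
    gt <- modlink:::.preparedMarkers(simulateStudy(cfg)$gt)
    clean <- detectUnlikelyGenotypes(gt, threshold = 4)
    expect_lt(nrow(clean) / sum(!is.na(genoMatrix(gt))), 0.01)
})
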