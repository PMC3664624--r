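test_that("map functions are monotone with the right limits", {
    d <- seq(0, 500, by = 0.5)
    for (fun in c("haldane", "kosambi")) {
        th <- mapTheta(d, fun)
        expect_equal(th[1], 0)
        expect_true(all(diff(th) > 0))
        expect_true(all(th < 0.5))
        expect_equal(mapTheta(1e6, fun), 0.5, tolerance = 1e-12)
    }
})

test_that("trio single-marker likelihood matches the closed form", {
    ped <- data.frame(family = "F", id = c("1", "2", "3"),
                      father = c(NA, NA, "1"), mother = c(NA, NA, "2"),
                      sex = c(1L, 2L, 1L), affection = c(1L, 1L, 2L))
    g <- matrix(c(1L, 0L, 0L), 1, 3, dimnames = list("m1", NULL))
    p <- 0.6
    gt <- handGT(ped, g, freq = p)
    # P(father 1/2) P(mother 1/1) P(child 1/1 | parents)
    expect_equal(unname(10^markerLikelihood(gt)), 2 * p * (1 - p) * p^2 * 0.5,
                 tolerance = 1e-12)
    expect_equal(bruteForceLikelihood(gt, "F"), 2 * p * (1 - p) * p^2 * 0.5,
                 tolerance = 1e-12)
})

test_that("all-missing data give likelihood 1 and a uniform posterior", {
    ped <- randomPedigree(6)
    set.seed(2)
    gt <- droppedGT(ped, cm = c(0, 5, 11), freq = c(0.3, 0.5, 0.7),
                    seed = 1, missing = 0)
    gm <- genoMatrix(gt)
    gm[] <- NA_integer_
    SummarizedExperiment::assay(gt, "geno") <- gm
    expect_equal(unname(markerLikelihood(gt)), 0, tolerance = 1e-12)
    post <- inheritancePosterior(gt, "F", positions = c(0, 2.5, 11))
    expect_equal(as.numeric(post),
                 rep(1 / ncol(post), length(post)), tolerance = 1e-12)
})

test_that("HMM equals exhaustive enumeration on random small families", {
    set.seed(71)
    for (it in 1:30) {
        n <- sample(3:6, 1)
        M <- sample(1:3, 1)
        ped <- randomPedigree(n)
        cm <- sort(stats::runif(M, 0, 20)); cm <- cm - cm[1]
        freq <- stats::runif(M, 0.15, 0.85)
        gt <- droppedGT(ped, cm, freq, seed = it)
        ph <- 10^unname(markerLikelihood(gt))
        pb <- bruteForceLikelihood(gt, "F")
        expect_lt(abs(ph - pb) / pb, 1e-10)
    }
})

test_that("trait LOD (with and without imprinting) equals the two-locus oracle", {
    set.seed(72)
    for (it in 1:12) {
        n <- sample(3:5, 1)
        M <- sample(1:2, 1)
        ped <- randomPedigree(n)
        cm <- sort(stats::runif(M, 0, 10)); cm <- cm - cm[1]
        freq <- stats::runif(M, 0.2, 0.8)
        gt <- droppedGT(ped, cm, freq, seed = 100 + it)
        model <- if (it %% 2 == 0) {
            f <- sort(stats::runif(3))
            traitModel(q = stats::runif(1, 0.05, 0.3), f0 = f[1], f1 = f[2],
                       f2 = f[3])
        } else {
            traitModel(q = 0.1, f0 = 0.05, f2 = 0.9, f1pat = 0.1, f1mat = 0.8)
        }
        pos <- stats::runif(1, 0, max(cm) + 5)
        tl <- traitLod(gt, model, positions = pos)
        expect_equal(unname(tl$total), bruteTraitLod(gt, "F", model, pos),
                     tolerance = 1e-9)
        expect_equal(unname(rowSums(tl$perFamily)), unname(tl$total))
    }
})

test_that("phase-known fully informative meioses give the textbook LOD", {
    # grandfather affected 2/2, grandmother unaffected 1/1 pin the phase of
    # their affected 1/2 child; 10 offspring meioses, no recombinants, a
    # fully penetrant dominant model, marker co-located with the trait:
    # every meiosis contributes log10(2)
    nk <- 10; k <- 4
    ids <- c("GF", "GM", "P", "S", paste0("C", 1:nk))
    ped <- data.frame(family = "F", id = ids,
                      father = c(NA, NA, "GF", NA, rep("P", nk)),
                      mother = c(NA, NA, "GM", NA, rep("S", nk)),
                      sex = c(1L, 2L, 1L, 2L, rep(c(1L, 2L), nk / 2)),
                      affection = c(2L, 1L, 2L, 1L, rep(2L, k), rep(1L, nk - k)))
    g <- matrix(c(2L, 0L, 1L, 0L, rep(1L, k), rep(0L, nk - k)), 1,
                dimnames = list("m1", NULL))
    gt <- handGT(ped, g, freq = 0.6)
    tl <- traitLod(gt, traitModel(q = 0.05, f0 = 0, f1 = 1, f2 = 1),
                   positions = 0)
    expect_equal(unname(tl$total), 10 * log10(2), tolerance = 1e-9)
})

test_that("a degenerate equal-penetrance model scores exactly zero", {
    set.seed(5)
    ped <- randomPedigree(6)
    gt <- droppedGT(ped, cm = c(0, 4), freq = c(0.4, 0.6), seed = 9)
    tl <- traitLod(gt, traitModel(q = 0.1, f0 = 0.5, f1 = 0.5, f2 = 0.5))
    expect_identical(unname(tl$total), rep(0, length(tl$positions)))
})

test_that("an untyped childless leaf never changes the marker likelihood", {
    set.seed(6)
    base <- data.frame(family = "F", id = c("1", "2", "3", "4"),
                       father = c(NA, NA, "1", "1"),
                       mother = c(NA, NA, "2", "2"),
                       sex = c(1L, 2L, 1L, 2L), affection = 1L)
    gt <- droppedGT(base, cm = c(0, 3, 8), freq = c(0.3, 0.6, 0.5),
                    seed = 21, missing = 0.1)
    withLeaf <- rbind(base, data.frame(family = "F", id = "5", father = "1",
                                       mother = "2", sex = 1L, affection = 1L))
    g2 <- rbind(t(genoMatrix(gt)), NA_integer_)
    rownames(g2) <- paste("F", withLeaf$id, sep = ":")
    gt2 <- handGT(withLeaf, t(g2), freq = alleleFreqs(gt), cm = c(0, 3, 8))
    expect_equal(unname(markerLikelihood(gt)), unname(markerLikelihood(gt2)),
                 tolerance = 1e-12)
})

test_that("the bit limit rejects oversized families and engine errors are clear", {
    big <- randomPedigree(20)
    set.seed(7)
    gt <- droppedGT(big, cm = 0, freq = 0.5, seed = 3, missing = 0)
    expect_error(markerLikelihood(gt, bitLimit = 4L), "exceeds limit")
    # Mendelian-inconsistent data are a hard error naming the marker
    ped <- data.frame(family = "F", id = c("1", "2", "3"),
                      father = c(NA, NA, "1"), mother = c(NA, NA, "2"),
                      sex = c(1L, 2L, 1L), affection = 1L)
    g <- matrix(c(0L, 0L, 2L), 1, dimnames = list("m1", NULL))
    expect_error(markerLikelihood(handGT(ped, g, freq = 0.5)),
                 "marker index 1")
})
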