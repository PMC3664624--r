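test_that("EM haplotype frequencies reproduce the hand-worked case", {
    # three founders: (1/1, 1/2), (1/1, 1/2), (2/2, 2/2); phase unambiguous
    em <- emHaplotypeFreqs(c(0L, 0L, 2L), c(1L, 1L, 2L))
    expect_equal(c(em$p11, em$p12, em$p21, em$p22),
                 c(1 / 3, 1 / 3, 0, 1 / 3), tolerance = 1e-12)
    expect_equal(em$D, 1 / 9, tolerance = 1e-12)
    expect_equal(em$r2, 0.25, tolerance = 1e-12)
    expect_true(all(abs(sum(c(em$p11, em$p12, em$p21, em$p22)) - 1) < 1e-12))
})

test_that("identical genotype columns (with double heterozygotes) give r2 = 1", {
    gA <- c(1L, 1L, 0L, 2L, 1L, 0L)
    em <- emHaplotypeFreqs(gA, gA)
    expect_equal(em$r2, 1, tolerance = 1e-8)
})

test_that("EM rejects degenerate inputs", {
    expect_error(emHaplotypeFreqs(c(0L, 0L, 0L), c(1L, 0L, 2L)), "monomorphic")
    expect_error(emHaplotypeFreqs(c(0L, NA), c(NA, 1L)), "insufficient")
})

test_that("EM log-likelihood is non-decreasing and matches a grid search", {
    gridR2 <- function(gA, gB) {
        n <- length(gA)
        tab <- table(factor(gA, 0:2), factor(gB, 0:2))
        pA <- (2 * sum(tab[1, ]) + sum(tab[2, ])) / (2 * n)
        pB <- (2 * sum(tab[, 1]) + sum(tab[, 2])) / (2 * n)
        best <- -Inf; bestp <- NA
        for (p11 in seq(max(0, pA + pB - 1), min(pA, pB), by = 1e-3)) {
            p <- pmax(c(p11, pA - p11, pB - p11, 1 - pA - pB + p11), 0)
            ll <- modlink:::.haploLogLik(p, tab)
            if (ll > best) { best <- ll; bestp <- p11 }
        }
        (bestp - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
    }
    set.seed(23)
    tested <- 0
    while (tested < 25) {
        n <- sample(20:60, 1)
        h1 <- rbinom(n, 1, .4); h2 <- ifelse(runif(n) < .7, h1, rbinom(n, 1, .5))
        h3 <- rbinom(n, 1, .4); h4 <- ifelse(runif(n) < .7, h3, rbinom(n, 1, .5))
        gA <- h1 + h3; gB <- h2 + h4
        em <- tryCatch(emHaplotypeFreqs(gA, gB), error = function(e) NULL)
        if (is.null(em)) next
        tested <- tested + 1
        expect_true(all(diff(em$logLikTrace) > -1e-9))
        expect_lt(abs(em$r2 - gridR2(gA, gB)), 5e-3)
    }
})

test_that("independent loci rarely exceed the pruning threshold", {
    set.seed(24)
    above <- 0
    for (i in 1:200) {
        gA <- rbinom(200, 2, .5); gB <- rbinom(200, 2, .5)
        em <- tryCatch(emHaplotypeFreqs(gA, gB), error = function(e) NULL)
        if (!is.null(em) && em$r2 > 0.2) above <- above + 1
    }
    expect_lte(above, 2)   # > 99 percent below threshold
})

test_that("pruning removes the later marker and the survivors verify clean", {
    # founders engineered so m1-m2 and m2-m3 are in strong LD but m1-m3 less
    set.seed(25)
    nf <- 40
    h1 <- rbinom(nf * 2, 1, 0.5)
    h2 <- ifelse(runif(nf * 2) < 0.9, h1, 1 - h1)
    h3 <- ifelse(runif(nf * 2) < 0.9, h2, 1 - h2)
    gen <- function(h) h[seq(1, nf * 2, 2)] + h[seq(2, nf * 2, 2)]
    ped <- data.frame(family = paste0("F", 1:nf), id = "1",
                      father = NA_character_, mother = NA_character_,
                      sex = 1L, affection = 0L)
    g <- rbind(m1 = gen(h1), m2 = gen(h2), m3 = gen(h3))
    gt <- handGT(ped, g, freq = NA_real_, cm = c(0, 1, 2))
    pr <- pruneByLD(gt, threshold = 0.2)
    expect_identical(pr$pairs$removed[1], "m2")   # later of the first pair
    expect_true(all(pr$pairs$removed %in% c("m2", "m3")))
    expect_identical(nrow(verifyPruning(pr$gt, threshold = 0.2)), 0L)
    # no pairs above threshold -> identity
    set.seed(26)
    g2 <- matrix(rbinom(3 * nf, 2, .5), 3, dimnames = list(c("a", "b", "c"), NULL))
    gt2 <- handGT(ped, g2, freq = NA_real_, cm = c(0, 1, 2))
    pr2 <- pruneByLD(gt2, threshold = 0.2)
    expect_identical(pr2$kept, c("a", "b", "c"))
})

test_that("the chain rule keeps A and C when only A-B and B-C exceed", {
    # construct: B correlated with both A and C, A and C nearly independent
    set.seed(27)
    nf <- 300
    hA <- rbinom(nf * 2, 1, 0.5)
    hC <- rbinom(nf * 2, 1, 0.5)
    hB <- ifelse(rbinom(nf * 2, 1, 0.5) == 1, hA, hC)   # r2 ~ 0.25 with each
    gen <- function(h) h[seq(1, nf * 2, 2)] + h[seq(2, nf * 2, 2)]
    ped <- data.frame(family = paste0("F", 1:nf), id = "1",
                      father = NA_character_, mother = NA_character_,
                      sex = 1L, affection = 0L)
    g <- rbind(A = gen(hA), B = gen(hB), C = gen(hC))
    gt <- handGT(ped, g, freq = NA_real_, cm = c(0, 1, 2))
    r2 <- function(x, y) emHaplotypeFreqs(g[x, ], g[y, ])$r2
    skip_if(r2("A", "B") <= 0.2 || r2("B", "C") <= 0.2 || r2("A", "C") > 0.2,
            "construction did not realize the intended LD pattern")
    pr <- pruneByLD(gt, threshold = 0.2)
    expect_identical(pr$kept, c("A", "C"))
})
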