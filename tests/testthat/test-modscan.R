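test_that("MOD dominates every grid model and every family reordering", {
    sim <- simulateStudy(studyConfig(nFamilies = 3L, nTrios = 0L,
                                     nMarkers = 12L, spacingCm = 4,
                                     seed = 81, missingRate = 0))
    gt <- modlink:::.preparedMarkers(sim$gt)
    grid <- modGrid(penStep = 0.5, qValues = c(0.05, 0.2), refine = FALSE)
    pos <- c(0, 10, 22, 33.5)
    sc <- modScan(gt, positions = pos, grid = grid)
    expect_true(all(sc@mod >= 0))
    models <- modlink:::.gridModels(grid)
    for (j in sample(ncol(models), 6)) {
        m <- models[, j]
        tl <- traitLod(gt, traitModel(q = m["q"], f0 = m["f0"], f2 = m["f2"],
                                      f1pat = m["f1pat"], f1mat = m["f1mat"]),
                       positions = pos)
        expect_true(all(sc@mod - tl$total >= -1e-9))
    }
    # per-family contributions sum to the MOD
    expect_equal(unname(rowSums(sc@perFamily)), unname(sc@mod),
                 tolerance = 1e-9)
    # family order never matters
    sc2 <- modScan(gt, positions = pos, grid = grid,
                   families = rev(familyNames(gt)))
    expect_equal(unname(sc2@mod), unname(sc@mod), tolerance = 1e-12)
})

test_that("imprinting search nests the standard one (pointwise dominance)", {
    sim <- simulateStudy(studyConfig(nFamilies = 4L, nTrios = 0L,
                                     nMarkers = 10L, spacingCm = 5,
                                     seed = 82))
    gt <- modlink:::.preparedMarkers(sim$gt)
    pos <- seq(0, 45, by = 9)
    std <- modScan(gt, positions = pos,
                   grid = modGrid(penStep = 0.5, qValues = c(0.05, 0.2),
                                  refine = FALSE))
    imp <- modScanImprinting(gt, positions = pos,
                             grid = modGrid(penStep = 0.5,
                                            qValues = c(0.05, 0.2),
                                            imprinting = TRUE, refine = FALSE))
    expect_true(all(imp@mod - std@mod >= 0))
    # explicit collapsed imprinting model set equals the standard scan
    models <- modlink:::.gridModels(modGrid(penStep = 0.5,
                                            qValues = c(0.05, 0.2)))
    shuffled <- models[, sample(ncol(models)), drop = FALSE]
    scA <- modScan(gt, positions = pos, models = models)
    scB <- modScan(gt, positions = pos, models = shuffled)
    expect_equal(unname(scA@mod), unname(scB@mod), tolerance = 1e-12)
    expect_equal(unname(scA@mod), unname(std@mod), tolerance = 1e-12)
})

test_that("simplex refinement never falls below the grid maximum", {
    sim <- simulateStudy(studyConfig(nFamilies = 2L, nTrios = 0L,
                                     nMarkers = 8L, spacingCm = 5, seed = 83))
    gt <- modlink:::.preparedMarkers(sim$gt)
    pos <- c(0, 12, 25)
    gridOnly <- modScan(gt, positions = pos,
                        grid = modGrid(penStep = 0.5, qValues = c(0.05, 0.2),
                                       refine = FALSE))
    refined <- modScan(gt, positions = pos,
                       grid = modGrid(penStep = 0.5, qValues = c(0.05, 0.2),
                                      refine = TRUE))
    expect_true(all(refined@mod - gridOnly@mod >= -1e-9))
    expect_equal(unname(rowSums(refined@perFamily)), unname(refined@mod),
                 tolerance = 1e-9)
})

test_that("spurious imprinting evidence stays near the extra degree of freedom", {
    set.seed(84)
    gaps <- numeric(6)
    for (r in seq_along(gaps)) {
        sim <- simulateStudy(studyConfig(nFamilies = 4L, nTrios = 0L,
                                         nMarkers = 15L, spacingCm = 3,
                                         model = traitModel(q = 0.1, f0 = 0.02,
                                                            f1 = 0.4, f2 = 0.9),
                                         seed = 8400 + r))
        gt <- modlink:::.preparedMarkers(sim$gt)
        pos <- seq(0, 42, by = 7)
        std <- modScan(gt, positions = pos,
                       grid = modGrid(penStep = 0.25, qValues = c(0.05, 0.1, 0.3),
                                      refine = FALSE))
        imp <- modScanImprinting(gt, positions = pos,
                                 grid = modGrid(penStep = 0.25,
                                                qValues = c(0.05, 0.1, 0.3),
                                                imprinting = TRUE,
                                                refine = FALSE))
        gaps[r] <- max(imp@mod) - max(std@mod)
    }
    expect_lt(mean(gaps), 0.5)
})

test_that("a fully imprinted scenario rewards the imprinting scan", {
    set.seed(85)
    wins <- 0
    for (r in 1:8) {
        sim <- simulateStudy(studyConfig(
            nFamilies = 6L, nTrios = 0L,
            model = traitModel(q = 0.15, f0 = 0, f2 = 0.95,
                               f1mat = 0.9, f1pat = 0),
            seed = 8500 + r))
        gt <- modlink:::.preparedMarkers(sim$gt)
        pos <- SummarizedExperiment::rowData(gt)$cm
        pos <- pos[seq(1, length(pos), by = 5)]
        std <- modScan(gt, positions = pos,
                       grid = modGrid(penStep = 1 / 3, qValues = c(0.05, 0.15, 0.3),
                                      refine = FALSE))
        imp <- modScanImprinting(gt, positions = pos,
                                 grid = modGrid(penStep = 1 / 3,
                                                qValues = c(0.05, 0.15, 0.3),
                                                imprinting = TRUE,
                                                refine = FALSE))
        if (max(imp@mod) - max(std@mod) > 1) wins <- wins + 1
    }
    expect_gte(wins, 5)
})

test_that("per-family contributions reproduce a published-style decomposition", {
    # six per-family LODs and an "All" row equal to their sum, as printed in
    # family-wise linkage tables
    lods <- utils::read.delim(system.file("extdata", "chd_family_lods.tsv",
                                          package = "modlink"))
    fams <- lods[lods$family != "All", ]
    all <- lods[lods$family == "All", ]
    expect_lt(abs(sum(fams$lod_15q26.3) - all$lod_15q26.3), 0.001)
    expect_lt(abs(sum(fams$lod_18q21.2) - all$lod_18q21.2), 0.001)
    # the same additivity holds exactly for our own decomposition
    sim <- simulateStudy(studyConfig(nFamilies = 6L, nTrios = 0L, seed = 86))
    gt <- modlink:::.preparedMarkers(sim$gt)
    model <- traitModel(q = 0.1, f0 = 0, f1 = 0, f2 = 0.98)
    tab <- perFamilyContributions(gt, model, positions = c(30, 50))
    expect_equal(unname(unlist(tab["All", ])),
                 unname(colSums(as.matrix(tab[familyNames(gt), ]))),
                 tolerance = 1e-9)
    # single family: contribution equals the total
    tab1 <- perFamilyContributions(gt, model, positions = 50, families = "F1")
    expect_equal(tab1["F1", 1], tab1["All", 1])
})
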