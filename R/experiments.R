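## Validation experiments at desk scale: null calibration of the gene-drop
## empirical P value, and parameter recovery of the MOD scan under the
## study's best-fitting recessive model.  Both are deterministic given their
## seed and are the basis of the package's reported operating
## characteristics.

# compact scan settings used by the experiments: coarse penetrance grid and
# a thinned position grid; the empirical-P construction is valid for any
# fixed scan configuration as long as the observed data and the replicates
# are analyzed identically
.experimentGrid <- function() {
    modGrid(penStep = 1 / 3, qValues = c(0.01, 0.1, 0.3), refine = FALSE)
}

# marker filters plus founder allele-frequency estimation; markers whose
# founder-estimated frequency is degenerate (allele seen only in untyped
# founders) cannot enter the likelihood and are dropped as well
.preparedMarkers <- function(gt) {
    gt <- estimateAlleleFreqs(filterMarkers(gt)$gt)
    f <- alleleFreqs(gt)
    gt[!is.na(f) & f > 0 & f < 1, ]
}

#' Null calibration of the gene-drop empirical P value
#'
#' Simulates independent null studies (six multiplex pedigrees, trait
#' unlinked to the markers), computes each study's maximum MOD score and its
#' gene-drop empirical P value with R inner replicates, and reports the
#' rejection rate at the nominal level.  Under the null the empirical P is
#' approximately uniform, so the rejection rate should fall inside the
#' exact binomial confidence interval around the nominal level.
#'
#' @param nDatasets outer null studies (default 200).
#' @param R gene-drop replicates per study (default 200).
#' @param alpha nominal level (default 0.05).
#' @param seed master seed.
#' @param nMarkers markers per study (default 50).
#' @param thinPositions scan every k-th marker position (default 6).
#' @return list: \code{pValues}, \code{rejectionRate}, \code{ciLow},
#'   \code{ciHigh} (exact binomial 95 percent acceptance bounds for the
#'   rejection count), \code{inInterval}.
#' @export
nullCalibration <- function(nDatasets = 200L, R = 200L, alpha = 0.05,
                            seed = 1L, nMarkers = 50L, thinPositions = 6L) {
    set.seed(seed)
    dataSeeds <- sample.int(.Machine$integer.max - 1L, 2L * nDatasets)
    grid <- .experimentGrid()
    pv <- numeric(nDatasets)
    for (d in seq_len(nDatasets)) {
        cfg <- studyConfig(nTrios = 0L, nMarkers = nMarkers, traitPosCm = NA,
                           seed = dataSeeds[d])
        sim <- simulateStudy(cfg)
        gt <- .preparedMarkers(sim$gt)
        engine <- .engineBuild(gt, NULL, 20L, "haldane")
        pos <- engine$cm[seq(1L, length(engine$cm), by = thinPositions)]
        sc <- modScan(gt, positions = pos, grid = grid, engine = engine)
        rep <- replicateScan(gt, positions = pos, grid = grid, R = R,
                             masterSeed = dataSeeds[nDatasets + d],
                             engine = engine)
        pv[d] <- empiricalP(max(sc@mod), rep$maxima)@p
    }
    rej <- sum(pv <= alpha)
    ci <- stats::qbinom(c(0.025, 0.975), nDatasets, alpha)
    list(pValues = pv, rejectionRate = rej / nDatasets,
         ciLow = ci[1] / nDatasets, ciHigh = ci[2] / nDatasets,
         inInterval = rej >= ci[1] && rej <= ci[2])
}

#' Trait-locus recovery under the recessive benchmark model
#'
#' Simulates linked studies under the recessive model with incomplete
#' penetrance (q = 0.1, penetrances 0, 0, 0.98), runs a grid MOD scan over
#' the marker positions, and reports how often the peak falls within
#' \code{tolCm} of the true locus and how often the best-fitting model is
#' recessive-like (fitted heterozygote minus baseline penetrance below 0.2).
#'
#' @param nReplicates simulated studies (default 100).
#' @param seed master seed.
#' @param tolCm peak-location tolerance in cM (default 10).
#' @return list: \code{peakRate}, \code{recessiveRate}, \code{peakCm},
#'   \code{truePos}.
#' @export
recoveryExperiment <- function(nReplicates = 100L, seed = 1L, tolCm = 10) {
    set.seed(seed)
    dataSeeds <- sample.int(.Machine$integer.max - 1L, nReplicates)
    grid <- modGrid(penStep = 0.25, qValues = c(0.01, 0.05, 0.1, 0.2, 0.5),
                    refine = FALSE)
    models <- cbind(.gridModels(grid),
                    c(0.1, 0, 0, 0, 0.98))   # generating model itself
    rownames(models) <- c("q", "f0", "f1pat", "f1mat", "f2")
    peakCm <- numeric(nReplicates)
    recessive <- logical(nReplicates)
    truePos <- numeric(nReplicates)
    for (r in seq_len(nReplicates)) {
        sim <- simulateStudy(studyConfig(nTrios = 0L, seed = dataSeeds[r]))
        gt <- .preparedMarkers(sim$gt)
        pos <- rowData(gt)$cm
        sc <- modScan(gt, positions = pos, models = models)
        i <- which.max(sc@mod)
        peakCm[r] <- sc@positions[i]
        recessive[r] <- sc@models["f1pat", i] - sc@models["f0", i] < 0.2
        truePos[r] <- sim$truth$traitPos
    }
    list(peakRate = mean(abs(peakCm - truePos) <= tolCm),
         recessiveRate = mean(recessive),
         peakCm = peakCm, truePos = truePos)
}
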