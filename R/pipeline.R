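## End-to-end orchestration: QC -> LD prune -> MOD scan (optionally with
## imprinting) -> gene-drop empirical P -> family-based association.
## Stages communicate through on-disk artifacts in the run directory so
## each stage is independently re-runnable; a rerun with the same inputs
## and seeds is byte-identical.

#' Run the full analysis pipeline
#'
#' @param gt input \linkS4class{GenotypeTable}; alternatively give
#'   \code{pedFile}/\code{mapFile}.
#' @param outDir run directory (created; existing artifacts overwritten).
#' @param pedFile,mapFile input files, read with \code{\link{readPed}} when
#'   \code{gt} is \code{NULL}.
#' @param minCallRate QC marker call-rate threshold.
#' @param unlikelyThreshold QC unlikely-genotype threshold (NA = skip).
#' @param r2Threshold,windowMarkers LD-pruning parameters.
#' @param grid \linkS4class{ModGrid} for the scan and the replicates.
#' @param positions scan positions (default marker grid + midpoints after
#'   pruning).
#' @param imprinting additionally run the imprinting scan.
#' @param replicates gene-drop replicates for the empirical P (0 = skip).
#' @param modThreshold association-region MOD threshold.
#' @param alpha family-wise error target.
#' @param bitLimit,mapFunction engine settings.
#' @param seed master seed for the replicate stage.
#' @param linkageFamilies families used for linkage; defaults to those not
#'   marked \code{role == "trio"} in the pedigree (trios still enter the
#'   association stage).
#' @return the summary list (also written as \code{summary.json}),
#'   invisibly.
#' @export
runPipeline <- function(gt = NULL, outDir, pedFile = NULL, mapFile = NULL,
                        minCallRate = 0.95, unlikelyThreshold = NA,
                        r2Threshold = 0.2, windowMarkers = 50L,
                        grid = modGrid(penStep = 0.25,
                                       qValues = c(0.01, 0.05, 0.1, 0.3, 0.5),
                                       refine = FALSE),
                        positions = NULL, imprinting = FALSE,
                        replicates = 0L, modThreshold = 2.5, alpha = 0.05,
                        bitLimit = 20L, mapFunction = "haldane", seed = 1L) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))
    }
    tsv <- function(x, f) utils::write.table(
        x, file.path(outDir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    if (is.null(gt))
        gt <- stage("read", readPed(pedFile, mapFile))
    nInput <- nrow(gt)
    qc <- stage("qc", runQC(gt, minCallRate = minCallRate,
                            unlikelyThreshold = unlikelyThreshold,
                            bitLimit = bitLimit))
    tsv(qc$report@removedMarkers, "qc_removed_markers.tsv")
    tsv(qc$report@mendelErrors, "qc_mendel_errors.tsv")
    tsv(qc$report@flaggedPairs, "qc_flagged_pairs.tsv")
    writePed(qc$gt, file.path(outDir, "qc.ped"))
    writeMap(qc$gt, file.path(outDir, "qc.map"))
    pr <- stage("prune", pruneByLD(qc$gt, threshold = r2Threshold,
                                   windowMarkers = windowMarkers))
    writeLines(pr$kept, file.path(outDir, "pruned_markers.txt"))
    tsv(pr$pairs, "prune_pairs.tsv")
    gtScan <- pr$gt
    cd <- colData(gtScan)
    linkageFamilies <- if ("role" %in% colnames(cd))
        unique(cd$family[cd$role != "trio"]) else unique(cd$family)
    scan <- stage("scan", modScan(gtScan, positions = positions, grid = grid,
                                  families = linkageFamilies,
                                  bitLimit = bitLimit,
                                  mapFunction = mapFunction))
    scanTab <- cbind(modScores(scan), perFamilyLod(scan))
    tsv(scanTab, "scan.tsv")
    scanImp <- NULL
    if (imprinting) {
        gridImp <- grid
        gridImp@imprinting <- TRUE
        scanImp <- stage("scan-imprinting",
                         modScan(gtScan, positions = positions, grid = gridImp,
                                 families = linkageFamilies,
                                 bitLimit = bitLimit, mapFunction = mapFunction))
        tsv(cbind(modScores(scanImp), perFamilyLod(scanImp)),
            "scan_imprinting.tsv")
    }
    peak <- which.max(scan@mod)
    emp <- NULL
    if (replicates > 0L) {
        rep <- stage("empirical", replicateScan(
            gtScan, positions = scan@positions, grid = grid,
            R = replicates, masterSeed = seed, families = linkageFamilies,
            bitLimit = bitLimit, mapFunction = mapFunction))
        emp <- empiricalP(max(scan@mod), rep$maxima, masterSeed = seed)
        tsv(data.frame(replicate = seq_along(rep$maxima), max_mod = rep$maxima),
            "replicate_maxima.tsv")
    }
    assoc <- stage("assoc", regionAssociation(gtScan, scan,
                                              modThreshold = modThreshold,
                                              alpha = alpha))
    tsv(assoc, "association.tsv")
    summary <- list(
        markers_input = nInput,
        markers_after_qc = nrow(qc$gt),
        qc_surviving_fraction = qc$report@survivingFraction,
        markers_after_prune = nrow(gtScan),
        peak = list(position_cm = scan@positions[peak],
                    mod = scan@mod[peak],
                    model = as.list(scan@models[, peak]),
                    per_family_lod = as.list(scan@perFamily[peak, ])),
        imprinting_peak_mod = if (!is.null(scanImp)) max(scanImp@mod) else NULL,
        empirical = if (!is.null(emp))
            list(observed = emp@observed, replicates = length(emp@maxima),
                 exceedances = emp@exceedances, p = emp@p) else NULL,
        association_markers = nrow(assoc),
        association_significant = sum(assoc$significant),
        parameters = list(min_call_rate = minCallRate,
                          r2_threshold = r2Threshold,
                          window_markers = windowMarkers,
                          mod_threshold = modThreshold,
                          alpha = alpha, seed = seed,
                          map_function = mapFunction))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(summary)
}
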