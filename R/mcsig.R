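## Gene-dropping Monte-Carlo null for MOD scores and empirical P values.

# one meiosis bit chain along the loci; optionally conditioned on the bit at
# one locus (used when markers are dropped jointly with a trait locus)
.meiosisBits <- function(theta, fixedAt = NULL, fixedVal = NULL) {
    L <- length(theta) + 1L
    bits <- integer(L)
    if (is.null(fixedAt)) {
        bits[1L] <- stats::rbinom(1L, 1L, 0.5)
        if (L > 1L) {
            flips <- stats::rbinom(L - 1L, 1L, theta)
            bits <- cumsum(c(bits[1L], flips)) %% 2L
        }
    } else {
        bits[fixedAt] <- fixedVal
        if (fixedAt < L) {
            flips <- stats::rbinom(L - fixedAt, 1L, theta[fixedAt:(L - 1L)])
            bits[(fixedAt + 1L):L] <- (fixedVal + cumsum(flips)) %% 2L
        }
        if (fixedAt > 1L) {
            flips <- stats::rbinom(fixedAt - 1L, 1L, rev(theta[1:(fixedAt - 1L)]))
            bits[(fixedAt - 1L):1L] <- (fixedVal + cumsum(flips)) %% 2L
        }
    }
    bits
}

# drop founder alleles and transmissions through one family structure;
# returns persons x markers matrix of allele-2 indicator pairs summed
.geneDropFamily <- function(st, freq, theta, condBits = NULL) {
    M <- length(freq)
    n <- st$n
    P2 <- matrix(0L, n, M)   # paternal-allele "allele 2" indicator
    M2 <- matrix(0L, n, M)
    for (i in seq_len(n)) {
        if (st$father[i] == 0L) {
            P2[i, ] <- stats::rbinom(M, 1L, 1 - freq)
            M2[i, ] <- stats::rbinom(M, 1L, 1 - freq)
        } else {
            for (side in 1:2) {
                par <- if (side == 1L) st$father[i] else st$mother[i]
                key <- paste0(i, ".", side)
                bits <- if (!is.null(condBits) && !is.null(condBits[[key]]))
                    condBits[[key]] else .meiosisBits(theta)
                src <- ifelse(bits == 0L, P2[par, ], M2[par, ])
                if (side == 1L) P2[i, ] <- src else M2[i, ] <- src
            }
        }
    }
    P2 + M2
}

#' Gene-drop simulation of marker genotypes under no linkage
#'
#' Founder haplotypes are drawn under Hardy-Weinberg and linkage
#' equilibrium at the table's allele frequencies and transmitted through
#' the pedigrees with recombination per the map function between adjacent
#' markers (free recombination across chromosome boundaries).  Affection
#' status is copied unchanged from the input and the observed missingness
#' mask is re-applied, so replicates mirror the real data in structure,
#' phenotype, marker spacing and allele frequencies, while the trait is
#' unlinked to the markers by construction.
#'
#' @param gt template \linkS4class{GenotypeTable} with frequencies set.
#' @param seed RNG seed.
#' @param mapFunction see \code{\link{mapTheta}}.
#' @return a new \linkS4class{GenotypeTable}.
#' @export
geneDrop <- function(gt, seed = NULL, mapFunction = "haldane") {
    if (!is.null(seed)) set.seed(seed)
    rd <- rowData(gt)
    freq <- .checkFreqs(rd$freq1)
    theta <- .dropTheta(rd, mapFunction)
    pedDf <- as.data.frame(colData(gt))
    g <- assay(gt, "geno")
    out <- g
    for (fam in unique(pedDf$family)) {
        st <- .famStruct(pedDf, fam)
        sim <- .geneDropFamily(st, freq, theta)
        out[, st$keys] <- t(sim)
    }
    out[is.na(g)] <- NA_integer_
    assay(gt, "geno") <- out
    gt
}

.dropTheta <- function(rd, mapFunction) {
    theta <- mapTheta(diff(rd$cm), mapFunction)
    chromBreak <- rd$chrom[-1] != rd$chrom[-nrow(rd)]
    theta[chromBreak] <- 0.5
    theta
}

#' Replicate MOD-score scan maxima under the gene-drop null
#'
#' Each replicate gene-drops the markers, re-runs the MOD scan with the
#' same positions and model grid as the real analysis, and records the
#' maximum MOD over the scanned region.  Replicate seeds are derived
#' deterministically from \code{masterSeed}, so reruns are bit-identical.
#'
#' @inheritParams modScan
#' @param R number of replicates.
#' @param masterSeed master seed.
#' @return list: \code{maxima} (length R), \code{seeds}, \code{masterSeed}.
#' @export
replicateScan <- function(gt, positions = NULL, grid = modGrid(refine = FALSE),
                          R = 100L, masterSeed = 1L, families = NULL,
                          bitLimit = 20L, mapFunction = "haldane",
                          engine = NULL) {
    if (is.null(engine)) engine <- .engineBuild(gt, families, bitLimit, mapFunction)
    if (is.null(positions)) positions <- .defaultPositions(engine$cm)
    models <- .gridModels(grid)
    set.seed(masterSeed)
    seeds <- sample.int(.Machine$integer.max - 1L, R)
    pedDf <- as.data.frame(colData(gt))
    masks <- lapply(engine$families, function(st) is.na(.familyGeno(gt, st)))
    geom <- .scanGeom(engine$cm, positions, mapFunction)
    maxima <- numeric(R)
    if (grid@refine) {
        for (i in seq_len(R)) {
            set.seed(seeds[i])
            g <- assay(gt, "geno")
            for (st in engine$families) {
                sim <- .geneDropFamily(st, engine$freq, engine$theta)
                sim[masks[[st$family]]] <- NA_integer_
                g[, st$keys] <- t(sim)
            }
            gtRep <- gt
            assay(gtRep, "geno") <- g
            sc <- modScan(gtRep, positions, grid, families = families,
                          bitLimit = bitLimit, mapFunction = mapFunction,
                          engine = engine)
            maxima[i] <- max(sc@mod)
        }
    } else {
        for (st in engine$families) .lgSetModels(st$xptr, models)
        for (i in seq_len(R)) {
            set.seed(seeds[i])
            total <- NULL
            for (st in engine$families) {
                sim <- .geneDropFamily(st, engine$freq, engine$theta)
                sim[masks[[st$family]]] <- NA_integer_
                lod <- .lgScanLOD(st$xptr, sim, engine$freq, engine$theta,
                                  geom$idx, geom$thetaL, geom$thetaR)
                total <- if (is.null(total)) lod else total + lod
            }
            maxima[i] <- max(total, 0)
        }
    }
    list(maxima = maxima, seeds = seeds, masterSeed = as.integer(masterSeed))
}

#' Empirical P value of an observed scan statistic
#'
#' p = (number of replicate maxima >= observed) / R; ties count as
#' exceedances.  The \code{(r+1)/(R+1)} variant is available via
#' \code{plusOne}.
#'
#' @param observed observed statistic (e.g. maximum MOD of the real scan).
#' @param maxima replicate maxima (e.g. from \code{\link{replicateScan}}).
#' @param masterSeed recorded in the result for reproducibility.
#' @param plusOne use (r+1)/(R+1).
#' @return an \linkS4class{EmpiricalResult}.
#' @export
empiricalP <- function(observed, maxima, masterSeed = NA_integer_,
                       plusOne = FALSE) {
    if (!length(maxima)) stop("maxima must be non-empty")
    r <- sum(maxima >= observed)
    R <- length(maxima)
    p <- if (plusOne) (r + 1) / (R + 1) else r / R
    new("EmpiricalResult", observed = as.numeric(observed),
        maxima = as.numeric(maxima), exceedances = as.integer(r),
        p = p, masterSeed = as.integer(masterSeed),
        convention = if (plusOne) "(r+1)/(R+1)" else "r/R")
}
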