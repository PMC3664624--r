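## Quality control: relationship and sex checks, Mendelian genotype
## elimination, unlikely-genotype (double-recombinant) detection, marker
## filters and founder allele-frequency estimation.

# identity-by-state (0/1/2 shared alleles) between two genotype-code vectors
.ibsVec <- function(g1, g2) {
    ok <- !is.na(g1) & !is.na(g2)
    2L - abs(g1[ok] - g2[ok])
}

# simulate the (mean, SD) IBS profile of a relationship class over the
# study's markers; classes: parent-offspring, full sibs, unrelated
.simPairIBS <- function(freq, class, nsim) {
    M <- length(freq)
    draw <- function() matrix(stats::rbinom(2L * M, 1L, rep(1 - freq, each = 2L)),
                              nrow = 2L)  # rows = two alleles, entries = allele-2 indicator
    t(vapply(seq_len(nsim), function(i) {
        fa <- draw(); mo <- draw()
        if (class == "parent-offspring") {
            g1 <- colSums(fa)
            ch <- rbind(fa[sample.int(2L, M, replace = TRUE) + 2L * (seq_len(M) - 1L)],
                        mo[sample.int(2L, M, replace = TRUE) + 2L * (seq_len(M) - 1L)])
            g2 <- colSums(ch)
        } else if (class == "fullsib") {
            c1 <- rbind(fa[sample.int(2L, M, replace = TRUE) + 2L * (seq_len(M) - 1L)],
                        mo[sample.int(2L, M, replace = TRUE) + 2L * (seq_len(M) - 1L)])
            c2 <- rbind(fa[sample.int(2L, M, replace = TRUE) + 2L * (seq_len(M) - 1L)],
                        mo[sample.int(2L, M, replace = TRUE) + 2L * (seq_len(M) - 1L)])
            g1 <- colSums(c1); g2 <- colSums(c2)
        } else {
            g1 <- colSums(fa); g2 <- colSums(mo)
        }
        ibs <- 2 - abs(g1 - g2)
        c(mean(ibs), stats::sd(ibs))
    }, numeric(2)))
}

#' Relationship check from identity-by-state sharing
#'
#' For every within-family pair, the mean and SD of the per-marker IBS count
#' (0/1/2 shared alleles) are compared with the distributions expected for
#' the claimed relationship class (parent-offspring, full sibs, other).
#' Class regions are calibrated mechanically by internal gene-drop
#' simulations at the study's estimated allele frequencies and classified by
#' a Gaussian discriminant; parent-offspring pairs are additionally required
#' to show essentially no IBS-0 markers (proportion < \code{ibs0Max}).
#' Pairs with too few jointly typed markers are reported untestable, not
#' flagged.
#'
#' @param gt a \linkS4class{GenotypeTable} with allele frequencies set.
#' @param minMarkers minimum jointly typed markers per pair.
#' @param nsim internal simulations per class.
#' @param ibs0Max maximal IBS-0 proportion for a parent-offspring pair.
#' @param seed seed for the internal calibration simulations.
#' @return data.frame of pairs: family, two person ids, claimed class,
#'   IBS mean/SD, IBS-0 proportion, assigned class, flagged, untestable.
#' @export
ibsRelationshipCheck <- function(gt, minMarkers = 200L, nsim = 200L,
                                 ibs0Max = 0.005, seed = 1L) {
    freq <- .checkFreqs(rowData(gt)$freq1)
    g <- assay(gt, "geno")
    p <- as.data.frame(colData(gt))
    set.seed(seed)
    classes <- c("parent-offspring", "fullsib", "other")
    sims <- list("parent-offspring" = .simPairIBS(freq, "parent-offspring", nsim),
                 fullsib = .simPairIBS(freq, "fullsib", nsim),
                 other = .simPairIBS(freq, "unrelated", nsim))
    mu <- lapply(sims, colMeans)
    pooled <- Reduce(`+`, lapply(sims, function(s) stats::cov(s))) / 3
    pooled <- pooled + diag(1e-8, 2)
    pinv <- solve(pooled)
    classify <- function(x) {
        d2 <- vapply(classes, function(cl) {
            v <- x - mu[[cl]]
            drop(v %*% pinv %*% v)
        }, numeric(1))
        classes[which.min(d2)]
    }
    out <- list()
    for (fam in unique(p$family)) {
        rows <- which(p$family == fam)
        if (length(rows) < 2L) next
        q <- p[rows, ]
        for (a in seq_along(rows)[-length(rows)]) for (b in (a + 1L):length(rows)) {
            ia <- rows[a]; ib <- rows[b]
            claimed <- if (q$id[b] %in% c(q$father[a], q$mother[a]) ||
                           q$id[a] %in% c(q$father[b], q$mother[b])) "parent-offspring"
            else if (!is.na(q$father[a]) && !is.na(q$father[b]) &&
                     q$father[a] == q$father[b] && q$mother[a] == q$mother[b]) "fullsib"
            else "other"
            ibs <- .ibsVec(g[, ia], g[, ib])
            if (length(ibs) < minMarkers) {
                out[[length(out) + 1L]] <- data.frame(
                    family = fam, id1 = q$id[a], id2 = q$id[b], claimed = claimed,
                    ibsMean = NA_real_, ibsSD = NA_real_, ibs0 = NA_real_,
                    assigned = NA_character_, flagged = FALSE, untestable = TRUE)
                next
            }
            x <- c(mean(ibs), stats::sd(ibs))
            ibs0 <- mean(ibs == 0L)
            assigned <- if (x[1] > 1.95 && x[2] < 0.25) "duplicate" else classify(x)
            flagged <- assigned != claimed ||
                (claimed == "parent-offspring" && ibs0 > ibs0Max)
            out[[length(out) + 1L]] <- data.frame(
                family = fam, id1 = q$id[a], id2 = q$id[b], claimed = claimed,
                ibsMean = x[1], ibsSD = x[2], ibs0 = ibs0,
                assigned = assigned, flagged = flagged, untestable = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(family = character(), id1 = character(), id2 = character(),
                          claimed = character(), ibsMean = numeric(), ibsSD = numeric(),
                          ibs0 = numeric(), assigned = character(),
                          flagged = logical(), untestable = logical()))
    do.call(rbind, out)
}

#' Sex-consistency check from X-marker heterozygosity
#'
#' Males are flagged when their heterozygosity across non-pseudoautosomal
#' X-chromosome markers exceeds \code{hetMale}; females when it falls below
#' \code{hetFemale}.  Individuals with fewer than \code{minMarkers} typed X
#' markers are untestable.  With no X markers at all the check is skipped
#' with a warning.
#'
#' @param gt a \linkS4class{GenotypeTable}; X markers are rows with
#'   \code{chrom} "X" (or "23").
#' @param hetMale,hetFemale heterozygosity thresholds.
#' @param minMarkers minimum typed X markers per individual.
#' @return data.frame: family, id, sex, X heterozygosity, typed markers,
#'   flagged, untestable.
#' @export
sexConsistencyCheck <- function(gt, hetMale = 0.05, hetFemale = 0.20,
                                minMarkers = 50L) {
    xrows <- rowData(gt)$chrom %in% c("X", "23")
    if (!any(xrows)) {
        warning("no X-chromosome markers; sex check skipped")
        return(data.frame(family = character(), id = character(), sex = integer(),
                          xHet = numeric(), typed = integer(),
                          flagged = logical(), untestable = logical()))
    }
    g <- assay(gt, "geno")[xrows, , drop = FALSE]
    p <- as.data.frame(colData(gt))
    typed <- colSums(!is.na(g))
    het <- colSums(g == 1L, na.rm = TRUE) / pmax(typed, 1L)
    untestable <- typed < minMarkers
    flagged <- !untestable &
        ((p$sex == 1L & het > hetMale) | (p$sex == 2L & het < hetFemale))
    data.frame(family = p$family, id = p$id, sex = p$sex, xHet = het,
               typed = typed, flagged = flagged, untestable = untestable,
               row.names = NULL)
}

# offspring genotype codes possible from unordered parental codes
.offspringSet <- function(gf, gm) {
    from <- function(g) switch(g + 1L, 0L, c(0L, 1L), 1L)  # transmitted allele-2 count
    unique(outer(from(gf), from(gm), `+`)[TRUE])
}

#' Mendelian genotype elimination for one family at one marker
#'
#' Lange-Goradia style set recoding: each person starts with the genotype
#' set compatible with their observed genotype ({0,1,2} if missing) and the
#' sets are iteratively restricted through every nuclear family until a
#' fixpoint.  An empty set for any person marks the family x marker as
#' Mendelian-incompatible.
#'
#' @param struct internal family structure (from a \code{PedigreeSet}, see
#'   \code{\link{mendelCheck}} for the table-level interface), or a
#'   \code{PedigreeSet} containing a single family.
#' @param geno integer genotype codes (count of allele 2, NA missing) in the
#'   order of \code{struct$ids} (topological).
#' @return list with \code{sets} (list of compatible genotype-code sets per
#'   person, named by id) and \code{incompatible} (logical).
#' @export
genotypeElimination <- function(struct, geno) {
    if (is(struct, "PedigreeSet")) {
        fam <- unique(struct@ped$family)
        if (length(fam) != 1L) stop("supply a single family")
        struct <- .famStruct(struct@ped, fam)
    }
    n <- struct$n
    sets <- lapply(seq_len(n), function(i)
        if (is.na(geno[i])) c(0L, 1L, 2L) else geno[i])
    # nuclear units: unique parent couples with their children
    couples <- unique(cbind(struct$father, struct$mother))
    couples <- couples[couples[, 1] > 0L, , drop = FALSE]
    repeat {
        changed <- FALSE
        for (k in seq_len(nrow(couples))) {
            fa <- couples[k, 1]; mo <- couples[k, 2]
            kids <- which(struct$father == fa & struct$mother == mo)
            savedF <- integer(0); savedM <- integer(0)
            savedK <- lapply(kids, function(i) integer(0))
            for (gf in sets[[fa]]) for (gm in sets[[mo]]) {
                O <- .offspringSet(gf, gm)
                kidSets <- lapply(kids, function(i) intersect(sets[[i]], O))
                if (all(lengths(kidSets) > 0L)) {
                    savedF <- union(savedF, gf)
                    savedM <- union(savedM, gm)
                    for (j in seq_along(kids))
                        savedK[[j]] <- union(savedK[[j]], kidSets[[j]])
                }
            }
            newSets <- sets
            newSets[[fa]] <- sort(savedF)
            newSets[[mo]] <- sort(savedM)
            for (j in seq_along(kids)) newSets[[kids[j]]] <- sort(savedK[[j]])
            if (!identical(newSets, sets)) { sets <- newSets; changed <- TRUE }
            if (any(lengths(sets) == 0L)) changed <- FALSE
            if (any(lengths(sets) == 0L)) break
        }
        if (!changed || any(lengths(sets) == 0L)) break
    }
    incompatible <- any(lengths(sets) == 0L)
    if (incompatible)   # no globally consistent assignment exists at all
        sets <- lapply(sets, function(x) integer(0))
    names(sets) <- struct$ids
    list(sets = sets, incompatible = incompatible)
}

#' Detect and clear Mendelian incompatibilities
#'
#' Runs \code{\link{genotypeElimination}} for every family x marker and, on
#' incompatibility, clears the whole family's genotypes at that marker
#' (per-genotype attribution of the error is not identifiable in general,
#' so removing the family's marker data is the conservative resolution).
#'
#' @param gt a \linkS4class{GenotypeTable}.
#' @return list: \code{gt} (cleaned), \code{errors} (data.frame family,
#'   marker, description), \code{genotypesCleared}.
#' @export
mendelCheck <- function(gt) {
    g <- assay(gt, "geno")
    pedDf <- as.data.frame(colData(gt))
    errs <- list()
    cleared <- 0L
    for (fam in unique(pedDf$family)) {
        st <- .famStruct(pedDf, fam)
        sub <- g[, st$keys, drop = FALSE]
        for (m in seq_len(nrow(g))) {
            gv <- sub[m, ]
            if (all(is.na(gv))) next
            r <- genotypeElimination(st, gv)
            if (r$incompatible) {
                errs[[length(errs) + 1L]] <- data.frame(
                    family = fam, marker = rownames(g)[m],
                    description = "genotype set exhausted")
                cleared <- cleared + sum(!is.na(gv))
                g[m, st$keys] <- NA_integer_
            }
        }
    }
    assay(gt, "geno") <- g
    errors <- if (length(errs)) do.call(rbind, errs)
        else data.frame(family = character(), marker = character(),
                        description = character())
    list(gt = gt, errors = errors, genotypesCleared = cleared)
}

#' Detect unlikely genotypes (double-recombinant screen)
#'
#' For each typed genotype g the statistic
#' Lambda(g) = log10 [ P(data with g removed) * P_single(g) / P(data) ]
#' is computed with the multipoint engine, where P_single is the genotype's
#' unconditional HWE probability.  A large Lambda means the observed
#' genotype is vastly less likely than a typing error producing it (for
#' example by forcing close double recombinants); genotypes with Lambda
#' above \code{threshold} (default 4, i.e. odds of 10^4 against) are
#' reported.
#'
#' @inheritParams markerLikelihood
#' @param threshold flag when Lambda exceeds this.
#' @return data.frame: family, id, marker, lambda.
#' @export
detectUnlikelyGenotypes <- function(gt, threshold = 4, families = NULL,
                                    bitLimit = 20L, mapFunction = "haldane") {
    engine <- .engineBuild(gt, families, bitLimit, mapFunction)
    freq <- engine$freq
    out <- list()
    for (st in engine$families) {
        geno <- .familyGeno(gt, st)
        base <- .lgLik(st$xptr, geno, freq, engine$theta)
        typed <- which(!is.na(geno), arr.ind = TRUE)
        for (k in seq_len(nrow(typed))) {
            i <- typed[k, 1]; m <- typed[k, 2]
            g2 <- geno
            g2[i, m] <- NA_integer_
            drop1 <- .lgLik(st$xptr, g2, freq, engine$theta)
            p <- freq[m]
            psingle <- switch(geno[i, m] + 1L, p^2, 2 * p * (1 - p), (1 - p)^2)
            lambda <- drop1 + log10(psingle) - base
            if (lambda > threshold)
                out[[length(out) + 1L]] <- data.frame(
                    family = st$family, id = st$ids[i],
                    marker = engine$markers[m], lambda = lambda)
        }
    }
    if (!length(out))
        return(data.frame(family = character(), id = character(),
                          marker = character(), lambda = numeric()))
    do.call(rbind, out)
}

#' Set flagged genotypes to missing
#'
#' @param gt a \linkS4class{GenotypeTable}.
#' @param flags data.frame with columns family, id, marker (e.g. from
#'   \code{\link{detectUnlikelyGenotypes}}).
#' @export
wipeGenotypes <- function(gt, flags) {
    g <- assay(gt, "geno")
    keys <- paste(flags$family, flags$id, sep = ":")
    for (k in seq_len(nrow(flags)))
        g[flags$marker[k], keys[k]] <- NA_integer_
    assay(gt, "geno") <- g
    gt
}

#' Marker filters: missing position, call rate, monomorphism
#'
#' Removal reasons are assigned in the order no_position, call_rate,
#' monomorphic (one primary reason per marker).  The filter is idempotent.
#'
#' @param gt a \linkS4class{GenotypeTable}.
#' @param minCallRate minimum call rate (default 0.95).
#' @return list: \code{gt} (kept markers), \code{removed} (data.frame
#'   marker, reason), \code{survivingFraction}.
#' @export
filterMarkers <- function(gt, minCallRate = 0.95) {
    g <- assay(gt, "geno")
    cr <- rowMeans(!is.na(g))
    noPos <- is.na(rowData(gt)$cm)
    lowCall <- !noPos & cr < minCallRate
    mono <- !noPos & !lowCall &
        apply(g, 1L, function(x) {
            x <- x[!is.na(x)]
            length(x) == 0L || all(x == 0L) || all(x == 2L)
        })
    reason <- rep(NA_character_, nrow(g))
    reason[mono] <- "monomorphic"
    reason[lowCall] <- "call_rate"
    reason[noPos] <- "no_position"
    removed <- data.frame(marker = rownames(g)[!is.na(reason)],
                          reason = reason[!is.na(reason)])
    keep <- is.na(reason)
    list(gt = gt[keep, ], removed = removed,
         survivingFraction = sum(keep) / nrow(g))
}

#' Maximum-likelihood allele frequencies from founders
#'
#' Counts alleles among typed founders (the ML estimate under HWE and
#' random missingness; non-founders are excluded to keep observations
#' independent).  Markers with no typed founder fall back to counting over
#' all individuals, with a warning.
#'
#' @param gt a \linkS4class{GenotypeTable}.
#' @return the table with \code{freq1} (frequency of allele 1) filled in.
#' @export
estimateAlleleFreqs <- function(gt) {
    g <- assay(gt, "geno")
    fo <- is.na(colData(gt)$father)
    gf <- g[, fo, drop = FALSE]
    n2 <- rowSums(gf, na.rm = TRUE)             # allele-2 count
    nTot <- 2 * rowSums(!is.na(gf))
    freq <- 1 - n2 / nTot
    none <- nTot == 0
    if (any(none)) {
        warning(sprintf("%d marker(s) with no typed founder; falling back to all individuals",
                        sum(none)))
        n2a <- rowSums(g[none, , drop = FALSE], na.rm = TRUE)
        na <- 2 * rowSums(!is.na(g[none, , drop = FALSE]))
        freq[none] <- 1 - n2a / pmax(na, 1L)
        freq[none][na == 0] <- NA_real_
    }
    alleleFreqs(gt) <- freq
    gt
}

#' Run the full QC stage
#'
#' Order mirrors a standard pedigree-genotype pipeline: relationship and sex
#' checks (report-only), Mendelian elimination (incompatible family x marker
#' genotypes cleared), optional unlikely-genotype screen (flagged genotypes
#' wiped), marker filters, and founder allele-frequency estimation.
#'
#' @param gt a \linkS4class{GenotypeTable}.
#' @param minCallRate marker call-rate threshold.
#' @param unlikelyThreshold Lambda threshold; \code{NA} skips the screen
#'   (it requires allele frequencies and is the slowest step).
#' @param skipSexCheck,skipIBSCheck skip the respective report-only check.
#' @param bitLimit engine limit for the unlikely-genotype screen.
#' @return list: \code{gt} (cleaned, filtered, with frequencies),
#'   \code{report} (a \linkS4class{QCReport}).
#' @export
runQC <- function(gt, minCallRate = 0.95, unlikelyThreshold = NA,
                  skipSexCheck = FALSE, skipIBSCheck = FALSE, bitLimit = 20L) {
    emptyPairs <- ibs0 <- NULL
    gt0 <- estimateAlleleFreqs(gt)
    pairs <- if (skipIBSCheck)
        data.frame(family = character(), id1 = character(), id2 = character(),
                   claimed = character(), ibsMean = numeric(), ibsSD = numeric(),
                   ibs0 = numeric(), assigned = character(),
                   flagged = logical(), untestable = logical())
    else tryCatch(ibsRelationshipCheck(gt0), error = function(e)
        data.frame(family = character(), id1 = character(), id2 = character(),
                   claimed = character(), ibsMean = numeric(), ibsSD = numeric(),
                   ibs0 = numeric(), assigned = character(),
                   flagged = logical(), untestable = logical()))
    sexes <- if (skipSexCheck)
        data.frame(family = character(), id = character(), sex = integer(),
                   xHet = numeric(), typed = integer(),
                   flagged = logical(), untestable = logical())
    else suppressWarnings(sexConsistencyCheck(gt0))
    mc <- mendelCheck(gt)
    gt <- mc$gt
    unlikely <- data.frame(family = character(), id = character(),
                           marker = character(), lambda = numeric())
    if (!is.na(unlikelyThreshold)) {
        gt <- estimateAlleleFreqs(gt)
        unlikely <- detectUnlikelyGenotypes(gt, unlikelyThreshold,
                                            bitLimit = bitLimit)
        if (nrow(unlikely)) gt <- wipeGenotypes(gt, unlikely)
    }
    fl <- filterMarkers(gt, minCallRate)
    gt <- estimateAlleleFreqs(fl$gt)
    report <- new("QCReport",
                  flaggedPairs = pairs[pairs$flagged | pairs$untestable, , drop = FALSE],
                  sexFlags = sexes[sexes$flagged | sexes$untestable, , drop = FALSE],
                  mendelErrors = mc$errors,
                  unlikelyGenotypes = unlikely,
                  removedMarkers = fl$removed,
                  survivingFraction = fl$survivingFraction)
    list(gt = gt, report = report)
}
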