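## Synthetic study generator: multiplex pedigrees plus affected-child trios,
## dense biallelic markers, a diallelic trait locus with configurable
## penetrances (optionally parent-of-origin specific), missingness, and
## injectable genotyping errors.  Emulates a six-family congenital-heart-
## defect linkage design so that every pipeline stage can be exercised
## without external data.

#' Pedigree templates
#'
#' Six hand-built family structures spanning 4 to 13 members (48 individuals
#' in total): nuclear sibships and three-generation pedigrees with married-in
#' founders, echoing the range of structures in multiplex clinical linkage
#' studies.  The structures are approximations, not copies of any real
#' family.
#'
#' @return list of data.frames (id, father, mother, sex), plus a
#'   \code{trio} template.
#' @export
pedigreeTemplates <- function() {
    tpl <- function(...) {
        d <- data.frame(...)
        d$id <- as.character(d$id)
        d$father <- ifelse(d$father == "0", NA_character_, as.character(d$father))
        d$mother <- ifelse(d$mother == "0", NA_character_, as.character(d$mother))
        d
    }
    list(
        F1 = tpl(id = 1:4, father = c("0", "0", 1, 1), mother = c("0", "0", 2, 2),
                 sex = c(1, 2, 1, 2)),
        F2 = tpl(id = 1:5, father = c("0", "0", 1, 1, 1),
                 mother = c("0", "0", 2, 2, 2), sex = c(1, 2, 1, 2, 1)),
        F3 = tpl(id = 1:6, father = c("0", "0", 1, 1, 1, 1),
                 mother = c("0", "0", 2, 2, 2, 2), sex = c(1, 2, 1, 2, 1, 2)),
        F4 = tpl(id = 1:9,
                 father = c("0", "0", 1, 1, 1, "0", 3, 3, 3),
                 mother = c("0", "0", 2, 2, 2, "0", 6, 6, 6),
                 sex = c(1, 2, 1, 2, 1, 2, 1, 2, 1)),
        F5 = tpl(id = 1:11,
                 father = c("0", "0", 1, 1, 1, "0", "0", 3, 3, 7, 7),
                 mother = c("0", "0", 2, 2, 2, "0", "0", 6, 6, 4, 4),
                 sex = c(1, 2, 1, 2, 1, 2, 1, 1, 2, 1, 2)),
        F6 = tpl(id = 1:13,
                 father = c("0", "0", 1, 1, 1, "0", "0", "0", 3, 3, 7, 7, 8),
                 mother = c("0", "0", 2, 2, 2, "0", "0", "0", 6, 6, 4, 4, 5),
                 sex = c(1, 2, 1, 2, 2, 2, 1, 1, 1, 2, 1, 2, 2)),
        trio = tpl(id = 1:3, father = c("0", "0", 1), mother = c("0", "0", 2),
                   sex = c(1, 2, 1)))
}

#' Study-design configuration for the synthetic generator
#'
#' Defaults emulate the target design: 6 multiplex families (4-13 members,
#' 48 individuals) plus 7 affected-child trios, dense biallelic SNPs on one
#' chromosome, and a recessive trait locus with incomplete penetrance
#' (homozygote penetrance 0.98 by default; the weak-penetrance 0.27
#' scenario is the stress alternative).
#'
#' @param nFamilies number of multiplex families (templates are recycled
#'   beyond 6).
#' @param nTrios number of affected-child trios.
#' @param nMarkers,spacingCm marker count and spacing.
#' @param chrom chromosome label.
#' @param mafRange founder minor-allele-frequency range (uniform).
#' @param model trait \linkS4class{TraitModel}.
#' @param traitPosCm trait-locus position in cM, or \code{NA} for a trait
#'   unlinked to the markers.
#' @param missingRate per-genotype missingness probability.
#' @param mendelErrors,flips counts of injected Mendelian errors
#'   (family x marker events) and consistency-preserving genotype flips.
#' @param ascertainMinAffected a family enters the study only with at least
#'   this many affected members (trios always require an affected child).
#' @param seed master seed.
#' @export
studyConfig <- function(nFamilies = 6L, nTrios = 7L, nMarkers = 50L,
                        spacingCm = 2, chrom = "1", mafRange = c(0.05, 0.5),
                        model = traitModel(q = 0.1, f0 = 0, f1 = 0, f2 = 0.98),
                        traitPosCm = 50, missingRate = 0.02,
                        mendelErrors = 0L, flips = 0L,
                        ascertainMinAffected = 2L, seed = 1L) {
    stopifnot(missingRate >= 0, missingRate <= 1, nMarkers >= 1,
              mafRange[1] > 0, mafRange[2] <= 0.5)
    structure(list(nFamilies = nFamilies, nTrios = nTrios,
                   nMarkers = nMarkers, spacingCm = spacingCm, chrom = chrom,
                   mafRange = mafRange, model = model, traitPosCm = traitPosCm,
                   missingRate = missingRate, mendelErrors = mendelErrors,
                   flips = flips, ascertainMinAffected = ascertainMinAffected,
                   seed = seed),
              class = "studyConfig")
}

# trait-locus drop through one structure, batched over candidate draws so
# that ascertainment rejection is vectorized; returns the first accepted
# draw's disease-allele indicators, meiosis origin bits and affection
.dropTraitAscertained <- function(st, model, accept, batch = 256L,
                                  maxBatches = 2000L) {
    n <- st$n
    q <- model@q
    for (b in seq_len(maxBatches)) {
        patD <- matrix(0L, n, batch)
        matD <- matrix(0L, n, batch)
        bp <- matrix(0L, n, batch)
        bm <- matrix(0L, n, batch)
        for (i in seq_len(n)) {
            if (st$father[i] == 0L) {
                patD[i, ] <- stats::rbinom(batch, 1L, q)
                matD[i, ] <- stats::rbinom(batch, 1L, q)
            } else {
                fa <- st$father[i]; mo <- st$mother[i]
                bp[i, ] <- stats::rbinom(batch, 1L, 0.5)
                bm[i, ] <- stats::rbinom(batch, 1L, 0.5)
                patD[i, ] <- ifelse(bp[i, ] == 0L, patD[fa, ], matD[fa, ])
                matD[i, ] <- ifelse(bm[i, ] == 0L, patD[mo, ], matD[mo, ])
            }
        }
        pen <- matrix(.penetrance(model, patD, matD), n, batch)
        aff <- matrix(stats::rbinom(n * batch, 1L, pen), n, batch) + 1L
        ok <- which(accept(aff))
        if (length(ok)) {
            j <- ok[1L]
            bits <- list()
            for (i in which(st$father > 0L)) {
                bits[[paste0(i, ".1")]] <- bp[i, j]
                bits[[paste0(i, ".2")]] <- bm[i, j]
            }
            return(list(patD = patD[, j], matD = matD[, j], bits = bits,
                        aff = aff[, j]))
        }
    }
    stop("ascertainment failed; check the trait model")
}

.penetrance <- function(model, patD, matD) {
    ifelse(patD & matD, model@f2,
           ifelse(patD, model@f1pat, ifelse(matD, model@f1mat, model@f0)))
}

# marker meiosis bits conditional on the trait-locus origin bit, when linked
.markerBitsGiven <- function(traitBit, cmAll, traitIdx, mapFunction) {
    theta <- mapTheta(diff(cmAll), mapFunction)
    bits <- .meiosisBits(theta, fixedAt = traitIdx, fixedVal = traitBit)
    bits[-traitIdx]
}

#' Simulate a complete synthetic study
#'
#' Draws pedigree affection by dropping a diallelic trait locus through the
#' template structures (rejection-sampled until the ascertainment condition
#' holds, mirroring the recruitment of multiplex families), then drops the
#' markers jointly with the trait locus (recombination per the map) so that
#' linked scenarios carry real co-segregation signal.  Affected-child trios
#' are ascertained on the child.  Missingness and injected errors are
#' applied last and recorded in the truth registry.
#'
#' @param cfg a \code{\link{studyConfig}}.
#' @param mapFunction see \code{\link{mapTheta}}.
#' @return list: \code{gt} (a \linkS4class{GenotypeTable} whose
#'   \code{freq1} holds the simulation-truth frequencies), \code{truth}
#'   (trait position, model, per-individual trait genotypes, error
#'   registry).
#' @export
simulateStudy <- function(cfg = studyConfig(), mapFunction = "haldane") {
    set.seed(cfg$seed)
    M <- cfg$nMarkers
    maf <- stats::runif(M, cfg$mafRange[1], cfg$mafRange[2])
    flip <- stats::rbinom(M, 1L, 0.5) == 1L
    freq1 <- ifelse(flip, maf, 1 - maf)
    cm <- (seq_len(M) - 1L) * cfg$spacingCm
    map <- MarkerMap(data.frame(chrom = cfg$chrom,
                                marker = sprintf("snp%04d", seq_len(M)),
                                cm = cm, bp = cm * 1e6 + 1))
    linked <- !is.na(cfg$traitPosCm)
    if (linked) {
        cmAll <- sort(c(cm, cfg$traitPosCm))
        traitIdx <- which(cmAll == cfg$traitPosCm)[1]
    }
    theta <- mapTheta(diff(cm), mapFunction)
    tpl <- pedigreeTemplates()
    famNames <- sprintf("F%d", seq_len(cfg$nFamilies))
    trioNames <- if (cfg$nTrios > 0) sprintf("T%d", seq_len(cfg$nTrios)) else character(0)
    pedRows <- list()
    genoCols <- list()
    truthRows <- list()
    simulateUnit <- function(structDf, fam, accept) {
        st <- .famStruct(cbind(family = fam, structDf,
                               affection = 0L), fam)
        tr <- .dropTraitAscertained(st, cfg$model, accept)
        aff <- tr$aff
        n <- st$n
        P2 <- matrix(0L, n, M); M2 <- matrix(0L, n, M)
        for (i in seq_len(n)) {
            if (st$father[i] == 0L) {
                P2[i, ] <- stats::rbinom(M, 1L, 1 - freq1)
                M2[i, ] <- stats::rbinom(M, 1L, 1 - freq1)
            } else {
                for (side in 1:2) {
                    par <- if (side == 1L) st$father[i] else st$mother[i]
                    bits <- if (linked)
                        .markerBitsGiven(tr$bits[[paste0(i, ".", side)]],
                                         cmAll, traitIdx, mapFunction)
                    else .meiosisBits(theta)
                    src <- ifelse(bits == 0L, P2[par, ], M2[par, ])
                    if (side == 1L) P2[i, ] <- src else M2[i, ] <- src
                }
            }
        }
        list(st = st, aff = aff, geno = P2 + M2, patD = tr$patD, matD = tr$matD)
    }
    units <- list()
    minAff <- cfg$ascertainMinAffected
    for (k in seq_len(cfg$nFamilies)) {
        structDf <- tpl[[((k - 1L) %% 6L) + 1L]]
        units[[famNames[k]]] <- simulateUnit(
            structDf, famNames[k],
            function(aff) colSums(aff == 2L) >= minAff)
    }
    for (k in seq_along(trioNames))     # ascertained on the affected child
        units[[trioNames[k]]] <- simulateUnit(tpl$trio, trioNames[k],
                                              function(aff) aff[3L, ] == 2L)
    for (fam in names(units)) {
        u <- units[[fam]]
        st <- u$st
        pedRows[[fam]] <- data.frame(
            family = fam, id = st$ids,
            father = ifelse(st$father == 0L, NA_character_,
                            st$ids[pmax(st$father, 1L)]),
            mother = ifelse(st$mother == 0L, NA_character_,
                            st$ids[pmax(st$mother, 1L)]),
            sex = st$sex, affection = u$aff,
            role = if (startsWith(fam, "T")) "trio" else "family")
        gm <- t(u$geno)
        colnames(gm) <- paste(fam, st$ids, sep = ":")
        genoCols[[fam]] <- gm
        truthRows[[fam]] <- data.frame(family = fam, id = st$ids,
                                       patD = u$patD, matD = u$matD)
    }
    ped <- PedigreeSet(do.call(rbind, pedRows))
    geno <- do.call(cbind, genoCols)
    rownames(geno) <- map@map$marker
    # missingness mask
    if (cfg$missingRate > 0) {
        mask <- matrix(stats::runif(length(geno)) < cfg$missingRate,
                       nrow(geno), ncol(geno))
        geno[mask] <- NA_integer_
    }
    gt <- GenotypeTable(geno, ped, map, freq1 = freq1)
    truth <- list(traitPos = cfg$traitPosCm, model = cfg$model,
                  traitGeno = do.call(rbind, truthRows),
                  errors = data.frame(family = character(), id = character(),
                                      marker = character(), kind = character(),
                                      oldCode = integer(), newCode = integer()))
    if (cfg$mendelErrors > 0L || cfg$flips > 0L) {
        inj <- injectErrors(gt, truth, nMendel = cfg$mendelErrors,
                            nFlips = cfg$flips, seed = cfg$seed + 1L)
        gt <- inj$gt
        truth <- inj$truth
    }
    list(gt = gt, truth = truth)
}

# uniquely determinable transmitted alleles (allele-2 indicators c(from
# father, from mother)) for one typed trio at one marker; NULL if ambiguous
# or inconsistent
.detTransmission <- function(gf, gm, gc) {
    if (gf == 1L && gm == 1L) return(NULL)
    if (gf == 1L || gm == 1L) {
        hom <- if (gf == 1L) gm else gf
        h2 <- hom %/% 2L
        t2 <- gc - h2
        if (t2 < 0L || t2 > 1L) return(NULL)
        if (gf == 1L) c(t2, h2) else c(h2, t2)
    } else {
        tf <- gf %/% 2L; tm <- gm %/% 2L
        if (tf + tm != gc) return(NULL)
        c(tf, tm)
    }
}

#' Inject genotyping errors into a synthetic study
#'
#' Mendelian errors resample a child genotype to one that is incompatible
#' with its parents' genotypes (at family x marker events where such a
#' genotype exists); flips change a genotype to a different value while
#' keeping the family Mendelian-consistent at that marker, which at dense
#' markers manufactures unlikely double recombinants.  All corrupted cells
#' are recorded in the truth registry.
#'
#' @param gt a \linkS4class{GenotypeTable}.
#' @param truth truth list from \code{\link{simulateStudy}} (or \code{NULL}).
#' @param nMendel number of Mendelian-error events.
#' @param nFlips number of consistency-preserving flips.
#' @param seed RNG seed.
#' @return list: \code{gt} (corrupted), \code{truth} (registry updated).
#' @export
injectErrors <- function(gt, truth = NULL, nMendel = 0L, nFlips = 0L,
                         seed = 1L) {
    set.seed(seed)
    if (is.null(truth))
        truth <- list(errors = data.frame(family = character(), id = character(),
                                          marker = character(), kind = character(),
                                          oldCode = integer(), newCode = integer()))
    g <- assay(gt, "geno")
    pedDf <- as.data.frame(colData(gt))
    keys <- rownames(colData(gt))
    registry <- list(truth$errors)
    structs <- lapply(unique(pedDf$family), function(f) .famStruct(pedDf, f))
    names(structs) <- unique(pedDf$family)
    # candidate (family, marker, child) cells where a Mendelian error exists
    if (nMendel > 0L) {
        cand <- list()
        for (st in structs) {
            kids <- which(st$father > 0L)
            for (i in kids) {
                fk <- st$keys[st$father[i]]; mk <- st$keys[st$mother[i]]
                for (m in seq_len(nrow(g))) {
                    gf <- g[m, fk]; gm <- g[m, mk]
                    if (is.na(gf) || is.na(gm) || is.na(g[m, st$keys[i]])) next
                    if (gf == 1L && gm == 1L) next   # any genotype compatible
                    cand[[length(cand) + 1L]] <- c(st$family, st$ids[i],
                                                   rownames(g)[m])
                }
            }
        }
        if (length(cand) < nMendel)
            stop("not enough candidate cells for Mendelian-error injection")
        cm <- do.call(rbind, cand)
        # at most one injection per family x marker event
        ev <- paste(cm[, 1], cm[, 3])
        pick <- sample(seq_len(nrow(cm)))
        pick <- pick[!duplicated(ev[pick])][seq_len(nMendel)]
        for (k in pick) {
            fam <- cm[k, 1]; id <- cm[k, 2]; mk <- cm[k, 3]
            st <- structs[[fam]]
            i <- match(id, st$ids)
            gf <- g[mk, st$keys[st$father[i]]]; gm <- g[mk, st$keys[st$mother[i]]]
            bad <- setdiff(0:2, .offspringSet(gf, gm))
            newCode <- if (length(bad) == 1L) bad else sample(bad, 1L)
            key <- paste(fam, id, sep = ":")
            registry[[length(registry) + 1L]] <- data.frame(
                family = fam, id = id, marker = mk, kind = "mendel",
                oldCode = g[mk, key], newCode = newCode)
            g[mk, key] <- newCode
        }
    }
    if (nFlips > 0L) {
        # a flip is injected only where it demonstrably switches one
        # parent's transmitted allele against agreeing determinable
        # transmissions at the immediately adjacent markers, so that it
        # manufactures a tight double recombinant
        cand <- list()
        for (st in structs) {
            kids <- which(st$father > 0L)
            for (i in kids) {
                ck <- st$keys[i]
                fk <- st$keys[st$father[i]]; mk <- st$keys[st$mother[i]]
                for (m in 2:(nrow(g) - 1L)) {
                    gf <- g[m, fk]; gm <- g[m, mk]; gc <- g[m, ck]
                    if (anyNA(c(gf, gm, gc))) next
                    side <- if (gf == 1L && gm != 1L) 1L
                            else if (gm == 1L && gf != 1L) 2L else next
                    tNow <- .detTransmission(gf, gm, gc)
                    if (is.null(tNow)) next
                    # a flank is phase-informative only when the same parent
                    # is heterozygous there (and the other parent homozygous)
                    flank <- function(k) {
                        if (anyNA(c(g[k, fk], g[k, mk], g[k, ck])))
                            return(NA_integer_)
                        het <- if (side == 1L) g[k, fk] == 1L && g[k, mk] != 1L
                               else g[k, mk] == 1L && g[k, fk] != 1L
                        if (!het) return(NA_integer_)
                        d <- .detTransmission(g[k, fk], g[k, mk], g[k, ck])
                        if (is.null(d)) NA_integer_ else d[side]
                    }
                    tL <- flank(m - 1L)
                    tR <- flank(m + 1L)
                    if (is.na(tL) || is.na(tR) || tL != tR) next
                    if (tNow[side] != tL) next   # already recombinant here
                    # require the parent's phase at m to be pinned by at
                    # least one sibling with determinable transmissions
                    # across the same span, so the flip cannot be absorbed
                    # by re-phasing the parent
                    sibs <- setdiff(kids[st$father[kids] == st$father[i] &
                                         st$mother[kids] == st$mother[i]], i)
                    support <- FALSE
                    for (sb in sibs) {
                        sk <- st$keys[sb]
                        dts <- lapply((m - 1L):(m + 1L), function(k) {
                            if (anyNA(c(g[k, fk], g[k, mk], g[k, sk]))) NULL
                            else .detTransmission(g[k, fk], g[k, mk], g[k, sk])
                        })
                        if (!any(vapply(dts, is.null, logical(1)))) {
                            ts <- vapply(dts, `[`, integer(1), side)
                            if (ts[1] == ts[2] && ts[2] == ts[3]) {
                                support <- TRUE
                                break
                            }
                        }
                    }
                    if (!support) next
                    hom <- if (side == 1L) gm else gf
                    newCode <- hom %/% 2L + (1L - tL)
                    cand[[length(cand) + 1L]] <- data.frame(
                        family = st$family, id = st$ids[i],
                        marker = rownames(g)[m], key = ck,
                        oldCode = gc, newCode = newCode)
                }
            }
        }
        if (!length(cand))
            stop("no candidate cells for double-recombinant flips")
        cd <- do.call(rbind, cand)
        cd <- cd[sample.int(nrow(cd)), , drop = FALSE]
        # one flip per (person, marker) cell
        cd <- cd[!duplicated(paste(cd$key, cd$marker)), , drop = FALSE]
        done <- 0L
        usedAt <- list()   # accepted flip marker indices per family
        for (k in seq_len(nrow(cd))) {
            if (done >= nFlips) break
            st <- structs[[cd$family[k]]]
            midx <- match(cd$marker[k], rownames(g))
            prev <- usedAt[[cd$family[k]]]
            # keep flips well separated within a family so their
            # likelihood signals do not overlap
            if (!is.null(prev) && any(abs(prev - midx) <= 5L)) next
            g2 <- g[cd$marker[k], st$keys]
            g2[match(cd$key[k], st$keys)] <- cd$newCode[k]
            # the flipped person may be a parent; keep the family consistent
            if (genotypeElimination(st, g2)$incompatible) next
            g[cd$marker[k], cd$key[k]] <- cd$newCode[k]
            registry[[length(registry) + 1L]] <- data.frame(
                family = cd$family[k], id = cd$id[k], marker = cd$marker[k],
                kind = "flip", oldCode = cd$oldCode[k], newCode = cd$newCode[k])
            usedAt[[cd$family[k]]] <- c(prev, midx)
            done <- done + 1L
        }
        if (done < nFlips)
            warning(sprintf("only %d of %d flips could be injected", done, nFlips))
    }
    assay(gt, "geno") <- g
    truth$errors <- do.call(rbind, registry)
    list(gt = gt, truth = truth)
}
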