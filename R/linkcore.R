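## Multipoint likelihood engine wrappers: map functions, per-family engine
## handles around the inheritance-vector HMM, LOD scores, and the exhaustive
## small-pedigree oracle.

#' Map functions: genetic distance to recombination fraction
#'
#' Haldane: theta(d) = (1 - exp(-2 d / 100)) / 2; Kosambi:
#' theta(d) = tanh(2 d / 100) / 2, with d in centimorgan.  Both are 0 at
#' d = 0, increase monotonically, and approach 1/2.
#'
#' @param d genetic distance in cM (vectorized; negative values are treated
#'   as their absolute value).
#' @param mapFunction \code{"haldane"} (default) or \code{"kosambi"}.
#' @return recombination fraction(s) in [0, 0.5).
#' @export
mapTheta <- function(d, mapFunction = c("haldane", "kosambi")) {
    mapFunction <- match.arg(mapFunction)
    d <- abs(d) / 100
    switch(mapFunction,
           haldane = (1 - exp(-2 * d)) / 2,
           kosambi = tanh(2 * d) / 2)
}

# topologically sorted structure of one family, ready for the C++ engine
.famStruct <- function(pedDf, fam) {
    q <- pedDf[pedDf$family == fam, , drop = FALSE]
    ord <- .topoOrder(q)
    if (is.null(ord)) stop(sprintf("family %s contains a cycle", fam))
    q <- q[ord, , drop = FALSE]
    list(family = fam,
         ids = q$id,
         keys = paste(q$family, q$id, sep = ":"),
         father = ifelse(is.na(q$father), 0L, match(q$father, q$id)),
         mother = ifelse(is.na(q$mother), 0L, match(q$mother, q$id)),
         sex = q$sex,
         affection = q$affection,
         n = nrow(q))
}

# persons x markers genotype matrix for one family, topo order
.familyGeno <- function(gt, struct) {
    g <- t(assay(gt, "geno")[, struct$keys, drop = FALSE])
    storage.mode(g) <- "integer"
    g
}

.checkFreqs <- function(freq) {
    if (anyNA(freq))
        stop("allele frequencies are not set; run estimateAlleleFreqs() first")
    if (any(freq <= 0 | freq >= 1))
        stop("allele frequencies must lie strictly in (0, 1); remove monomorphic markers")
    freq
}

# scan-position geometry relative to the marker grid
.scanGeom <- function(cm, positions, mapFunction) {
    i <- findInterval(positions, cm)
    idx <- pmin(i - 1L, length(cm) - 1L)   # C convention: -1 before first
    dL <- ifelse(idx >= 0, positions - cm[pmax(idx, 0L) + 1L], 0)
    dR <- ifelse(idx < length(cm) - 1L, cm[pmin(idx + 2L, length(cm))] - positions, 0)
    list(idx = as.integer(idx),
         thetaL = mapTheta(pmax(dL, 0), mapFunction),
         thetaR = mapTheta(pmax(dR, 0), mapFunction))
}

# Build per-family engine handles (descent tables + trait key tables).
# Families, affection and marker map are fixed for the lifetime of the
# engine; genotypes are supplied per call so that gene-drop replicates can
# reuse the expensive tables.
.engineBuild <- function(gt, families = NULL, bitLimit = 20L,
                         mapFunction = "haldane") {
    rd <- rowData(gt)
    if (length(unique(rd$chrom)) != 1L)
        stop("the engine operates on one chromosome at a time; subset first")
    freq <- .checkFreqs(rd$freq1)
    cm <- rd$cm
    if (is.unsorted(cm)) stop("markers must be sorted by genetic position")
    pedDf <- as.data.frame(colData(gt))
    if (is.null(families)) families <- unique(pedDf$family)
    fams <- lapply(families, function(f) {
        st <- .famStruct(pedDf, f)
        st$xptr <- .lgBuild(st$father, st$mother, as.integer(bitLimit))
        st$K <- .lgSetAffection(st$xptr, as.integer(st$affection))
        st$keysMat <- .lgKeys(st$xptr)
        st$W0 <- .lgW0(st$xptr)
        st$nslot <- 2L * sum(st$father == 0L)
        st$nV <- .lgInfo(st$xptr)$states
        st
    })
    names(fams) <- families
    theta <- mapTheta(diff(cm), mapFunction)
    list(families = fams, cm = cm, freq = as.numeric(freq),
         theta = as.numeric(theta), mapFunction = mapFunction,
         markers = rownames(gt))
}

# per-family posterior key weights at the scan positions
.engineWeights <- function(engine, genoList, positions) {
    geom <- .scanGeom(engine$cm, positions, engine$mapFunction)
    lapply(engine$families, function(st)
        .lgScanWeights(st$xptr, genoList[[st$family]], engine$freq,
                       engine$theta, geom$idx, geom$thetaL, geom$thetaR))
}

# log-penetrance design matrix trick: phi = exp(keys %*% B + offset), with
# log(0) replaced by a very negative finite value so 0 * log(0) = 0
.phiMatrix <- function(keysMat, models, nslot) {
    lg <- function(x) log(pmax(x, 1e-300))
    q <- models["q", ]; f0 <- models["f0", ]
    f1p <- models["f1pat", ]; f1m <- models["f1mat", ]; f2 <- models["f2", ]
    fh <- (f1p + f1m) / 2                  # founder heterozygote
    B <- rbind(lg(q) - lg(1 - q),
               lg(f0), lg(f1p), lg(f1m), lg(f2), lg(fh),
               lg(1 - f0), lg(1 - f1p), lg(1 - f1m), lg(1 - f2), lg(1 - fh))
    offset <- nslot * lg(1 - q)
    exp(sweep(keysMat %*% B, 2L, offset, "+"))
}

.isDegenerate <- function(models) {
    models["f0", ] == models["f1pat", ] &
        models["f0", ] == models["f1mat", ] &
        models["f0", ] == models["f2", ]
}

# per-family LOD matrix (positions x models) from key weights; the model
# axis is processed in blocks to bound the size of the phi matrix
.lodFromWeights <- function(st, W, models) {
    nmod <- ncol(models)
    K <- nrow(st$keysMat)
    blk <- max(1L, min(nmod, as.integer(2e7 / max(K, 1L))))
    lod <- matrix(0, nrow(W), nmod)
    for (s in seq(1L, nmod, by = blk)) {
        e <- min(s + blk - 1L, nmod)
        phi <- .phiMatrix(st$keysMat, models[, s:e, drop = FALSE], st$nslot)
        L1 <- W %*% phi
        L0 <- drop(st$W0 %*% phi)
        x <- log10(sweep(L1, 2L, L0, "/"))
        x[is.nan(x)] <- -Inf
        lod[, s:e] <- x
    }
    lod[, .isDegenerate(models)] <- 0
    lod
}

#' Multipoint marker likelihood per family
#'
#' Runs the inheritance-vector HMM over all markers of one chromosome and
#' returns log10 P(marker genotypes) per family.  With all genotypes missing
#' the likelihood is exactly 1 (log10 = 0).
#'
#' @param gt single-chromosome \linkS4class{GenotypeTable} with allele
#'   frequencies set.
#' @param families family subset (default: all).
#' @param bitLimit reject families whose founder-reduced meiosis bit count
#'   (2 non-founders minus founders) exceeds this.
#' @param mapFunction see \code{\link{mapTheta}}.
#' @return named numeric vector of log10 likelihoods.
#' @export
markerLikelihood <- function(gt, families = NULL, bitLimit = 20L,
                             mapFunction = "haldane") {
    engine <- .engineBuild(gt, families, bitLimit, mapFunction)
    vapply(engine$families, function(st)
        .lgLik(st$xptr, .familyGeno(gt, st), engine$freq, engine$theta),
        numeric(1))
}

#' Posterior inheritance distribution at chromosome positions
#'
#' @inheritParams markerLikelihood
#' @param family one family id.
#' @param positions positions in cM (default: the marker positions).
#' @return matrix (positions x inheritance vectors) of posterior
#'   probabilities over the founder-symmetry-reduced inheritance vectors.
#' @export
inheritancePosterior <- function(gt, family, positions = NULL, bitLimit = 20L,
                                 mapFunction = "haldane") {
    engine <- .engineBuild(gt, family, bitLimit, mapFunction)
    if (is.null(positions)) positions <- engine$cm
    st <- engine$families[[1]]
    geom <- .scanGeom(engine$cm, positions, mapFunction)
    .lgPosterior(st$xptr, .familyGeno(gt, st), engine$freq, engine$theta,
                 geom$idx, geom$thetaL, geom$thetaR)
}

.modelMatrix <- function(model) {
    matrix(c(model@q, model@f0, model@f1pat, model@f1mat, model@f2),
           nrow = 5, dimnames = list(c("q", "f0", "f1pat", "f1mat", "f2"), NULL))
}

#' Parametric LOD score under a fixed trait model
#'
#' The multipoint LOD at each position is
#' log10 P(trait, markers | trait locus at x) - log10 (P(trait) P(markers)),
#' computed per family from the posterior inheritance distribution; the
#' total is the sum over families.  A degenerate model with equal
#' penetrances returns exactly 0 everywhere.
#'
#' @inheritParams markerLikelihood
#' @param model a \linkS4class{TraitModel}.
#' @param positions scan positions in cM (default: marker positions plus
#'   interval midpoints).
#' @return list with \code{positions}, \code{total} (LOD per position) and
#'   \code{perFamily} (positions x families; rows sum to the total).
#' @export
traitLod <- function(gt, model, positions = NULL, families = NULL,
                     bitLimit = 20L, mapFunction = "haldane", engine = NULL) {
    if (is.null(engine)) engine <- .engineBuild(gt, families, bitLimit, mapFunction)
    if (is.null(positions)) positions <- .defaultPositions(engine$cm)
    genoList <- lapply(engine$families, function(st) .familyGeno(gt, st))
    names(genoList) <- names(engine$families)
    Ws <- .engineWeights(engine, genoList, positions)
    models <- .modelMatrix(model)
    perFam <- vapply(names(engine$families), function(f)
        drop(.lodFromWeights(engine$families[[f]], Ws[[f]], models)),
        numeric(length(positions)))
    perFam <- matrix(perFam, nrow = length(positions),
                     dimnames = list(NULL, names(engine$families)))
    list(positions = positions, total = rowSums(perFam), perFamily = perFam)
}

#' Per-family LOD decomposition under a fixed model
#'
#' Evaluates, at the given position(s), each family's LOD contribution under
#' one trait model (typically the best-fitting model from a scan).  The
#' per-family values sum exactly to the total; negative contributions are
#' possible.
#'
#' @inheritParams traitLod
#' @return data.frame with one row per family plus an \code{"All"} row.
#' @export
perFamilyContributions <- function(gt, model, positions, families = NULL,
                                   bitLimit = 20L, mapFunction = "haldane") {
    r <- traitLod(gt, model, positions, families, bitLimit, mapFunction)
    out <- as.data.frame(t(r$perFamily))
    colnames(out) <- sprintf("pos_%g", r$positions)
    out <- rbind(out, All = r$total)
    out
}

.defaultPositions <- function(cm) {
    if (length(cm) == 1L) return(cm)
    sort(unique(c(cm, (cm[-1] + cm[-length(cm)]) / 2)))
}

#' Exhaustive pedigree likelihood (test oracle)
#'
#' Computes P(marker genotypes [, affection]) for one small family by brute
#' force: every person's ordered multilocus haplotype pair is enumerated
#' against HWE founder priors and per-meiosis transmission probabilities
#' with recombination between adjacent loci.  Exact up to float rounding;
#' intended as an independent cross-check of the HMM, not for production
#' use (at most 12 persons and 4 marker loci).
#'
#' @param gt single-chromosome \linkS4class{GenotypeTable}.
#' @param family family id.
#' @param model optional \linkS4class{TraitModel}; when given together with
#'   \code{traitPos} the affection status enters the likelihood through a
#'   trait locus at that cM position.
#' @param traitPos trait-locus position in cM.
#' @param markers optional marker subset (character); \code{character(0)}
#'   with a model gives P(affection) alone.
#' @param mapFunction see \code{\link{mapTheta}}.
#' @return the probability.
#' @export
bruteForceLikelihood <- function(gt, family, model = NULL, traitPos = NULL,
                                 markers = NULL, mapFunction = "haldane") {
    rd <- rowData(gt)
    if (is.null(markers)) markers <- rownames(gt)
    sel <- match(markers, rownames(gt))
    cm <- rd$cm[sel]
    freq <- rd$freq1[sel]
    pedDf <- as.data.frame(colData(gt))
    st <- .famStruct(pedDf, family)
    g <- .familyGeno(gt, st)[, sel, drop = FALSE]
    loci <- data.frame(cm = cm, type = rep(0L, length(cm)), pbit = 1 - freq)
    obs <- g
    if (!is.null(model)) {
        if (is.null(traitPos)) stop("traitPos required with a trait model")
        loci <- rbind(loci, data.frame(cm = traitPos, type = 1L, pbit = model@q))
        obs <- cbind(obs, st$affection)
        pen <- c(model@f0, model@f1pat, model@f1mat, model@f2)
    } else {
        pen <- c(0, 0, 0, 0)
    }
    if (nrow(loci) == 0L) stop("no loci selected")
    o <- order(loci$cm)
    loci <- loci[o, , drop = FALSE]
    obs <- obs[, o, drop = FALSE]
    if (nrow(loci) > 1 && any(is.na(freq)))
        stop("allele frequencies are required")
    storage.mode(obs) <- "integer"
    .bfLikelihood(st$father, st$mother, as.integer(loci$type), obs,
                  as.numeric(loci$pbit), as.numeric(pen),
                  mapTheta(diff(loci$cm), mapFunction))
}
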