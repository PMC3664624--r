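## Linkage-disequilibrium pruning: two-locus haplotype frequencies by the
## Excoffier-Slatkin EM algorithm on founder genotypes, r-squared, and a
## greedy sliding-window threshold prune.

#' Two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood haplotype frequencies for two biallelic loci from
#' unphased genotypes of unrelated individuals (founders), by
#' expectation-maximization: the only ambiguous class, the double
#' heterozygote, is split between cis (1-1 / 2-2) and trans (1-2 / 2-1)
#' configurations according to the current frequency estimates.  Started
#' from linkage equilibrium; converges when no frequency moves by more than
#' \code{tol}.
#'
#' @param gA,gB genotype codes (count of allele 2; NA missing) at the two
#'   loci for the same individuals.
#' @param tol convergence tolerance (default 1e-10).
#' @param maxit maximum EM iterations.
#' @return list with haplotype frequencies \code{p11}, \code{p12},
#'   \code{p21}, \code{p22} (first index = allele at locus A), allele
#'   frequencies \code{pA}, \code{pB} (allele 1), disequilibrium \code{D},
#'   \code{r2}, the number of complete observations \code{n}, iterations,
#'   and the attained log-likelihood with its per-iteration trace
#'   (non-decreasing, as for any EM).
#' @export
emHaplotypeFreqs <- function(gA, gB, tol = 1e-10, maxit = 1000L) {
    ok <- !is.na(gA) & !is.na(gB)
    gA <- gA[ok]; gB <- gB[ok]
    n <- length(gA)
    if (n < 2L) stop("insufficient data: fewer than 2 complete observations")
    # genotype class counts; alleles 1/2 per locus, haplotypes 11,12,21,22
    tab <- table(factor(gA, 0:2), factor(gB, 0:2))
    dh <- tab["1", "1"]            # double heterozygotes
    # every genotype class except the double heterozygote has known phase;
    # expand each into its two haplotypes
    base <- c(p11 = 0, p12 = 0, p21 = 0, p22 = 0)
    for (a in 0:2) for (b in 0:2) {
        nInd <- tab[a + 1L, b + 1L]
        if (nInd == 0 || (a == 1L && b == 1L)) next
        aAll <- c(rep(1L, 2L - a), rep(2L, a))
        bAll <- c(rep(1L, 2L - b), rep(2L, b))
        if (a == 1L) {
            # locus A het, B hom: haplotypes (1,bAll[1]) and (2,bAll[1])
            h <- c(paste0("p1", bAll[1]), paste0("p2", bAll[1]))
        } else if (b == 1L) {
            h <- c(paste0("p", aAll[1], "1"), paste0("p", aAll[1], "2"))
        } else {
            h <- c(paste0("p", aAll[1], bAll[1]), paste0("p", aAll[2], bAll[2]))
        }
        for (hh in h) base[hh] <- base[hh] + nInd
    }
    pA <- (2 * sum(tab[1, ]) + sum(tab[2, ])) / (2 * n)
    pB <- (2 * sum(tab[, 1]) + sum(tab[, 2])) / (2 * n)
    if (pA %in% c(0, 1) || pB %in% c(0, 1))
        stop("monomorphic locus: r-squared undefined")
    p <- c(p11 = pA * pB, p12 = pA * (1 - pB), p21 = (1 - pA) * pB,
           p22 = (1 - pA) * (1 - pB))
    it <- 0L
    llTrace <- .haploLogLik(p, tab)
    repeat {
        it <- it + 1L
        cis <- p["p11"] * p["p22"]
        trans <- p["p12"] * p["p21"]
        wCis <- if (cis + trans > 0) cis / (cis + trans) else 0.5
        h <- base
        h["p11"] <- h["p11"] + dh * wCis
        h["p22"] <- h["p22"] + dh * wCis
        h["p12"] <- h["p12"] + dh * (1 - wCis)
        h["p21"] <- h["p21"] + dh * (1 - wCis)
        pNew <- h / (2 * n)
        delta <- max(abs(pNew - p))
        p <- pNew
        llTrace <- c(llTrace, .haploLogLik(p, tab))
        if (delta < tol || it >= maxit) break
    }
    D <- p[["p11"]] - pA * pB
    r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
    list(p11 = p[["p11"]], p12 = p[["p12"]], p21 = p[["p21"]], p22 = p[["p22"]],
         pA = pA, pB = pB, D = D, r2 = r2, n = n, iterations = it,
         logLik = llTrace[length(llTrace)], logLikTrace = llTrace)
}

# multinomial log-likelihood of the 9 genotype classes given haplotype freqs
.haploLogLik <- function(p, tab) {
    gp <- matrix(0, 3, 3)
    hap <- rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
    for (i in 1:4) for (j in 1:4) {
        a <- (hap[i, 1] == 2) + (hap[j, 1] == 2)
        b <- (hap[i, 2] == 2) + (hap[j, 2] == 2)
        gp[a + 1, b + 1] <- gp[a + 1, b + 1] + p[i] * p[j]
    }
    sum(tab * log(pmax(gp, 1e-300)))
}

#' Pairwise r-squared between two markers from founder genotypes
#'
#' @param gt a \linkS4class{GenotypeTable}.
#' @param markerA,markerB marker ids.
#' @return the EM result of \code{\link{emHaplotypeFreqs}}.
#' @export
founderR2 <- function(gt, markerA, markerB) {
    fo <- is.na(colData(gt)$father)
    g <- assay(gt, "geno")
    emHaplotypeFreqs(g[markerA, fo], g[markerB, fo])
}

#' Greedy LD pruning at an r-squared threshold
#'
#' Markers are scanned in map order; whenever a marker is within
#' \code{windowMarkers} of an already kept marker and their founder
#' r-squared exceeds \code{threshold}, the later marker (by position) is
#' removed.  The surviving set therefore contains no within-window pair
#' above the threshold.  Pairs whose r-squared is undefined (monomorphic
#' among founders, too few complete founder genotypes) never trigger a
#' removal.
#'
#' @param gt a \linkS4class{GenotypeTable}.
#' @param threshold prune when r2 > threshold (default 0.20).
#' @param windowMarkers window size in kept markers (default 50).
#' @return list: \code{gt} (pruned), \code{kept} (marker ids),
#'   \code{removed} (marker ids), \code{pairs} (data.frame of removals:
#'   kept marker, removed marker, r2).
#' @export
pruneByLD <- function(gt, threshold = 0.20, windowMarkers = 50L) {
    fo <- is.na(colData(gt)$father)
    g <- assay(gt, "geno")[, fo, drop = FALSE]
    rd <- rowData(gt)
    ord <- order(rd$chrom, rd$bp)
    kept <- integer(0)
    pairs <- list()
    removed <- integer(0)
    for (j in ord) {
        win <- kept[rd$chrom[kept] == rd$chrom[j]]
        win <- utils::tail(win, windowMarkers)
        hit <- FALSE
        for (i in rev(win)) {
            r2 <- tryCatch(emHaplotypeFreqs(g[i, ], g[j, ])$r2,
                           error = function(e) NA_real_)
            if (!is.na(r2) && r2 > threshold) {
                pairs[[length(pairs) + 1L]] <- data.frame(
                    kept = rownames(g)[i], removed = rownames(g)[j], r2 = r2)
                hit <- TRUE
                break
            }
        }
        if (hit) removed <- c(removed, j) else kept <- c(kept, j)
    }
    kept <- sort(kept)
    list(gt = gt[kept, ],
         kept = rownames(g)[kept],
         removed = rownames(g)[sort(removed)],
         pairs = if (length(pairs)) do.call(rbind, pairs)
                 else data.frame(kept = character(), removed = character(),
                                 r2 = numeric()))
}

#' Verify a pruned marker set
#'
#' Recomputes every within-window founder r-squared among the kept markers
#' and returns the violating pairs (none after a successful prune).
#'
#' @inheritParams pruneByLD
#' @return data.frame of pairs with r2 > threshold.
#' @export
verifyPruning <- function(gt, threshold = 0.20, windowMarkers = 50L) {
    fo <- is.na(colData(gt)$father)
    g <- assay(gt, "geno")[, fo, drop = FALSE]
    rd <- rowData(gt)
    ord <- order(rd$chrom, rd$bp)
    out <- list()
    for (a in seq_along(ord)) {
        ia <- ord[a]
        upper <- min(a + windowMarkers, length(ord))
        for (b in seq_len(upper - a) + a) {
            ib <- ord[b]
            if (rd$chrom[ia] != rd$chrom[ib]) next
            r2 <- tryCatch(emHaplotypeFreqs(g[ia, ], g[ib, ])$r2,
                           error = function(e) NA_real_)
            if (!is.na(r2) && r2 > threshold)
                out[[length(out) + 1L]] <- data.frame(
                    markerA = rownames(g)[ia], markerB = rownames(g)[ib], r2 = r2)
        }
    }
    if (!length(out))
        return(data.frame(markerA = character(), markerB = character(),
                          r2 = numeric()))
    do.call(rbind, out)
}
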