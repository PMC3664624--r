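## Family-based association: transmission disequilibrium test at markers in
## linked regions, Bonferroni-adjusted over the region.

#' Transmission disequilibrium test
#'
#' Counts transmissions from heterozygous parents to affected offspring
#' across all families and trios: b transmissions of allele 1, c of allele
#' 2, McNemar chi-square (b - c)^2 / (b + c) with 1 df.  Both parents of an
#' affected child must be typed for the child to contribute; a child with
#' two heterozygous parents contributes two transmissions.  Markers with
#' b + c = 0 are untestable.
#'
#' @param gt a \linkS4class{GenotypeTable}.
#' @param markers marker subset (default all).
#' @return data.frame: marker, b, c, chi2, p, untestable.
#' @export
tdt <- function(gt, markers = NULL) {
    g <- assay(gt, "geno")
    if (is.null(markers)) markers <- rownames(g)
    p <- as.data.frame(colData(gt))
    keys <- rownames(colData(gt))
    # affected children with both parents present and typed
    kid <- which(p$affection == 2L & !is.na(p$father))
    faIdx <- match(paste(p$family[kid], p$father[kid], sep = ":"), keys)
    moIdx <- match(paste(p$family[kid], p$mother[kid], sep = ":"), keys)
    out <- data.frame(marker = markers, b = 0L, c = 0L,
                      chi2 = NA_real_, p = NA_real_, untestable = TRUE)
    for (mi in seq_along(markers)) {
        m <- markers[mi]
        gc <- g[m, kid]; gf <- g[m, faIdx]; gm <- g[m, moIdx]
        ok <- !is.na(gc) & !is.na(gf) & !is.na(gm)
        b <- 0L; c2 <- 0L
        for (k in which(ok)) {
            trans <- .transmittedAlleles(gf[k], gm[k], gc[k])
            if (is.null(trans)) next
            b <- b + trans["b"]
            c2 <- c2 + trans["c"]
        }
        out$b[mi] <- b; out$c[mi] <- c2
        if (b + c2 > 0L) {
            chi2 <- (b - c2)^2 / (b + c2)
            out$chi2[mi] <- chi2
            out$p[mi] <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
            out$untestable[mi] <- FALSE
        }
    }
    out
}

# transmissions of allele 1 (b) and allele 2 (c) from heterozygous parents,
# for one affected child; NULL when the trio is Mendelian-inconsistent
.transmittedAlleles <- function(gf, gm, gc) {
    nHet <- (gf == 1L) + (gm == 1L)
    if (nHet == 0L) return(c(b = 0L, c = 0L))
    if (nHet == 2L) {
        # both parents het: the child's two alleles are the two transmissions
        return(switch(gc + 1L, c(b = 2L, c = 0L), c(b = 1L, c = 1L),
                      c(b = 0L, c = 2L)))
    }
    # one het parent, one homozygous parent transmitting its fixed allele
    hom <- if (gf == 1L) gm else gf
    homAllele2 <- hom %/% 2L                 # allele-2 indicator transmitted
    t2 <- gc - homAllele2                    # het parent's transmitted allele
    if (t2 < 0L || t2 > 1L) return(NULL)     # inconsistent trio
    if (t2 == 1L) c(b = 0L, c = 1L) else c(b = 1L, c = 0L)
}

#' Region-wise family-based association with Bonferroni adjustment
#'
#' Runs the TDT at every marker selected by a MOD-score threshold from a
#' scan and adjusts the P values by Bonferroni with m = number of markers
#' tested in the region.
#'
#' @param gt a \linkS4class{GenotypeTable}.
#' @param scan a \linkS4class{ScanResult} over the same markers, or
#'   \code{NULL} to test an explicit \code{markers} set.
#' @param modThreshold select markers whose nearest scan position has
#'   MOD > threshold (default 2.5).
#' @param markers explicit marker set (overrides scan selection).
#' @param alpha family-wise error target for the significance column.
#' @return data.frame: marker, b, c, chi2, p, pBonferroni, significant.
#' @export
regionAssociation <- function(gt, scan = NULL, modThreshold = 2.5,
                              markers = NULL, alpha = 0.05) {
    if (is.null(markers)) {
        if (is.null(scan)) stop("supply a ScanResult or a marker set")
        cm <- rowData(gt)$cm
        nearest <- vapply(cm, function(x)
            scan@mod[which.min(abs(scan@positions - x))], numeric(1))
        markers <- rownames(gt)[nearest > modThreshold]
    }
    if (!length(markers))
        return(data.frame(marker = character(), b = integer(), c = integer(),
                          chi2 = numeric(), p = numeric(),
                          pBonferroni = numeric(), significant = logical()))
    res <- tdt(gt, markers)
    m <- length(markers)
    res$pBonferroni <- pmin(1, m * res$p)
    res$significant <- !res$untestable & res$pBonferroni <= alpha
    res
}
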