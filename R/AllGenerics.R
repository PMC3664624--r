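#' @rdname PedigreeSet-class
#' @param ped data.frame with columns family, id, father, mother, sex,
#'   affection (see the class description for codings).
#' @return a validated \code{PedigreeSet}.
#' @export
PedigreeSet <- function(ped) {
    ped$family <- as.character(ped$family)
    ped$id <- as.character(ped$id)
    ped$father <- as.character(ped$father)
    ped$mother <- as.character(ped$mother)
    ped$sex <- as.integer(ped$sex)
    ped$affection <- as.integer(ped$affection)
    rownames(ped) <- NULL
    new("PedigreeSet", ped = ped)
}

#' @rdname MarkerMap-class
#' @param map data.frame with columns chrom, marker, cm, bp.
#' @param rejected optional data.frame of markers excluded upstream.
#' @export
MarkerMap <- function(map, rejected = NULL) {
    map$chrom <- as.character(map$chrom)
    map$marker <- as.character(map$marker)
    map <- map[order(map$chrom, map$bp), , drop = FALSE]
    rownames(map) <- NULL
    if (is.null(rejected))
        rejected <- data.frame(chrom = character(), marker = character(),
                               reason = character())
    new("MarkerMap", map = map, rejected = rejected)
}

#' @rdname GenotypeTable-class
#' @param geno integer matrix, markers x individuals, each entry the count of
#'   allele 2 (0/1/2) or NA.  Row names are marker ids, column names are
#'   \code{family:id} keys.
#' @param pedigree a \code{PedigreeSet} covering every column.
#' @param map a \code{MarkerMap} covering every row.
#' @param freq1 optional per-marker frequency of allele 1.
#' @export
GenotypeTable <- function(geno, pedigree, map, freq1 = NA_real_) {
    stopifnot(is(pedigree, "PedigreeSet"), is(map, "MarkerMap"))
    p <- pedigree@ped
    m <- map@map
    keys <- paste(p$family, p$id, sep = ":")
    if (is.null(colnames(geno))) colnames(geno) <- keys
    if (is.null(rownames(geno))) rownames(geno) <- m$marker
    if (!setequal(colnames(geno), keys))
        stop("genotype columns do not match the pedigree")
    if (!setequal(rownames(geno), m$marker))
        stop("genotype rows do not match the map")
    geno <- geno[m$marker, keys, drop = FALSE]
    mode(geno) <- "integer"
    bad <- !(geno %in% c(NA, 0L, 1L, 2L))
    if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
    rd <- DataFrame(chrom = m$chrom, cm = m$cm, bp = m$bp,
                    freq1 = rep_len(as.numeric(freq1), nrow(m)),
                    row.names = m$marker)
    cd <- DataFrame(p, row.names = keys)
    se <- SummarizedExperiment(assays = list(geno = geno),
                               rowData = rd, colData = cd)
    new("GenotypeTable", se)
}

#' @rdname TraitModel-class
#' @param q disease-allele frequency.
#' @param f0,f1,f2 penetrances for 0/1/2 disease alleles.
#' @param f1pat,f1mat heterozygote penetrances by transmitting parent;
#'   default to \code{f1}.
#' @export
traitModel <- function(q, f0, f1 = NULL, f2, f1pat = f1, f1mat = f1) {
    if (is.null(f1pat) || is.null(f1mat))
        stop("supply f1 or both f1pat and f1mat")
    new("TraitModel", q = q, f0 = f0, f1pat = f1pat, f1mat = f1mat, f2 = f2)
}

#' @rdname ModGrid-class
#' @param qValues disease-allele frequency grid.
#' @param penStep penetrance grid step.
#' @param imprinting split heterozygote penetrances by parental origin.
#' @param ordered enforce f0 <= f1 <= f2.
#' @param refine simplex refinement from the best grid point.
#' @export
modGrid <- function(qValues = c(1e-4, 5e-4, 1e-3, 5e-3, 0.01, 0.05, 0.1,
                                0.2, 0.3, 0.4, 0.5),
                    penStep = if (imprinting) 0.1 else 0.05,
                    imprinting = FALSE, ordered = TRUE, refine = TRUE) {
    new("ModGrid", qValues = sort(qValues), penStep = penStep,
        imprinting = imprinting, ordered = ordered, refine = refine)
}

## ------------------------------------------------------------------ accessors

#' @export
setGeneric("pedigree", function(x, ...) standardGeneric("pedigree"))
#' @export
setGeneric("markerMap", function(x, ...) standardGeneric("markerMap"))
#' @export
setGeneric("genoMatrix", function(x, ...) standardGeneric("genoMatrix"))
#' @export
setGeneric("alleleFreqs", function(x, ...) standardGeneric("alleleFreqs"))
#' @export
setGeneric("alleleFreqs<-", function(x, value) standardGeneric("alleleFreqs<-"))
#' @export
setGeneric("callRates", function(x, ...) standardGeneric("callRates"))
#' @export
setGeneric("familyNames", function(x, ...) standardGeneric("familyNames"))
#' @export
setGeneric("founders", function(x, ...) standardGeneric("founders"))
#' @export
setGeneric("meiosisCount", function(x, ...) standardGeneric("meiosisCount"))

#' @describeIn GenotypeTable-class the pedigree as a \code{PedigreeSet}.
#' @export
setMethod("pedigree", "GenotypeTable", function(x, ...)
    PedigreeSet(as.data.frame(colData(x))))

#' @describeIn GenotypeTable-class the marker map as a \code{MarkerMap}.
#' @export
setMethod("markerMap", "GenotypeTable", function(x, ...) {
    rd <- rowData(x)
    MarkerMap(data.frame(chrom = rd$chrom, marker = rownames(x),
                         cm = rd$cm, bp = rd$bp))
})

#' @describeIn GenotypeTable-class the genotype matrix (markers x samples).
#' @export
setMethod("genoMatrix", "GenotypeTable", function(x, ...) assay(x, "geno"))

#' @describeIn GenotypeTable-class per-marker frequency of allele 1.
#' @export
setMethod("alleleFreqs", "GenotypeTable", function(x, ...) {
    f <- rowData(x)$freq1
    names(f) <- rownames(x)
    f
})

#' @describeIn GenotypeTable-class set the per-marker frequency of allele 1.
#' @export
setReplaceMethod("alleleFreqs", "GenotypeTable", function(x, value) {
    rowData(x)$freq1 <- as.numeric(value)
    x
})

#' @describeIn GenotypeTable-class per-marker call rate (typed / total).
#' @export
setMethod("callRates", "GenotypeTable", function(x, ...) {
    g <- assay(x, "geno")
    rowMeans(!is.na(g))
})

#' @describeIn PedigreeSet-class family identifiers.
#' @export
setMethod("familyNames", "PedigreeSet", function(x, ...) unique(x@ped$family))

#' @describeIn GenotypeTable-class family identifiers.
#' @export
setMethod("familyNames", "GenotypeTable", function(x, ...) unique(colData(x)$family))

#' @describeIn PedigreeSet-class logical vector marking founders.
#' @export
setMethod("founders", "PedigreeSet", function(x, ...) is.na(x@ped$father))

#' @describeIn PedigreeSet-class meioses per family (2 x non-founders).
#' @export
setMethod("meiosisCount", "PedigreeSet", function(x, ...) {
    p <- x@ped
    vapply(split(is.na(p$father), p$family), function(fo) 2L * sum(!fo),
           integer(1))[unique(p$family)]
})

#' @export
setGeneric("pedTable", function(x, ...) standardGeneric("pedTable"))
#' @describeIn PedigreeSet-class the underlying individual table.
#' @export
setMethod("pedTable", "PedigreeSet", function(x, ...) x@ped)

#' @export
setGeneric("mapTable", function(x, ...) standardGeneric("mapTable"))
#' @describeIn MarkerMap-class the underlying marker table.
#' @export
setMethod("mapTable", "MarkerMap", function(x, ...) x@map)

## ----------------------------------------------------------------------- show

setMethod("show", "PedigreeSet", function(object) {
    p <- object@ped
    cat(sprintf("PedigreeSet: %d individuals in %d famil%s (%d founders, %d affected)\n",
                nrow(p), length(unique(p$family)),
                if (length(unique(p$family)) == 1L) "y" else "ies",
                sum(is.na(p$father)), sum(p$affection == 2L)))
})

setMethod("show", "MarkerMap", function(object) {
    m <- object@map
    cat(sprintf("MarkerMap: %d markers on %d chromosome(s); %d rejected\n",
                nrow(m), length(unique(m$chrom)), nrow(object@rejected)))
})

setMethod("show", "TraitModel", function(object) {
    imp <- object@f1pat != object@f1mat
    cat(sprintf("TraitModel: q = %g, penetrances f0 = %g, %s, f2 = %g%s\n",
                object@q, object@f0,
                if (imp) sprintf("f1pat = %g, f1mat = %g", object@f1pat, object@f1mat)
                else sprintf("f1 = %g", object@f1pat),
                object@f2, if (imp) " (imprinting)" else ""))
})

setMethod("show", "ScanResult", function(object) {
    i <- which.max(object@mod)
    cat(sprintf("ScanResult: %d positions%s; peak MOD = %.3f at %.2f cM\n",
                length(object@positions),
                if (object@imprinting) " (imprinting)" else "",
                object@mod[i], object@positions[i]))
    m <- object@models[, i]
    cat(sprintf("  best model there: q = %.4g, f = (%.3g, %.3g/%.3g, %.3g)\n",
                m["q"], m["f0"], m["f1pat"], m["f1mat"], m["f2"]))
})

setMethod("show", "EmpiricalResult", function(object) {
    cat(sprintf("EmpiricalResult: observed = %.3f, R = %d replicates, r = %d, p = %g (%s)\n",
                object@observed, length(object@maxima), object@exceedances,
                object@p, object@convention))
})

setMethod("show", "QCReport", function(object) {
    cat("QCReport:\n")
    cat(sprintf("  flagged relationship pairs : %d\n", nrow(object@flaggedPairs)))
    cat(sprintf("  sex-consistency flags      : %d\n", nrow(object@sexFlags)))
    cat(sprintf("  Mendelian family x marker  : %d\n", nrow(object@mendelErrors)))
    cat(sprintf("  unlikely genotypes         : %d\n", nrow(object@unlikelyGenotypes)))
    cat(sprintf("  removed markers            : %d\n", nrow(object@removedMarkers)))
    cat(sprintf("  surviving fraction         : %.4f\n", object@survivingFraction))
})

## ---------------------------------------------------------- ScanResult access

#' @export
setGeneric("modScores", function(x, ...) standardGeneric("modScores"))
#' @describeIn ScanResult-class data.frame of position, MOD and best model.
#' @export
setMethod("modScores", "ScanResult", function(x, ...) {
    data.frame(position = x@positions, mod = x@mod,
               q = x@models["q", ], f0 = x@models["f0", ],
               f1pat = x@models["f1pat", ], f1mat = x@models["f1mat", ],
               f2 = x@models["f2", ])
})

#' @export
setGeneric("perFamilyLod", function(x, ...) standardGeneric("perFamilyLod"))
#' @describeIn ScanResult-class per-family LOD contributions (positions x
#'   families); rows sum to the MOD.
#' @export
setMethod("perFamilyLod", "ScanResult", function(x, ...) x@perFamily)
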