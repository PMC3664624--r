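#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- rowData rowData<- colData colData<-
#' @useDynLib modlink, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Pedigree structures for a set of families
#'
#' Holds one or more families as a single table of individuals.  Founders are
#' individuals whose parents are both absent (\code{NA}); all other
#' individuals must reference a male father and a female mother within the
#' same family, and the parent-child graph of each family must be acyclic.
#'
#' @slot ped \code{data.frame} with columns \code{family}, \code{id},
#'   \code{father}, \code{mother} (character, \code{NA} for founders),
#'   \code{sex} (1 = male, 2 = female) and \code{affection}
#'   (0 = unknown, 1 = unaffected, 2 = affected).
#' @export
setClass("PedigreeSet", representation(ped = "data.frame"))

setValidity("PedigreeSet", function(object) {
    p <- object@ped
    need <- c("family", "id", "father", "mother", "sex", "affection")
    if (!all(need %in% names(p)))
        return(paste("missing columns:", paste(setdiff(need, names(p)), collapse = ", ")))
    msgs <- character()
    if (anyDuplicated(paste(p$family, p$id)))
        msgs <- c(msgs, "person ids must be unique within a family")
    one <- is.na(p$father) != is.na(p$mother)
    if (any(one))
        msgs <- c(msgs, "parents must be both present or both absent")
    if (!all(p$sex %in% c(1L, 2L)))
        msgs <- c(msgs, "sex must be coded 1 (male) or 2 (female)")
    if (!all(p$affection %in% c(0L, 1L, 2L)))
        msgs <- c(msgs, "affection must be coded 0/1/2")
    for (fam in unique(p$family)) {
        q <- p[p$family == fam, ]
        for (col in c("father", "mother")) {
            ref <- q[[col]][!is.na(q[[col]])]
            if (!all(ref %in% q$id)) {
                msgs <- c(msgs, sprintf("family %s references missing parent(s)", fam))
                break
            }
        }
        fa <- q$sex[match(q$father, q$id)]
        mo <- q$sex[match(q$mother, q$id)]
        if (any(fa == 2L, na.rm = TRUE)) msgs <- c(msgs, sprintf("family %s: father is female", fam))
        if (any(mo == 1L, na.rm = TRUE)) msgs <- c(msgs, sprintf("family %s: mother is male", fam))
        if (is.null(.topoOrder(q))) msgs <- c(msgs, sprintf("family %s: pedigree contains a cycle", fam))
    }
    if (length(msgs)) msgs else TRUE
})

#' Genetic marker map
#'
#' Marker positions on one or more chromosomes.  Within a chromosome the
#' markers are kept sorted by physical position and the genetic position must
#' be non-decreasing in that order.  Markers lacking a genetic position are
#' rejected at read time (see \code{\link{readMap}}) and reported in the
#' \code{rejected} slot.
#'
#' @slot map \code{data.frame} with columns \code{chrom}, \code{marker},
#'   \code{cm} (sex-averaged genetic position, centimorgan) and \code{bp}
#'   (1-based physical position).
#' @slot rejected \code{data.frame} of markers dropped at read time with a
#'   \code{reason} column.
#' @export
setClass("MarkerMap", representation(map = "data.frame", rejected = "data.frame"),
         prototype(rejected = data.frame(chrom = character(), marker = character(),
                                         reason = character())))

setValidity("MarkerMap", function(object) {
    m <- object@map
    need <- c("chrom", "marker", "cm", "bp")
    if (!all(need %in% names(m))) return("map needs columns chrom, marker, cm, bp")
    if (anyDuplicated(m$marker)) return("duplicated marker ids")
    if (anyNA(m$cm)) return("markers with missing genetic position must be rejected upstream")
    for (ch in unique(m$chrom)) {
        q <- m[m$chrom == ch, ]
        if (is.unsorted(q$bp)) return(sprintf("chromosome %s not sorted by bp", ch))
        d <- diff(q$cm)
        if (any(d < 0)) {
            i <- which(d < 0)[1]
            return(sprintf("non-monotone genetic position on chromosome %s between %s and %s",
                           ch, q$marker[i], q$marker[i + 1]))
        }
    }
    TRUE
})

#' Biallelic genotypes with pedigree and map annotation
#'
#' A \linkS4class{SummarizedExperiment} with markers as rows and individuals
#' as columns.  The single assay \code{"geno"} stores each genotype as the
#' count of allele 2 (0, 1, 2) with \code{NA} for missing.  \code{rowData}
#' carries the marker map (\code{chrom}, \code{cm}, \code{bp}) plus the
#' per-marker frequency of allele 1 (\code{freq1}, \code{NA} until estimated
#' by \code{\link{estimateAlleleFreqs}} or supplied as simulation truth);
#' \code{colData} carries the pedigree columns of \linkS4class{PedigreeSet}.
#'
#' @export
setClass("GenotypeTable", contains = "SummarizedExperiment")

#' Parametric trait model
#'
#' A diallelic trait locus: disease-allele frequency \code{q} and penetrances
#' for 0, 1 and 2 copies of the disease allele.  Under genomic imprinting the
#' heterozygote penetrance is split by the parent that transmitted the
#' disease allele (\code{f1pat}: from the father, \code{f1mat}: from the
#' mother); without imprinting the two are equal.
#'
#' @export
setClass("TraitModel", representation(q = "numeric", f0 = "numeric",
                                      f1pat = "numeric", f1mat = "numeric",
                                      f2 = "numeric"))

setValidity("TraitModel", function(object) {
    v <- c(object@f0, object@f1pat, object@f1mat, object@f2)
    if (object@q <= 0 || object@q >= 1) return("q must lie strictly in (0, 1)")
    if (any(v < 0 | v > 1)) return("penetrances must lie in [0, 1]")
    TRUE
})

#' Trait-model search grid for MOD scores
#'
#' Defines the discrete model space over which the LOD is maximized at each
#' position, plus an optional box-constrained downhill-simplex refinement
#' started from the best grid point.
#'
#' @slot qValues disease-allele frequencies to explore.
#' @slot penStep step of the penetrance grid on [0, 1].
#' @slot imprinting if \code{TRUE}, heterozygote penetrances are split by
#'   parental origin (\code{f0 <= min(f1mat, f1pat)},
#'   \code{max(f1mat, f1pat) <= f2} when \code{ordered}).
#' @slot ordered enforce \code{f0 <= f1 <= f2} in the grid and refinement.
#' @slot refine run the simplex refinement from the best grid point.
#' @export
setClass("ModGrid", representation(qValues = "numeric", penStep = "numeric",
                                   imprinting = "logical", ordered = "logical",
                                   refine = "logical"))

#' Result of a MOD-score scan
#'
#' Per scan position: the MOD score, the best-fitting trait model, and the
#' per-family LOD contributions under that model (these sum to the MOD).
#'
#' @export
setClass("ScanResult", representation(positions = "numeric", mod = "numeric",
                                      models = "matrix", perFamily = "matrix",
                                      imprinting = "logical"))

#' Gene-dropping empirical significance result
#'
#' @slot observed observed scan statistic (maximum MOD over the region).
#' @slot maxima per-replicate scan maxima.
#' @slot exceedances number of replicates with maximum >= observed.
#' @slot p empirical P value (exceedances / replicates, or the
#'   \code{(r+1)/(R+1)} variant).
#' @slot masterSeed seed from which replicate streams were derived.
#' @slot convention \code{"r/R"} or \code{"(r+1)/(R+1)"}.
#' @export
setClass("EmpiricalResult", representation(observed = "numeric", maxima = "numeric",
                                           exceedances = "integer", p = "numeric",
                                           masterSeed = "integer",
                                           convention = "character"))

#' Quality-control report
#'
#' @slot flaggedPairs within-family pairs whose identity-by-state profile is
#'   inconsistent with the claimed relationship.
#' @slot sexFlags individuals whose X-marker heterozygosity contradicts the
#'   declared sex.
#' @slot mendelErrors family-by-marker Mendelian incompatibilities.
#' @slot unlikelyGenotypes genotypes implying unlikely double recombinants.
#' @slot removedMarkers markers removed by the marker filters, with one
#'   primary reason each.
#' @slot survivingFraction kept / (kept + removed) markers.
#' @export
setClass("QCReport", representation(flaggedPairs = "data.frame",
                                    sexFlags = "data.frame",
                                    mendelErrors = "data.frame",
                                    unlikelyGenotypes = "data.frame",
                                    removedMarkers = "data.frame",
                                    survivingFraction = "numeric"))
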