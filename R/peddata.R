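## Pedigree / genotype / map file handling (pre-makeped LINKAGE dialect).

# topological order of one family's individuals (founders first, parents
# before children); NULL if the parent-child graph has a cycle
.topoOrder <- function(fam) {
    n <- nrow(fam)
    placed <- logical(n)
    ord <- integer(0)
    repeat {
        ready <- !placed &
            (is.na(fam$father) | fam$father %in% fam$id[placed]) &
            (is.na(fam$mother) | fam$mother %in% fam$id[placed])
        if (!any(ready)) break
        ord <- c(ord, which(ready))
        placed[ready] <- TRUE
    }
    if (!all(placed)) NULL else ord
}

#' Read a pre-makeped PED file
#'
#' Whitespace-delimited text, one individual per line: family id, person id,
#' father id, mother id (0 = absent), sex (1 = male, 2 = female), affection
#' (2 = affected, 1 = unaffected, 0 = unknown), then two allele columns per
#' marker.  Alleles are 1/2 with 0 for missing; base letters (A/C/G/T) are
#' recoded to 1/2 by lexical order per marker.  A genotype with either allele
#' missing is treated as missing.
#'
#' @param pedPath path to the PED file.
#' @param mapPath path to the matching MAP file (see \code{\link{readMap}}).
#' @return a \linkS4class{GenotypeTable}.
#' @export
readPed <- function(pedPath, mapPath) {
    map <- readMap(mapPath)
    lines <- readLines(pedPath)
    lines <- lines[nzchar(trimws(lines))]
    tok <- strsplit(trimws(lines), "[ \t]+")
    ncols <- lengths(tok)
    if (length(unique(ncols)) != 1L) stop("ragged PED file")
    nc <- ncols[1]
    if (nc < 8L || (nc - 6L) %% 2L != 0L)
        stop("PED file must have 6 leading columns plus an even number of allele columns")
    nm <- (nc - 6L) %/% 2L
    if (nm != nrow(map@map))
        stop(sprintf("PED has %d markers but MAP has %d", nm, nrow(map@map)))
    m <- do.call(rbind, tok)
    sex <- suppressWarnings(as.integer(m[, 5]))
    if (!all(sex %in% c(1L, 2L))) stop("unknown sex code in PED file")
    affRaw <- suppressWarnings(as.integer(m[, 6]))
    if (!all(affRaw %in% c(0L, 1L, 2L))) stop("unknown affection code in PED file")
    ped <- PedigreeSet(data.frame(
        family = m[, 1], id = m[, 2],
        father = ifelse(m[, 3] == "0", NA_character_, m[, 3]),
        mother = ifelse(m[, 4] == "0", NA_character_, m[, 4]),
        sex = sex, affection = affRaw))
    al <- m[, -(1:6), drop = FALSE]
    geno <- matrix(NA_integer_, nm, nrow(m))
    for (j in seq_len(nm)) {
        a1 <- al[, 2L * j - 1L]
        a2 <- al[, 2L * j]
        lev <- sort(setdiff(unique(c(a1, a2)), "0"))
        if (length(lev) > 2L)
            stop(sprintf("marker %d: more than two alleles", j))
        if (!all(lev %in% c("1", "2"))) {
            a1 <- as.character(match(a1, lev))
            a2 <- as.character(match(a2, lev))
            a1[is.na(a1)] <- "0"; a2[is.na(a2)] <- "0"
        }
        if (!all(c(a1, a2) %in% c("0", "1", "2")))
            stop(sprintf("marker %d: allele symbol outside {0,1,2}", j))
        miss <- a1 == "0" | a2 == "0"
        g <- (a1 == "2") + (a2 == "2")
        g[miss] <- NA_integer_
        geno[j, ] <- as.integer(g)
    }
    rownames(geno) <- map@map$marker
    colnames(geno) <- paste(m[, 1], m[, 2], sep = ":")
    GenotypeTable(geno, ped, map)
}

#' Write a pre-makeped PED file
#'
#' @param gt a \linkS4class{GenotypeTable}.
#' @param path output file.
#' @export
writePed <- function(gt, path) {
    p <- as.data.frame(colData(gt))
    g <- assay(gt, "geno")
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, "2", "1"))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2L, "2", "1"))
    nI <- ncol(g)
    al <- matrix("", 2L * nrow(g), nI)
    al[seq(1, nrow(al), 2), ] <- a1
    al[seq(2, nrow(al), 2), ] <- a2
    lines <- vapply(seq_len(nI), function(i) {
        paste(c(p$family[i], p$id[i],
                ifelse(is.na(p$father[i]), "0", p$father[i]),
                ifelse(is.na(p$mother[i]), "0", p$mother[i]),
                p$sex[i], p$affection[i], al[, i]), collapse = " ")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a 4-column MAP file
#'
#' Columns: chromosome, marker id, genetic position (cM), physical position
#' (bp).  Markers are grouped by chromosome and sorted by physical position;
#' the genetic position must be non-decreasing in that order.  Markers whose
#' genetic position is missing (\code{NA}, \code{.} or \code{-}) are put in
#' the rejected set rather than the map.
#'
#' @param path path to the MAP file.
#' @return a \linkS4class{MarkerMap} (rejected markers in its
#'   \code{rejected} slot).
#' @export
readMap <- function(path) {
    raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                             col.names = c("chrom", "marker", "cm", "bp"))
    cm <- suppressWarnings(as.numeric(ifelse(raw$cm %in% c("NA", ".", "-", ""),
                                             NA, raw$cm)))
    bp <- as.numeric(raw$bp)
    bad <- is.na(cm)
    rejected <- data.frame(chrom = raw$chrom[bad], marker = raw$marker[bad],
                           reason = rep("no_position", sum(bad)))
    MarkerMap(data.frame(chrom = raw$chrom[!bad], marker = raw$marker[!bad],
                         cm = cm[!bad], bp = bp[!bad]),
              rejected = rejected)
}

#' Write a 4-column MAP file
#'
#' @param map a \linkS4class{MarkerMap} or \linkS4class{GenotypeTable}.
#' @param path output file.
#' @export
writeMap <- function(map, path) {
    if (is(map, "GenotypeTable")) map <- markerMap(map)
    m <- map@map
    utils::write.table(m[, c("chrom", "marker", "cm", "bp")], path,
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Structural validation of pedigrees
#'
#' Report-only check for cycles, one-parent individuals, sex-role conflicts
#' and members disconnected from the rest of their family.  Unlike the class
#' validity check this never throws; it is meant for data triage.
#'
#' @param ped a \code{PedigreeSet} or its underlying data.frame.
#' @return data.frame with columns \code{family}, \code{person},
#'   \code{issue}; zero rows when the pedigrees are clean.
#' @export
validatePedigrees <- function(ped) {
    p <- if (is(ped, "PedigreeSet")) ped@ped else ped
    out <- list()
    add <- function(fam, person, issue)
        out[[length(out) + 1L]] <<- data.frame(family = fam, person = person,
                                               issue = issue)
    for (fam in unique(p$family)) {
        q <- p[p$family == fam, ]
        one <- is.na(q$father) != is.na(q$mother)
        for (i in which(one)) add(fam, q$id[i], "one_parent")
        for (i in seq_len(nrow(q))) {
            fa <- q$father[i]
            mo <- q$mother[i]
            if (!is.na(fa) && fa %in% q$id && q$sex[match(fa, q$id)] == 2L)
                add(fam, q$id[i], "father_is_female")
            if (!is.na(mo) && mo %in% q$id && q$sex[match(mo, q$id)] == 1L)
                add(fam, q$id[i], "mother_is_male")
            if (!is.na(fa) && !(fa %in% q$id)) add(fam, q$id[i], "missing_father")
            if (!is.na(mo) && !(mo %in% q$id)) add(fam, q$id[i], "missing_mother")
        }
        ord <- .topoOrder(q)
        if (is.null(ord)) {
            # every person not reachable in topological order is on/behind a cycle
            placed <- logical(nrow(q))
            repeat {
                ready <- !placed &
                    (is.na(q$father) | q$father %in% q$id[placed]) &
                    (is.na(q$mother) | q$mother %in% q$id[placed])
                if (!any(ready)) break
                placed[ready] <- TRUE
            }
            for (i in which(!placed)) add(fam, q$id[i], "cycle")
        }
        # connectivity: undirected parent-child graph
        if (nrow(q) > 1L) {
            idx <- seq_len(nrow(q))
            adj <- vector("list", nrow(q))
            for (i in idx) {
                fa <- match(q$father[i], q$id)
                mo <- match(q$mother[i], q$id)
                for (pa in c(fa, mo)) if (!is.na(pa)) {
                    adj[[i]] <- c(adj[[i]], pa)
                    adj[[pa]] <- c(adj[[pa]], i)
                }
            }
            comp <- rep(NA_integer_, nrow(q))
            cid <- 0L
            for (i in idx) if (is.na(comp[i])) {
                cid <- cid + 1L
                queue <- i
                comp[i] <- cid
                while (length(queue)) {
                    v <- queue[[1]]
                    queue <- queue[-1]
                    for (w in adj[[v]]) if (is.na(comp[w])) {
                        comp[w] <- cid
                        queue <- c(queue, w)
                    }
                }
            }
            main <- which.max(tabulate(comp))
            for (i in which(comp != main)) add(fam, q$id[i], "disconnected")
        }
    }
    if (!length(out))
        return(data.frame(family = character(), person = character(),
                          issue = character()))
    do.call(rbind, out)
}

#' Write a validation report as TSV
#' @param report data.frame from \code{\link{validatePedigrees}}.
#' @param path output file.
#' @export
writeValidationReport <- function(report, path) {
    utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
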