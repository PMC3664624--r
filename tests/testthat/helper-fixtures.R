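# Shared fixture builders: all synthetic, generated in code at test time.

# random loop-free pedigree: start from a founder couple; each new member is
# either a child of an existing couple or a married-in founder spouse
randomPedigree <- function(n, famName = "F") {
    id <- c("1", "2"); father <- c(NA, NA); mother <- c(NA, NA)
    sex <- c(1L, 2L)
    couples <- list(c(1L, 2L))
    i <- 2L
    while (i < n) {
        if (stats::runif(1) < 0.35 && i + 2L <= n && length(id) > 2L) {
            p <- sample.int(length(id), 1L)
            i <- i + 1L
            id <- c(id, as.character(i))
            father <- c(father, NA); mother <- c(mother, NA)
            sex <- c(sex, if (sex[p] == 1L) 2L else 1L)
            couples[[length(couples) + 1L]] <-
                if (sex[p] == 1L) c(p, length(id)) else c(length(id), p)
        }
        if (i < n) {
            cp <- couples[[sample.int(length(couples), 1L)]]
            i <- i + 1L
            id <- c(id, as.character(i))
            father <- c(father, id[cp[1]]); mother <- c(mother, id[cp[2]])
            sex <- c(sex, sample(1:2, 1L))
        }
    }
    data.frame(family = famName, id = id, father = father, mother = mother,
               sex = sex, affection = sample(0:2, length(id), replace = TRUE))
}

# genotype table for one pedigree with gene-dropped genotypes and optional
# random missingness
droppedGT <- function(ped, cm, freq, seed, missing = 0.15) {
    M <- length(cm)
    map <- MarkerMap(data.frame(chrom = "1", marker = sprintf("m%d", seq_len(M)),
                                cm = cm, bp = seq_len(M)))
    keys <- paste(ped$family, ped$id, sep = ":")
    g <- matrix(0L, M, nrow(ped),
                dimnames = list(map@map$marker, keys))
    gt <- GenotypeTable(g, PedigreeSet(ped), map, freq1 = freq)
    gt <- geneDrop(gt, seed = seed)
    if (missing > 0) {
        gm <- genoMatrix(gt)
        gm[stats::runif(length(gm)) < missing] <- NA_integer_
        SummarizedExperiment::assay(gt, "geno") <- gm
    }
    gt
}

# small hand-built genotype table
handGT <- function(ped, genoByMarker, freq, cm = NULL) {
    M <- nrow(genoByMarker)
    if (is.null(cm)) cm <- (seq_len(M) - 1)
    map <- MarkerMap(data.frame(chrom = "1", marker = rownames(genoByMarker),
                                cm = cm, bp = seq_len(M)))
    colnames(genoByMarker) <- paste(ped$family, ped$id, sep = ":")
    GenotypeTable(genoByMarker, PedigreeSet(ped), map, freq1 = freq)
}

# exhaustive genotype-set enumeration (single-marker Mendelian oracle)
bruteGenotypeSets <- function(st, geno) {
    opts <- lapply(seq_len(st$n), function(i)
        if (is.na(geno[i])) 0:2 else geno[i])
    grids <- do.call(expand.grid, opts)
    okRow <- function(gv) {
        for (i in which(st$father > 0L)) {
            O <- modlink:::.offspringSet(gv[[st$father[i]]], gv[[st$mother[i]]])
            if (!(gv[[i]] %in% O)) return(FALSE)
        }
        TRUE
    }
    ok <- apply(grids, 1L, function(r) okRow(as.list(r)))
    sets <- lapply(seq_len(st$n), function(i)
        sort(unique(as.integer(grids[ok, i]))))
    names(sets) <- st$ids
    list(sets = sets, incompatible = !any(ok))
}

# exhaustive two-locus LOD oracle built from three brute-force likelihoods
bruteTraitLod <- function(gt, family, model, pos) {
    pj <- bruteForceLikelihood(gt, family, model = model, traitPos = pos)
    pm <- bruteForceLikelihood(gt, family)
    pt <- bruteForceLikelihood(gt, family, model = model, traitPos = pos,
                               markers = character(0))
    log10(pj / (pm * pt))
}
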