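## MOD-score scan: per-position maximization of the LOD over trait-model
## parameters (disease-allele frequency and penetrances), optionally with
## parent-of-origin (imprinting) heterozygote penetrances.

# enumerate the grid as a 5 x nmod matrix, columns sorted so that ties are
# broken toward smaller q, then smaller f2 (max.col with ties = "first")
.gridModels <- function(grid) {
    pen <- unique(c(seq(0, 1, by = grid@penStep), 1))
    q <- grid@qValues
    if (grid@imprinting) {
        g <- expand.grid(f0 = pen, f1pat = pen, f1mat = pen, f2 = pen)
        if (grid@ordered)
            g <- g[g$f0 <= pmin(g$f1pat, g$f1mat) &
                   pmax(g$f1pat, g$f1mat) <= g$f2, , drop = FALSE]
    } else {
        g <- expand.grid(f0 = pen, f1 = pen, f2 = pen)
        if (grid@ordered)
            g <- g[g$f0 <= g$f1 & g$f1 <= g$f2, , drop = FALSE]
        g$f1pat <- g$f1
        g$f1mat <- g$f1
        g$f1 <- NULL
    }
    g <- merge(data.frame(q = q), g)
    g <- g[order(g$q, g$f2, g$f1pat, g$f1mat, g$f0), , drop = FALSE]
    t(as.matrix(g[, c("q", "f0", "f1pat", "f1mat", "f2")]))
}

# ordered box-constrained parameterization for the simplex refinement
.packModel <- function(m, imprinting) {
    eps <- 1e-6
    cl <- function(x) pmin(pmax(x, eps), 1 - eps)
    q <- cl(m["q"]); f0 <- cl(m["f0"]); f2v <- cl(m["f2"])
    if (f2v <= f0) f2v <- min(f0 + eps, 1 - eps / 2)
    inner <- function(f1) {
        u <- (f1 - f0) / (f2v - f0)
        stats::qlogis(cl(u))
    }
    base <- c(stats::qlogis(q), stats::qlogis(f0),
              stats::qlogis((f2v - f0) / (1 - f0)))
    if (imprinting) c(base, inner(m["f1pat"]), inner(m["f1mat"]))
    else c(base, inner(m["f1pat"]))
}

.unpackModel <- function(t, imprinting) {
    q <- stats::plogis(t[1])
    f0 <- stats::plogis(t[2])
    f2 <- f0 + (1 - f0) * stats::plogis(t[3])
    if (imprinting) {
        f1p <- f0 + (f2 - f0) * stats::plogis(t[4])
        f1m <- f0 + (f2 - f0) * stats::plogis(t[5])
    } else {
        f1p <- f1m <- f0 + (f2 - f0) * stats::plogis(t[4])
    }
    c(q = q, f0 = f0, f1pat = f1p, f1mat = f1m, f2 = f2)
}

# total LOD at one position for an arbitrary model, from stored key weights
.lodAt <- function(engine, Ws, p, modelVec) {
    mm <- matrix(modelVec, nrow = 5,
                 dimnames = list(c("q", "f0", "f1pat", "f1mat", "f2"), NULL))
    tot <- 0
    for (f in names(engine$families)) {
        st <- engine$families[[f]]
        lod <- .lodFromWeights(st, Ws[[f]][p, , drop = FALSE], mm)
        tot <- tot + lod[1, 1]
    }
    tot
}

.refinePosition <- function(engine, Ws, p, startModel, imprinting, maxit = 200) {
    t0 <- .packModel(startModel, imprinting)
    fn <- function(t) {
        v <- .lodAt(engine, Ws, p, .unpackModel(t, imprinting))
        if (!is.finite(v)) 1e10 else -v
    }
    opt <- stats::optim(t0, fn, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    list(model = .unpackModel(opt$par, imprinting), lod = -opt$value)
}

#' MOD-score scan
#'
#' At each scan position the parametric LOD is maximized over the trait
#' models of a grid (\code{\link{modGrid}}), optionally followed by a
#' box-constrained downhill-simplex refinement from the best grid point;
#' the maximization is carried out separately at every position.  The grid
#' always contains a degenerate equal-penetrance model whose LOD is exactly
#' 0, so MOD scores are bounded below by 0.  With \code{imprinting} grids
#' the heterozygote penetrance is split by transmitting parent and the
#' search space nests the standard one, so the imprinting MOD dominates the
#' standard MOD pointwise (for equal grid settings).
#'
#' @inheritParams markerLikelihood
#' @param positions scan positions in cM; default marker positions plus
#'   interval midpoints.
#' @param grid a \linkS4class{ModGrid}.
#' @param models optional explicit 5 x n model matrix (rows q, f0, f1pat,
#'   f1mat, f2) overriding the grid enumeration; refinement is then skipped.
#' @param engine prebuilt internal engine (advanced; used by the replicate
#'   machinery to amortize table construction).
#' @return a \linkS4class{ScanResult}.
#' @export
modScan <- function(gt, positions = NULL, grid = modGrid(), models = NULL,
                    families = NULL, bitLimit = 20L,
                    mapFunction = "haldane", engine = NULL) {
    if (is.null(engine)) engine <- .engineBuild(gt, families, bitLimit, mapFunction)
    if (is.null(positions)) positions <- .defaultPositions(engine$cm)
    if (!length(positions)) stop("empty position list")
    explicit <- !is.null(models)
    if (!explicit) models <- .gridModels(grid)
    genoList <- lapply(engine$families, function(st) .familyGeno(gt, st))
    names(genoList) <- names(engine$families)
    P <- length(positions)
    famNames <- names(engine$families)
    needWeights <- !explicit && grid@refine
    # grid-only scans use the precomputed per-model trait tables in the
    # engine (fast, reused across gene-drop replicates); refinement needs
    # the per-position key weights instead
    # building the per-model tables costs ~nnz x nmod in the engine, which
    # only pays off for small grids or when the engine is reused across
    # replicates; larger one-shot grids go through the key-weight route
    useTables <- !needWeights && ncol(models) <= 256L
    Ws <- NULL
    if (useTables) {
        geom <- .scanGeom(engine$cm, positions, engine$mapFunction)
        degen <- .isDegenerate(models)
        lodFam <- lapply(famNames, function(f) {
            st <- engine$families[[f]]
            .lgSetModels(st$xptr, models)
            lod <- .lgScanLOD(st$xptr, genoList[[f]], engine$freq,
                              engine$theta, geom$idx, geom$thetaL, geom$thetaR)
            lod[, degen] <- 0
            lod
        })
    } else {
        Ws <- .engineWeights(engine, genoList, positions)
        lodFam <- lapply(famNames, function(f)
            .lodFromWeights(engine$families[[f]], Ws[[f]], models))
    }
    names(lodFam) <- famNames
    total <- Reduce(`+`, lodFam)
    best <- max.col(total, ties.method = "first")
    mod <- total[cbind(seq_len(P), best)]
    bestModels <- models[, best, drop = FALSE]
    rownames(bestModels) <- c("q", "f0", "f1pat", "f1mat", "f2")
    perFamily <- vapply(famNames, function(f)
        lodFam[[f]][cbind(seq_len(P), best)], numeric(P))
    perFamily <- matrix(perFamily, nrow = P, dimnames = list(NULL, famNames))
    if (!explicit && grid@refine) {
        for (p in seq_len(P)) {
            starts <- list(bestModels[, p])
            if (grid@imprinting) {
                # also replicate the standard (collapsed) refinement so the
                # imprinting MOD dominates the standard scan's result
                coll <- models["f1pat", ] == models["f1mat", ]
                bc <- which(coll)[which.max(total[p, coll])]
                starts <- c(starts, list(models[, bc]))
            }
            for (si in seq_along(starts)) {
                imp <- grid@imprinting && si == 1L
                r <- .refinePosition(engine, Ws, p, starts[[si]], imp)
                if (is.finite(r$lod) && r$lod > mod[p]) {
                    mod[p] <- r$lod
                    bestModels[, p] <- r$model
                    mm <- matrix(r$model, nrow = 5,
                                 dimnames = list(rownames(bestModels), NULL))
                    for (f in famNames)
                        perFamily[p, f] <- .lodFromWeights(
                            engine$families[[f]], Ws[[f]][p, , drop = FALSE], mm)[1, 1]
                    # keep exact additivity
                    mod[p] <- sum(perFamily[p, ])
                }
            }
        }
    }
    new("ScanResult", positions = as.numeric(positions), mod = as.numeric(mod),
        models = bestModels, perFamily = perFamily,
        imprinting = isTRUE(grid@imprinting))
}

#' @rdname modScan
#' @param ... passed to \code{modScan}.
#' @export
modScanImprinting <- function(gt, positions = NULL, grid = NULL, ...) {
    if (is.null(grid)) grid <- modGrid(imprinting = TRUE)
    if (!grid@imprinting) grid@imprinting <- TRUE
    modScan(gt, positions = positions, grid = grid, ...)
}
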