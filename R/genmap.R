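## Genetic-map interpolation: local quadratic regression of genetic on
## physical position, projected onto the nearest non-decreasing sequence.
## Used for sex-specific pseudoautosomal maps, where raw local fits can dip.

#' Interpolate genetic positions from physical positions
#'
#' Fits a local quadratic regression (tricube weights, bandwidth as a
#' fraction of the anchors) of cM on bp through the anchor points and
#' evaluates it at the query positions; the fitted values are then
#' projected onto the nearest non-decreasing sequence (isotonic regression
#' in query order), so the returned map is guaranteed monotone in bp.
#' No extrapolation: queries must lie within the anchor span.
#'
#' @param queryBp physical positions to interpolate at.
#' @param anchorBp,anchorCm anchor points (at least 3).
#' @param bandwidth local-regression span as a fraction of the anchors
#'   (default 0.3; widened automatically when too few anchors fall in a
#'   window to support a quadratic fit).
#' @param degree local polynomial degree (default 2).
#' @return interpolated cM, non-decreasing in \code{queryBp}.
#' @export
interpolateGeneticMap <- function(queryBp, anchorBp, anchorCm,
                                  bandwidth = 0.3, degree = 2) {
    if (length(anchorBp) < 3L) stop("at least 3 anchors are required")
    if (length(anchorBp) != length(anchorCm)) stop("anchor length mismatch")
    o <- order(anchorBp)
    anchorBp <- anchorBp[o]
    anchorCm <- anchorCm[o]
    if (any(queryBp < anchorBp[1] | queryBp > anchorBp[length(anchorBp)]))
        stop("query outside the anchor span (no extrapolation)")
    n <- length(anchorBp)
    qo <- order(queryBp)
    if (n < degree + 3) {
        # too few anchors for a windowed fit: single polynomial through all
        deg <- min(degree, n - 1L)
        fit <- stats::lm(anchorCm ~ stats::poly(anchorBp, deg, raw = TRUE))
        pred <- unname(stats::predict(
            fit, newdata = data.frame(anchorBp = queryBp[qo])))
    } else {
        span <- max(bandwidth, min(1, (degree + 3) / n))
        fit <- stats::loess(anchorCm ~ anchorBp, span = span, degree = degree,
                            family = "gaussian",
                            control = stats::loess.control(surface = "direct"))
        pred <- stats::predict(fit, newdata = data.frame(anchorBp = queryBp[qo]))
    }
    mono <- stats::isoreg(seq_along(pred), pred)$yf
    out <- numeric(length(queryBp))
    out[qo] <- mono
    out
}
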