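#' Fit a power law by least squares on logarithmized data
#'
#' Fits y = a * x^gamma by ordinary least squares of log10(y) on log10(x):
#' the slope is the exponent gamma and the back-transformed intercept the
#' amplitude a. Two agreement statistics are reported. \code{rSquared} is
#' the coefficient of determination of the linear regression on the
#' logarithmized data (identical to the squared Pearson correlation of the
#' log-log points). \code{r} is the Pearson correlation between the
#' observed y values and the fitted values a * x^gamma on the original
#' scale. The pair (r, R^2) generally does not satisfy r^2 = R^2 on noisy
#' data; keeping both mirrors the NetworkAnalyzer reporting convention.
#'
#' @param x,y Strictly positive numeric vectors of equal length (>= 2).
#'   Zero counts or zero clustering classes must be excluded upstream,
#'   where the exclusion is logged.
#' @param what Optional label describing what is being fitted.
#' @param nExcluded Number of points excluded upstream (carried into the
#'   result for reporting).
#' @return A \code{\linkS4class{PowerLawFit}}.
#' @examples
#' fitPowerLaw(c(1, 2, 4, 8), c(64, 16, 4, 1))  # exact y = 64 x^-2
#' @export
fitPowerLaw <- function(x, y, what = "power_law", nExcluded = 0L) {
    x <- as.numeric(x); y <- as.numeric(y)
    if (length(x) != length(y))
        stop("x and y must have equal length")
    if (anyNA(x) || anyNA(y) || any(x <= 0) || any(y <= 0))
        stop("all points must be strictly positive; ",
             "exclude zero values upstream")
    if (length(x) < 2L)
        stop("fit error: need at least two points")
    if (length(unique(x)) < 2L)
        stop("degenerate fit: all x values identical")
    lx <- log10(x); ly <- log10(y)
    fit <- stats::lm(ly ~ lx)
    gamma <- unname(stats::coef(fit)[2L])
    amplitude <- 10^unname(stats::coef(fit)[1L])
    if (stats::sd(ly) == 0) {
        # constant y: the flat line fits perfectly
        rSquared <- 1
    } else {
        rSquared <- stats::cor(lx, ly)^2
    }
    yhat <- amplitude * x^gamma
    r <- if (stats::sd(y) == 0 || stats::sd(yhat) == 0) NA_real_
         else stats::cor(y, yhat)
    new("PowerLawFit", gamma = gamma, amplitude = amplitude, r = r,
        rSquared = rSquared, nPoints = length(x),
        nExcluded = as.integer(nExcluded), what = what)
}

#' Power-law fit of the degree distribution
#'
#' Fits node count versus degree, n(k) = a * k^gamma, on the raw degree
#' classes (no binning) of a clean network. Zero-degree nodes cannot enter
#' (log 0 undefined) and are reported as excluded.
#'
#' @param x A clean \code{InteractionNetwork} with at least two distinct
#'   positive degrees.
#' @return A \code{\linkS4class{PowerLawFit}}.
#' @export
fitDegreeDistribution <- function(x) {
    dd <- degreeDistribution(x)
    nz <- attr(dd, "nZeroDegree")
    if (nz > 0L)
        .log("fitDegreeDistribution(", x@name, "): ", nz,
             " zero-degree node(s) excluded from the fit")
    if (nrow(dd) < 2L)
        stop("fit error: fewer than two distinct positive degree classes")
    fitPowerLaw(dd$k, dd$count, what = "degree_distribution",
                nExcluded = nz)
}

#' Per-degree-class mean clustering profile
#'
#' For every degree k >= 2 present in the network, the mean node clustering
#' coefficient over nodes of that degree -- the C(k) profile whose decay
#' with k is the signature of hierarchical architecture. Classes whose mean
#' clustering is zero are excluded from the returned profile (their
#' logarithm is undefined in the downstream fit) and the exclusion is
#' logged.
#'
#' @param x A clean \code{InteractionNetwork}.
#' @return \code{data.frame} with columns \code{k}, \code{meanCC},
#'   \code{nNodes}.
#' @export
degreeClusteringProfile <- function(x) {
    .checkClean(x, "degreeClusteringProfile")
    d <- nodeDegrees(x)
    cc <- nodeClusterings(x)
    ok <- d >= 2L
    if (!any(ok))
        return(data.frame(k = integer(), meanCC = numeric(),
                          nNodes = integer()))
    ks <- sort(unique(d[ok]))
    prof <- data.frame(
        k = as.integer(ks),
        meanCC = vapply(ks, function(k) mean(cc[d == k]), numeric(1L)),
        nNodes = vapply(ks, function(k) sum(d == k), integer(1L)))
    drop <- prof$meanCC == 0
    if (any(drop))
        .log("degreeClusteringProfile(", x@name, "): ", sum(drop),
             " zero-clustering degree class(es) excluded")
    prof <- prof[!drop, , drop = FALSE]
    rownames(prof) <- NULL
    attr(prof, "nExcluded") <- as.integer(sum(drop))
    prof
}

#' Power-law fit of degree versus clustering
#'
#' Fits the C(k) relation, mean clustering versus degree, as a power law on
#' logarithmized data. By default the per-degree-class mean clustering
#' profile is fitted; \code{perNode = TRUE} fits the raw per-node (k, C)
#' scatter instead (nodes with C = 0 or k < 2 excluded, logged).
#'
#' @param x A clean \code{InteractionNetwork}.
#' @param perNode Fit per-node values instead of per-class means.
#' @return A \code{\linkS4class{PowerLawFit}}.
#' @export
fitDegreeVsClustering <- function(x, perNode = FALSE) {
    if (perNode) {
        d <- nodeDegrees(x)
        cc <- nodeClusterings(x)
        ok <- d >= 2L & !is.na(cc) & cc > 0
        nEx <- sum(d >= 2L) - sum(ok)
        if (nEx > 0L)
            .log("fitDegreeVsClustering(", x@name, "): ", nEx,
                 " zero-clustering node(s) excluded")
        if (sum(ok) < 2L)
            stop("fit error: fewer than two usable (degree, clustering) ",
                 "points")
        return(fitPowerLaw(d[ok], cc[ok], what = "degree_vs_clustering",
                           nExcluded = nEx))
    }
    prof <- degreeClusteringProfile(x)
    if (nrow(prof) < 2L)
        stop("fit error: fewer than two usable degree classes in the ",
             "clustering profile")
    fitPowerLaw(prof$k, prof$meanCC, what = "degree_vs_clustering",
                nExcluded = attr(prof, "nExcluded"))
}

setMethod("show", "PowerLawFit", function(object) {
    cat("PowerLawFit (", object@what, "): y = ",
        signif(object@amplitude, 4L), " * x^(",
        sprintf("%.3f", object@gamma), ")\n", sep = "")
    cat("  r = ", sprintf("%.3f", object@r),
        "   R^2 (log-log) = ", sprintf("%.3f", object@rSquared),
        "   points = ", object@nPoints,
        if (object@nExcluded) paste0(" (", object@nExcluded, " excluded)")
        else "", "\n", sep = "")
    invisible(NULL)
})

#' @describeIn fitPowerLaw Serialize a fit to a one-row data.frame with the
#'   conventional gamma / r / R-squared columns (three decimals).
#' @param row.names,optional,... Ignored; present for generic consistency.
#' @export
as.data.frame.PowerLawFit <- function(x, row.names = NULL,
                                      optional = FALSE, ...) {
    data.frame(what = x@what,
               gamma = round(x@gamma, 3L),
               r = round(x@r, 3L),
               r_squared = round(x@rSquared, 3L),
               n_points = x@nPoints,
               stringsAsFactors = FALSE)
}
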