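#' Distribution-pattern vector over all grid cells
#'
#' Turns one group's distribution pattern into a numeric vector indexed by
#' every cell of the grid, with cells where the pattern is absent filled
#' with zero. Richness patterns use the group's per-cell ratio
#' \eqn{r_{gc}}; complementarity patterns place the group's component of
#' each selected cell's gain \eqn{G_c} at that cell.
#'
#' @param source a [RichnessPattern-class] or
#'   [ComplementaritySolution-class].
#' @param group one of \code{CONSERVATION_GROUPS}.
#' @param grid the common [GridSpec-class].
#' @return numeric vector of length \code{nCells(grid)}.
#' @export
patternVector <- function(source, group, grid) {
    stopifnot(is(grid, "GridSpec"))
    group <- match.arg(group, CONSERVATION_GROUPS)
    v <- numeric(nCells(grid))
    if (is(source, "RichnessPattern")) {
        if (nCells(source@grid) != nCells(grid))
            stop("pattern computed on a different grid")
        v <- source@ratios[group, ]
    } else if (is(source, "ComplementaritySolution")) {
        if (length(source@cellIds) &&
            max(source@cellIds) >= nCells(grid))
            stop("solution cells exceed the grid")
        v[source@cellIds + 1L] <- source@gainComponents[group, ]
    } else stop("unsupported source")
    v
}

#' Pearson correlation between two pattern vectors
#'
#' Standard product-moment correlation with the two-sided p-value from the
#' t distribution on n - 2 degrees of freedom. Errors when either vector
#' is constant (r is undefined there).
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return list with elements \code{r} and \code{p}.
#' @export
pearsonR <- function(x, y) {
    if (length(x) != length(y)) stop("vectors differ in length")
    if (length(x) < 3L) stop("need at least 3 observations")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("undefined correlation: constant vector")
    ct <- stats::cor.test(x, y, method = "pearson",
                          alternative = "two.sided")
    list(r = unname(ct$estimate), p = ct$p.value)
}

#' Seven-class qualitative correlation taxonomy
#'
#' Classifies a Pearson r by |r|: no correlation (r = 0), very weak
#' (0 < |r| < 0.2), weak (0.2 <= |r| < 0.4), moderate (0.4 <= |r| < 0.6),
#' strong (0.6 <= |r| < 0.8), very strong (0.8 <= |r| < 1) and perfect
#' (|r| = 1). r is rounded to two decimals first, matching how such
#' coefficients are reported.
#'
#' @param r numeric in [-1, 1] (vectorised).
#' @param digits decimals to round |r| to before binning (default 2).
#' @return character vector of class labels.
#' @examples
#' classifyR(0.42)  # "moderate"
#' classifyR(0.74)  # "strong"
#' @export
classifyR <- function(r, digits = 2) {
    if (any(abs(r) > 1 + 1e-12)) stop("|r| exceeds 1")
    a <- roundHalfUp(abs(r), digits)
    a <- pmin(a, 1)
    ifelse(a == 0, "no correlation",
    ifelse(a < 0.2, "very weak",
    ifelse(a < 0.4, "weak",
    ifelse(a < 0.6, "moderate",
    ifelse(a < 0.8, "strong",
    ifelse(a < 1,   "very strong", "perfect"))))))
}

#' Correlogram across distribution patterns
#'
#' Pairwise Pearson correlations, p-values and seven-class labels over a
#' list of pattern vectors. An optional normalization (z-score or min-max)
#' can be applied first; Pearson r is invariant under positive affine
#' transforms, so this affects presentation only.
#'
#' @param vectors named list of equal-length numeric vectors (e.g. the ten
#'   patterns R_All, R_EN, R_TH, R_CI, R_NP, C_All, C_EN, C_TH, C_CI,
#'   C_NP).
#' @param normalize \code{"none"} (default), \code{"zscore"} or
#'   \code{"minmax"}.
#' @return a [CorrelationReport-class].
#' @export
correlogram <- function(vectors, normalize = c("none", "zscore", "minmax")) {
    normalize <- match.arg(normalize)
    if (length(vectors) < 2L) stop("need at least 2 vectors")
    len <- lengths(vectors)
    if (length(unique(len)) != 1L) stop("vectors differ in length")
    if (is.null(names(vectors)))
        names(vectors) <- paste0("V", seq_along(vectors))
    vectors <- lapply(vectors, function(v) switch(normalize,
        none = v,
        zscore = (v - mean(v)) / stats::sd(v),
        minmax = (v - min(v)) / (max(v) - min(v))))
    n <- length(vectors)
    r <- diag(n); p <- matrix(NA_real_, n, n); diag(p) <- 0
    dimnames(r) <- dimnames(p) <- list(names(vectors), names(vectors))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        pr <- pearsonR(vectors[[i]], vectors[[j]])
        r[i, j] <- r[j, i] <- pr$r
        p[i, j] <- p[j, i] <- pr$p
    }
    cls <- matrix(classifyR(r), n, n, dimnames = dimnames(r))
    new("CorrelationReport", r = r, p = p, classes = cls)
}

#' The ten standard distribution patterns
#'
#' Convenience builder of the pattern vectors of both algorithms for all
#' five conservation groups, in the canonical order R_All, R_EN, R_TH,
#' R_CI, R_NP, C_All, C_EN, C_TH, C_CI, C_NP.
#'
#' @param pattern a [RichnessPattern-class].
#' @param solution a [ComplementaritySolution-class].
#' @param grid the common [GridSpec-class].
#' @return named list of ten numeric vectors.
#' @export
standardPatternVectors <- function(pattern, solution, grid) {
    short <- c(ALL = "All", ENDEMIC = "EN", THREATENED = "TH",
               CITES = "CI", NATIONAL_PROTECTED = "NP")
    out <- c(
        lapply(CONSERVATION_GROUPS, patternVector, source = pattern,
               grid = grid),
        lapply(CONSERVATION_GROUPS, patternVector, source = solution,
               grid = grid))
    names(out) <- c(paste0("R_", short), paste0("C_", short))
    out
}

#' Export a correlation report as CSV
#'
#' @param report a [CorrelationReport-class].
#' @param path output file.
#' @param form \code{"long"} (pair per row, default) or \code{"wide"} (the
#'   r matrix).
#' @return the path, invisibly.
#' @export
writeCorrelogramCSV <- function(report, path, form = c("long", "wide")) {
    stopifnot(is(report, "CorrelationReport"))
    form <- match.arg(form)
    if (form == "wide") {
        utils::write.csv(round(report@r, 4), path, quote = FALSE)
    } else {
        idx <- which(upper.tri(report@r), arr.ind = TRUE)
        nm <- rownames(report@r)
        df <- data.frame(x = nm[idx[, 1]], y = nm[idx[, 2]],
                         r = round(report@r[idx], 4),
                         p = signif(report@p[idx], 4),
                         class = report@classes[idx])
        utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    }
    invisible(path)
}
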