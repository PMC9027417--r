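#' Format a count as a percentage of a denominator
#'
#' The percentage formatter used by [coverageTable()] and the SHA overlap
#' summaries: \code{round(100 * num / den, digits)} followed by a percent
#' sign. Rounding is half-away-from-zero at the printed precision, the
#' convention of the summary tables this package emulates (e.g. 150/3047
#' prints as "5%", 25/150 with one digit as "16.7%").
#'
#' @param num,den numeric numerator(s) and denominator(s).
#' @param digits integer decimal places (default 0).
#' @return character vector like \code{"83%"}.
#' @examples
#' formatPercent(124, 150)            # "83%"
#' formatPercent(25, 150, digits = 1) # "16.7%"
#' @export
formatPercent <- function(num, den, digits = 0) {
    paste0(percentOf(num, den, digits), "%")
}

#' @rdname formatPercent
#' @return \code{percentOf} returns the bare number.
#' @export
percentOf <- function(num, den, digits = 0) {
    roundHalfUp(100 * num / den, digits)
}

# round half away from zero (base round() is banker's rounding)
roundHalfUp <- function(x, digits = 0) {
    m <- 10^digits
    sign(x) * floor(abs(x) * m + 0.5) / m
}

# Derive per-stage seeds from one master seed so generator stages use
# independent, individually reproducible streams.
stageSeeds <- function(seed, n = 6L) {
    stopifnot(is.finite(seed))
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed) %% .Machine$integer.max)
    sample.int(.Machine$integer.max - 1L, n)
}

# run expr under a temporary RNG state seeded with `seed`
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
        globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else rm(".Random.seed", envir = globalenv()))
    expr
}
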