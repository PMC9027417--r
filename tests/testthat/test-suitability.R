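fineStack <- function(perSpecies, grid, tau = 0.75,
                      scenario = "current") {
    vals <- array(unlist(perSpecies),
                  c(nRows(grid), nCols(grid), length(perSpecies)),
                  dimnames = list(NULL, NULL, names(perSpecies)))
    suitabilityStack(vals, grid, scenario = scenario, tau = tau)
}

test_that("modeling filter keeps group species with enough records", {
    cat <- fixtureCatalog(10, threatened = 1:10)
    # 7 of 10 species reach the 5-record floor
    counts <- c(5, 7, 4, 9, 5, 1, 12, 5, 2, 30)
    rec <- data.frame(
        species_id = rep(sprintf("sp%02d", 1:10), counts),
        lon = 0.1, lat = 0.1)
    occ <- occurrenceTable(rec)
    kept <- minOccurrenceFilter(occ, cat)
    expect_length(kept, 7)
    expect_true("sp01" %in% kept)     # exactly 5 records is included
    expect_false("sp03" %in% kept)    # 4 records is excluded
    expect_error(minOccurrenceFilter(occ, cat, nMin = 0), "nMin")
    # group restriction: non-threatened species never pass
    cat2 <- fixtureCatalog(10, threatened = 1:5)
    expect_false("sp10" %in% minOccurrenceFilter(occ, cat2))
})

test_that("replication plan switches from jackknife to cross-validation", {
    p <- replicationPlan(7)
    expect_equal(p$method, "jackknife")
    expect_equal(p$replicates, 7L)
    p30 <- replicationPlan(30)
    expect_equal(p30$method, "cross-validation")
    expect_equal(p30$replicates, 10L)
    expect_equal(replicationPlan(29)$method, "jackknife")
    expect_error(replicationPlan(4), "fewer than 5")
    many <- replicationPlan(c(5, 12, 29, 30, 300))
    expect_equal(many$method,
                 c("jackknife", "jackknife", "jackknife",
                   "cross-validation", "cross-validation"))
})

test_that("predictor screening enforces the correlation cutoff", {
    set.seed(2)
    n <- 200
    # mutually (near) uncorrelated set: everything retained
    x <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("v", 1:4)))
    expect_setequal(screenPredictors(x), paste0("v", 1:4))

    # construct a pair with exact sample correlation
    exactPair <- function(r) {
        a <- scale(rnorm(n))[, 1]
        b <- scale(resid(lm(rnorm(n) ~ a)))[, 1]
        cbind(x = a, y = r * a + sqrt(1 - r^2) * b)
    }
    atCut <- exactPair(0.70)
    expect_setequal(screenPredictors(atCut, cutoff = 0.70),
                    c("x", "y"))                 # = 0.70 is kept
    above <- exactPair(0.70001)
    expect_length(screenPredictors(above, cutoff = 0.70), 1)

    # 4 variables with one strongly correlated pair: 3 survive, and the
    # survivor set achieves the bound (exhaustive-search oracle)
    z <- cbind(exactPair(0.9), u = rnorm(n), w = rnorm(n))
    kept <- screenPredictors(z, cutoff = 0.70)
    expect_length(kept, 3)
    ok <- combn(colnames(z), 3, function(s) {
        r <- abs(cor(z[, s])); diag(r) <- 0; max(r) <= 0.70
    })
    expect_true(any(ok))
    r <- abs(cor(z[, kept])); diag(r) <- 0
    expect_lte(max(r), 0.70)

    expect_error(screenPredictors(cbind(a = rnorm(5), b = rep(1, 5))),
                 "constant")
})

test_that("screening output is deterministic and below the cutoff", {
    set.seed(77)
    for (i in 1:100) {
        n <- 60
        k <- sample(3:8, 1)
        base <- matrix(rnorm(n * k), n)
        # induce collinearity by mixing columns
        mix <- base %*% matrix(runif(k * k, -1, 1), k)
        colnames(mix) <- paste0("p", 1:k)
        kept <- screenPredictors(mix, cutoff = 0.70)
        expect_identical(kept, screenPredictors(mix, cutoff = 0.70))
        expect_true(all(kept %in% colnames(mix)))
        r <- abs(cor(mix[, kept, drop = FALSE])); diag(r) <- 0
        if (length(kept) > 1) expect_lte(max(r), 0.70)
    }
})

test_that("threshold rejection and superposition follow the 0.75 rule", {
    g <- makeGrid(c(0, 0, 0.5, 0.5), 0.25)  # 2x2 fine pixels
    m <- function(v) matrix(v, 2, 2)
    stk <- fineStack(list(a = m(0.6), b = m(0.6)), g)
    expect_true(all(thresholdAndSuperpose(stk) == 0))
    expect_false(any(shaMask(stk)))

    # 0.8 + 0.9 retained, 0.6 rejected -> 1.7
    stk2 <- fineStack(list(a = m(0.8), b = m(0.9), c = m(0.6)), g)
    expect_equal(unique(as.vector(thresholdAndSuperpose(stk2))), 1.7)

    # exactly tau is retained
    stk3 <- fineStack(list(a = m(0.75)), g)
    expect_true(all(thresholdAndSuperpose(stk3) == 0.75))
    stk4 <- fineStack(list(a = m(0.74999)), g)
    expect_true(all(thresholdAndSuperpose(stk4) == 0))
})

test_that("raising tau never increases the superposed map", {
    g <- makeGrid(c(0, 0, 1, 1), 0.25)
    set.seed(14)
    vals <- replicate(3, matrix(runif(16), 4, 4), simplify = FALSE)
    names(vals) <- c("a", "b", "c")
    taus <- c(0.5, 0.6, 0.75, 0.9)
    maps <- lapply(taus, function(t)
        thresholdAndSuperpose(fineStack(vals, g, tau = t)))
    for (i in seq_along(taus)[-1]) {
        expect_true(all(maps[[i]] <= maps[[i - 1]] + 1e-12))
        expect_true(all((maps[[i]] > 0) <= (maps[[i - 1]] > 0)))
    }
    # superposition is additive over species subsets
    full <- thresholdAndSuperpose(fineStack(vals, g))
    parts <- thresholdAndSuperpose(fineStack(vals[1:2], g)) +
             thresholdAndSuperpose(fineStack(vals[3], g))
    expect_equal(full, parts)
})

test_that("sub-cell overlap classes split complete, partial and none", {
    coarse <- makeGrid(c(0, 0, 1, 1), 0.5)
    fine <- refineGrid(coarse, 6L)
    mask <- matrix(FALSE, nRows(fine), nCols(fine))
    # cell 0 fully positive; cell 1: 20 of 36; cell 2: none
    mask[1:6, 1:6] <- TRUE
    sel <- cbind(rep(1:5, each = 4), rep(7:10, times = 5))
    mask[sel] <- TRUE
    cls <- shaOverlapClasses(0:3, mask, coarse, fine)
    expect_equal(cls$class, c("complete", "partial", "none", "none"))
    expect_equal(cls$n_positive[2], 20L)
    expect_equal(cls$n_subcells[1], 36L)
    # classes always partition the cell set
    expect_equal(sum(table(cls$class)), 4)
    # fractional rule: 20/36 > 0.5 counts as complete
    clsF <- shaOverlapClasses(0:3, mask, coarse, fine, minFraction = 0.5)
    expect_equal(clsF$class[2], "complete")
    # non-divisible resolutions are rejected
    odd <- makeGrid(c(0, 0, 1, 1), 0.15)
    expect_error(shaOverlapClasses(0L, mask, coarse, odd), "divide")
})

test_that("stable SHA is the pixelwise intersection of the scenarios", {
    set.seed(6)
    cur <- matrix(runif(144) > 0.4, 12, 12)
    fut <- matrix(runif(144) > 0.4, 12, 12)
    st <- stableSha(cur, fut)
    # independent mask arithmetic oracle
    expect_equal(st, !( !cur | !fut))
    expect_true(all(st <= cur) && all(st <= fut))
    expect_equal(stableSha(cur, cur), cur)
    disj <- !cur
    expect_false(any(stableSha(cur, disj)))
    expect_error(stableSha(cur, fut[1:6, ]), "misaligned")
})

test_that("hotspot SHA overlap combines scenarios and stability", {
    coarse <- makeGrid(c(0, 0, 1, 1), 0.5)
    fine <- refineGrid(coarse, 6L)
    full <- matrix(TRUE, 12, 12)
    none <- matrix(FALSE, 12, 12)
    ov <- hotspotShaOverlap(0:3, full, full, coarse, fine)
    expect_true(all(ov$class_current == "complete"))
    expect_true(all(ov$stable))
    ov2 <- hotspotShaOverlap(0:3, full, none, coarse, fine)
    expect_true(all(ov2$class_future == "none"))
    expect_false(any(ov2$stable))
    s <- shaOverlapSummary(ov2)
    expect_equal(s$count[s$measure == "current_complete"], 4L)
    expect_equal(s$percent[s$measure == "current_complete"], 100)
    expect_equal(s$count[s$measure == "stable"], 0L)
})

test_that("ESRI ASCII rasters round-trip values and geotransform", {
    g <- makeGrid(c(100, 20, 101, 20.5), 0.25)
    vals <- matrix(round(runif(nRows(g) * nCols(g)), 3), nRows(g))
    vals[1, 2] <- NA
    path <- withr::local_tempfile(fileext = ".asc")
    writeAsc(vals, g, path)
    back <- readAsc(path)
    expect_equal(back$values, vals)
    expect_equal(gridToConfig(back$grid), gridToConfig(g))
    # header orientation: first data row is the northernmost
    lines <- readLines(path)
    firstRow <- as.numeric(strsplit(lines[7], " ")[[1]])
    expect_equal(firstRow, ifelse(is.na(vals[nRows(g), ]), -9999,
                                  vals[nRows(g), ]))
})
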