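test_that("composite richness index sums the five group ratios", {
    grid <- makeGrid(c(0, 0, 1, 1), 0.5)
    # cell 0 holds every species of every group -> R_c = 5
    cat <- fixtureCatalog(4, endemic = 1:2, threatened = 2,
                          cites = 3, protected = 4)
    inc <- fixtureIncidence(list(`0` = sprintf("sp%02d", 1:4),
                                 `1` = "sp01"), grid)
    pat <- groupRichness(inc, cat)
    expect_equal(pat@composite[1], 5)
    expect_equal(pat@composite[3], 0)          # empty cell
    # hand ratio sum: 2/10 ALL + 1/4 ENDEMIC, other groups empty
    cat2 <- fixtureCatalog(10, endemic = 1:4)
    inc2 <- fixtureIncidence(list(`0` = c("sp01", "sp05")), grid,
                             species = sprintf("sp%02d", 1:10))
    expect_warning(pat2 <- groupRichness(inc2, cat2), "empty group")
    expect_equal(pat2@composite[1], 2 / 10 + 1 / 4)
    expect_true(all(pat2@composite >= 0 & pat2@composite <= 5))
})

test_that("adding an occurrence never decreases a cell's composite index", {
    grid <- makeGrid(c(0, 0, 2, 2), 0.5)
    set.seed(21)
    cat <- fixtureCatalog(12, endemic = 1:4, threatened = 5:6,
                          cites = 7, protected = 8)
    for (i in 1:10) {
        cells <- sample(0:15, 6)
        byCell <- lapply(cells, function(c)
            sample(sprintf("sp%02d", 1:12), sample(1:5, 1)))
        names(byCell) <- cells
        inc <- fixtureIncidence(byCell, grid,
                                species = sprintf("sp%02d", 1:12))
        pat <- groupRichness(inc, cat)
        # add one absent species to one occupied cell
        tgt <- sample(cells, 1)
        have <- speciesInCells(inc, tgt)
        absent <- setdiff(sprintf("sp%02d", 1:12), have)
        if (!length(absent)) next
        byCell[[as.character(tgt)]] <-
            c(byCell[[as.character(tgt)]], absent[1])
        pat2 <- groupRichness(fixtureIncidence(byCell, grid,
                              species = sprintf("sp%02d", 1:12)), cat)
        expect_gte(pat2@composite[tgt + 1], pat@composite[tgt + 1])
        expect_gt(pat2@composite[tgt + 1], pat@composite[tgt + 1] - 1e-12)
    }
})

test_that("top-richness ranking respects the fraction and extends ties", {
    grid <- makeGrid(c(0, 0, 5, 5), 0.5)
    # 100 occupied cells with strictly decreasing richness
    byCell <- lapply(1:100, function(i) sprintf("sp%03d", 1:i))
    names(byCell) <- 0:99
    inc <- fixtureIncidence(byCell, grid,
                            species = sprintf("sp%03d", 1:100))
    pat <- suppressWarnings(groupRichness(inc,
        fixtureCatalog(100, ids = sprintf("sp%03d", 1:100))))
    rk <- topRichnessHotspots(pat, fraction = 0.05)
    expect_length(hotspotCells(rk), 5)
    expect_false(rk@tieExtended)
    expect_equal(hotspotCells(rk), c(99L, 98L, 97L, 96L, 95L))
    expect_error(topRichnessHotspots(pat, fraction = 1.5), "fraction")

    # tied scores at the cutoff are all retained: 9,8,7,7,7,1 with K=4
    counts <- c(9, 8, 7, 7, 7, 1)
    byCell2 <- lapply(counts, function(k) sprintf("sp%03d", 1:k))
    names(byCell2) <- 0:5
    inc2 <- fixtureIncidence(byCell2, grid,
                             species = sprintf("sp%03d", 1:9))
    pat2 <- suppressWarnings(groupRichness(inc2,
        fixtureCatalog(9, ids = sprintf("sp%03d", 1:9))))
    rk2 <- topRichnessHotspots(pat2, kOverride = 4)
    expect_length(hotspotCells(rk2), 5)
    expect_true(rk2@tieExtended)
})

test_that("greedy complementarity follows the covering rule", {
    grid <- makeGrid(c(0, 0, 1, 1), 0.5)
    cat <- fixtureCatalog(4, endemic = 1, threatened = 2, cites = 3,
                          protected = 4)
    # single cell holding all species: one step, gain 5
    inc1 <- fixtureIncidence(list(`0` = sprintf("sp%02d", 1:4)), grid)
    sol1 <- greedyComplementarity(inc1, cat)
    expect_equal(sol1@cellIds, 0L)
    expect_equal(sol1@gains, 5)
    # A{s1,s2,s3}, B{s3,s4}, C{s4}: A then B; C never picked
    incA <- fixtureIncidence(list(`0` = c("sp01", "sp02", "sp03"),
                                  `1` = c("sp03", "sp04"),
                                  `2` = "sp04"), grid)
    solA <- greedyComplementarity(incA, cat)
    expect_equal(solA@cellIds, c(0L, 1L))
    expect_setequal(solA@newlyCovered[[2]], "sp04")
    # disjoint cells select in descending richness order
    incD <- fixtureIncidence(list(`0` = "sp01",
                                  `1` = c("sp02", "sp03", "sp04"),
                                  `3` = c("sp01")), grid,
                             species = sprintf("sp%02d", 1:4))
    solD <- greedyComplementarity(incD, cat)
    expect_equal(solD@cellIds[1], 1L)
    # zero-occurrence species violate termination
    incZ <- fixtureIncidence(list(`0` = "sp01"), grid,
                             species = c("sp01", "sp02"))
    expect_error(greedyComplementarity(incZ, cat), "zero occurrences")
})

test_that("greedy matches an independent brute-force simulation", {
    grid <- makeGrid(c(0, 0, 2, 1.5), 0.5)  # 12 cells
    set.seed(99)
    for (i in 1:60) {
        ins <- randomInstance()
        byCell <- ins$sets[lengths(ins$sets) > 0]
        names(byCell) <- which(lengths(ins$sets) > 0) - 1L
        inc <- fixtureIncidence(byCell, grid, species = ins$species)
        if (any(Matrix::rowSums(inc@mat) == 0)) next
        sol <- suppressWarnings(greedyComplementarity(inc, ins$catalog))
        # the oracle indexes the full cell list; map ids
        oracleSets <- ins$sets
        orc <- oracleGreedy(oracleSets, memberListOf(ins$catalog),
                            as.list(groupTotals(ins$catalog)))
        expect_equal(sol@cellIds, orc$order)
        expect_equal(sol@gains, orc$gains, tolerance = 1e-12)
        expect_equal(lapply(sol@newlyCovered, sort), orc$covered)
    }
})

test_that("greedy solutions cover all species and gains sum to the group count", {
    grid <- makeGrid(c(0, 0, 2, 1.5), 0.5)
    set.seed(123)
    for (i in 1:20) {
        ins <- randomInstance()
        byCell <- ins$sets[lengths(ins$sets) > 0]
        names(byCell) <- which(lengths(ins$sets) > 0) - 1L
        inc <- fixtureIncidence(byCell, grid, species = ins$species)
        sol <- suppressWarnings(greedyComplementarity(inc, ins$catalog))
        expect_setequal(unlist(sol@newlyCovered), ins$species)
        nonEmpty <- sum(groupTotals(ins$catalog) > 0)
        expect_equal(sum(sol@gains), nonEmpty, tolerance = 1e-9)
        expect_true(all(sol@gains > 0))
    }
})

test_that("complementarity ranking keeps ties at the cutoff", {
    mk <- function(gains) new("ComplementaritySolution",
        cellIds = seq_along(gains) - 1L, gains = gains,
        gainComponents = matrix(rep(gains / 5, each = 5), nrow = 5,
            dimnames = list(CONSERVATION_GROUPS, NULL)),
        newlyCovered = as.list(sprintf("s%d", seq_along(gains))),
        nUncovered = c(rev(seq_along(gains))[-1], 0L))
    rk <- topComplementarityHotspots(mk(c(1.0, 0.5, 0.5, 0.1)), k = 3)
    expect_length(hotspotCells(rk), 3)
    # tie crossing the cutoff pulls in the extra cell (151-for-150)
    rk2 <- topComplementarityHotspots(mk(c(1.0, 0.5, 0.3, 0.3)), k = 3)
    expect_length(hotspotCells(rk2), 4)
    expect_true(rk2@tieExtended)
    # k beyond the pool returns everything
    rk3 <- topComplementarityHotspots(mk(c(1, 0.5, 0.2)), k = 150)
    expect_length(hotspotCells(rk3), 3)
    expect_error(topComplementarityHotspots(mk(c(1)), k = 0), "k")
})

test_that("integration sums orders and fills with single-ranking cells", {
    # identical rankings: everything first-class
    r <- fixtureRanking(0:149)
    fin <- integrateHotspots(r, fixtureRanking(0:149,
                                               "complementarity"), 150)
    expect_length(firstClass(fin), 150)
    expect_length(secondClass(fin), 0)

    # rank_R = a,b,c ; rank_C = c,d,e ; k = 4
    rr <- fixtureRanking(c(0, 1, 2))
    rc <- fixtureRanking(c(2, 3, 4), "complementarity")
    fin2 <- integrateHotspots(rr, rc, 4)
    expect_equal(firstClass(fin2), 2L)
    expect_equal(secondClass(fin2), c(0L, 3L, 1L))

    # disjoint rankings interleave by recomputed order
    rd <- fixtureRanking(c(10, 11, 12), "complementarity")
    fin3 <- integrateHotspots(rr, rd, 4)
    expect_length(firstClass(fin3), 0)
    expect_equal(secondClass(fin3), c(0L, 10L, 1L, 11L))
})

test_that("first and second class conserve the target size and stay disjoint", {
    set.seed(42)
    for (i in 1:200) {
        pool <- 0:59
        a <- sample(pool, sample(5:30, 1))
        b <- sample(pool, sample(5:30, 1))
        kT <- sample(1:min(40, length(union(a, b))), 1)
        fin <- integrateHotspots(fixtureRanking(a),
                                 fixtureRanking(b, "complementarity"),
                                 kT)
        f <- firstClass(fin); s <- secondClass(fin)
        expect_length(intersect(f, s), 0)
        expect_equal(length(f) + length(s), kT)
        expect_true(all(c(f, s) %in% union(a, b)))
    }
})

test_that("hotspot CSV export carries order, score and class", {
    rr <- fixtureRanking(c(5, 3, 9))
    path <- withr::local_tempfile(fileext = ".csv")
    writeHotspotsCSV(rr, path)
    df <- read.csv(path)
    expect_equal(df$cell_id, c(5, 3, 9))
    expect_equal(df$order, 1:3)
    fin <- integrateHotspots(rr, fixtureRanking(c(9, 5, 1),
                                                "complementarity"), 4)
    writeHotspotsCSV(fin, path)
    df2 <- read.csv(path)
    expect_setequal(df2$class, c("first", "second"))
})
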