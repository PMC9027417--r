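# Fixture builders shared across the suite. Everything is generated in
# code; no binary data.

# catalog with explicit memberships; threat categories auto-filled
fixtureCatalog <- function(n, endemic = integer(0), threatened = integer(0),
                           cites = integer(0), protected = integer(0),
                           ids = sprintf("sp%02d", seq_len(n))) {
    speciesCatalog(ids,
                   endemic = seq_len(n) %in% endemic,
                   threatened = seq_len(n) %in% threatened,
                   threat_category = ifelse(seq_len(n) %in% threatened,
                                            "VU", "none"),
                   cites = seq_len(n) %in% cites,
                   national_protected = seq_len(n) %in% protected)
}

# incidence built through the real record path: one record per
# (species, cell) pair, placed at the cell centroid
fixtureIncidence <- function(speciesByCell, grid, species = NULL) {
    cells <- rep(as.integer(names(speciesByCell)),
                 lengths(speciesByCell))
    ctr <- cellCentroid(cells, grid)
    occ <- occurrenceTable(data.frame(
        species_id = unlist(speciesByCell, use.names = FALSE),
        lon = ctr[, "lon"], lat = ctr[, "lat"],
        stringsAsFactors = FALSE))
    buildIncidence(occ, grid, species = species)
}

# a HotspotRanking with orders implied by the given cell sequence
fixtureRanking <- function(cells, algorithm = "richness",
                           scores = NULL) {
    n <- length(cells)
    if (is.null(scores)) scores <- rev(seq_len(n))
    new("HotspotRanking", algorithm = algorithm,
        cellIds = as.integer(cells), scores = as.numeric(scores),
        k = n, tieExtended = FALSE)
}

# Independent step-by-step simulation of the greedy complementarity rule,
# written with plain lists/loops: the oracle for the fast implementation.
oracleGreedy <- function(cellSets, memberList, totals,
                         criterion = "all_species") {
    allSpecies <- sort(unique(unlist(cellSets)))
    wOf <- function(sp) {
        sum(vapply(names(totals), function(g) {
            if (totals[[g]] == 0) return(0)
            sum(sp %in% memberList[[g]]) / totals[[g]]
        }, 0))
    }
    uncovered <- allSpecies
    order <- integer(); gains <- numeric(); covered <- list()
    while (length(uncovered)) {
        cnt <- vapply(cellSets, function(s) sum(s %in% uncovered), 0L)
        gw <- vapply(cellSets, function(s)
            wOf(intersect(s, uncovered)), 0)
        ids <- seq_along(cellSets) - 1L
        cand <- if (criterion == "all_species") {
            c1 <- which(cnt == max(cnt))
            c1[gw[c1] >= max(gw[c1]) - 1e-9]
        } else which(gw >= max(gw) - 1e-9)
        pick <- cand[which.min(ids[cand])]
        newSp <- intersect(cellSets[[pick]], uncovered)
        uncovered <- setdiff(uncovered, newSp)
        order <- c(order, pick - 1L)
        gains <- c(gains, wOf(newSp))
        covered <- c(covered, list(sort(newSp)))
    }
    list(order = order, gains = gains, covered = covered)
}

# random small instance for the greedy oracle comparison
randomInstance <- function(nCellsMax = 12, nSpMax = 20) {
    nc <- sample(2:nCellsMax, 1)
    ns <- sample(3:nSpMax, 1)
    ids <- sprintf("sp%02d", seq_len(ns))
    # each species in >= 1 cell
    sets <- replicate(nc, character(0), simplify = FALSE)
    for (s in ids) {
        k <- sample.int(nc, sample(1:min(3, nc), 1))
        for (c in k) sets[[c]] <- c(sets[[c]], s)
    }
    cat <- fixtureCatalog(ns,
        endemic = which(stats::runif(ns) < 0.4),
        threatened = which(stats::runif(ns) < 0.2),
        cites = which(stats::runif(ns) < 0.1),
        protected = which(stats::runif(ns) < 0.1))
    list(sets = lapply(sets, sort), catalog = cat, species = ids)
}

memberListOf <- function(catalog) {
    sapply(CONSERVATION_GROUPS, function(g) speciesInGroup(catalog, g),
           simplify = FALSE)
}
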