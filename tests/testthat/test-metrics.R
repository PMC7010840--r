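test_that("colonization rate is infected over incubated segments", {
    recs <- toy_records(
        list("P1", "i1", "stem", 1, "none"), list("P1", "i1", "stem", 2, "none"),
        list("P1", "i1", "stem", 3, "none"), list("P1", "i1", "stem", 4, "none"),
        list("P1", "i1", "stem", 5, "none"), list("P1", "i1", "stem", 6, "none"),
        list("P1", "i1", "stem", 7, "none"), list("P1", "i1", "stem", 8, "none"),
        list("P1", "i2", "stem", 1, "A"), list("P1", "i2", "stem", 2, "A"),
        list("P1", "i2", "stem", 3, "B"), list("P1", "i2", "stem", 4, "A"),
        list("P1", "i2", "stem", 5, "none"), list("P1", "i2", "stem", 6, "none"),
        list("P1", "i2", "stem", 7, "none"), list("P1", "i2", "stem", 8, "none"))
    cr <- colonizationRate(surveyTable(recs))
    expect_equal(cr$colonization_rate[cr$individual_id == "i1"], 0)
    expect_equal(cr$colonization_rate[cr$individual_id == "i2"], 0.5)
    expect_true(all(cr$n_incubated == 8L))
    expect_error(colonizationRate(surveyTable(recs), by = "plot"), "unknown")
})

test_that("colonization rate is invariant to record order", {
    sv <- generateSurvey(surveyConfig(nSpecies = 3L, nIndividuals = 4L,
        seed = 9L))
    rec <- records(sv)
    shuf <- surveyTable(rec[sample(nrow(rec)), ],
        speciesList = plantSpecies(sv), taxonList = taxa(sv))
    a <- colonizationRate(sv); b <- colonizationRate(shuf)
    expect_equal(a[do.call(order, a[1:3]), ], b[do.call(order, b[1:3]), ],
        ignore_attr = TRUE)
})

test_that("replicate surveys recover a uniform colonization probability", {
    p <- 0.8375
    rates <- vapply(1:30, function(i) {
        sv <- generateSurvey(surveyConfig(nSpecies = 2L, nIndividuals = 5L,
            nSegments = 8L, colonizationProb = p, taxonPool = c("A", "B"),
            seed = 600L + i))
        rec <- records(sv)
        mean(rec$taxon != "none")
    }, 0)
    se <- sqrt(p * (1 - p) / (30 * 160))
    expect_lt(abs(mean(rates) - p), 3 * se)
})

test_that("relative abundance is isolates over group total", {
    sv <- surveyTable(toy_records(
        list("P1", "i1", "stem", 1, "A"), list("P1", "i1", "stem", 2, "A"),
        list("P1", "i1", "stem", 3, "A"), list("P1", "i2", "stem", 1, "B")))
    ra <- relativeAbundance(sampleTaxonMatrix(sv, mode = "count"))
    expect_equal(ra$proportion[ra$taxon == "A"], 0.75)
    expect_equal(ra$proportion[ra$taxon == "B"], 0.25)
    one <- relativeAbundance(sampleTaxonMatrix(surveyTable(toy_records(
        list("P1", "i1", "stem", 1, "A"))), mode = "count"))
    expect_equal(one$proportion, 1.0)
})

test_that("relative abundance matches a loop oracle and sums to one", {
    sv <- generateSurvey(surveyConfig(nSpecies = 4L, nIndividuals = 3L,
        seed = 21L))
    stm <- sampleTaxonMatrix(sv, mode = "count")
    ra <- relativeAbundance(stm, by = "plant_species")
    counts <- abundances(stm)
    sp <- plantSpecies(stm)
    for (s in unique(ra$plant_species)) {
        sub <- ra[ra$plant_species == s, ]
        expect_equal(sum(sub$proportion), 1, tolerance = 1e-12)
        tot <- sum(counts[sp == s, ])
        for (k in seq_len(nrow(sub)))
            expect_equal(sub$proportion[k],
                sum(counts[sp == s, sub$taxon[k]]) / tot)
    }
})

test_that("richness counts distinct taxa per sample", {
    pres <- rbind(c(0, 0, 0, 0), c(1, 0, 1, 1), c(1, 1, 1, 1))
    stm <- presence_stm(pres, c("P1", "P1", "P2"))
    r <- taxonRichness(stm)
    expect_equal(r$richness, c(0L, 3L, 4L))
    set.seed(77)
    m <- matrix(rpois(60, 1), nrow = 10)
    stm2 <- presence_stm(m > 0, rep(c("P1", "P2"), each = 5))
    expect_equal(taxonRichness(stm2)$richness,
        as.integer(rowSums(m > 0)))
})

test_that("one-way ANOVA matches the closed-form sums of squares", {
    vals <- c(2, 3, 4, 5,  6, 7, 8, 9,  1, 2, 3, 4)
    grp <- rep(c("g1", "g2", "g3"), each = 4)
    res <- anovaOneway(vals, grp)
    gm <- mean(vals)
    means <- tapply(vals, grp, mean)
    ssb <- sum(4 * (means - gm)^2)
    ssw <- sum((vals - means[grp])^2)
    fOracle <- (ssb / 2) / (ssw / 9)
    expect_equal(unname(res@statistic), fOracle, tolerance = 1e-10)
    expect_equal(unname(res@pValue), pf(fOracle, 2, 9, lower.tail = FALSE),
        tolerance = 1e-10)
    # identical groups: F = 0, p = 1, not NaN
    flat <- anovaOneway(rep(5, 8), rep(c("a", "b"), each = 4))
    expect_equal(unname(flat@statistic), 0)
    expect_equal(flat@pValue, 1)
    # optional square-root transform changes the response
    sq <- anovaOneway(vals, grp, sqrtTransform = TRUE)
    expect_match(sq@note, "sqrt-transformed")
})

test_that("well-separated groups are detected essentially always", {
    hits <- vapply(1:200, function(i) {
        set.seed(3000 + i)
        v <- c(rnorm(10, 0), rnorm(10, 5), rnorm(10, 10))
        anovaOneway(v, rep(1:3, each = 10))@pValue < 0.001
    }, TRUE)
    expect_gte(mean(hits), 0.99)
})

test_that("Tukey HSD adjusted p-values match the studentized range", {
    vals <- c(12, 14, 11, 13,  18, 20, 19, 21,  12, 15, 13, 14)
    grp <- factor(rep(c("g1", "g2", "g3"), each = 4))
    res <- tukeyHsd(vals, grp)
    means <- tapply(vals, grp, mean)
    msw <- sum((vals - means[grp])^2) / 9
    for (k in seq_len(nrow(res@pairwise))) {
        a <- res@pairwise$group_a[k]; b <- res@pairwise$group_b[k]
        q <- abs(means[a] - means[b]) / sqrt(msw / 4)
        expect_equal(res@pairwise$adjusted_p[k],
            unname(ptukey(q, nmeans = 3, df = 9, lower.tail = FALSE)),
            tolerance = 1e-8)
    }
    expect_equal(unname(res@letters["g2"]), "a") # highest mean, own letter
    expect_setequal(unname(res@letters[c("g1", "g3")]), "b")
})

test_that("letter displays collapse and separate correctly", {
    ident <- tukeyHsd(rep(c(3, 4), 6), rep(c("a", "b", "c"), each = 4))
    expect_true(all(ident@letters == "a"))
    set.seed(10)
    v <- c(rnorm(10), rnorm(10), rnorm(10, 10))
    shift <- tukeyHsd(v, rep(c("a", "b", "c"), each = 10))
    expect_equal(unname(shift@letters["c"]), "a") # highest mean gets 'a'
    expect_false(shift@letters["c"] %in% shift@letters[c("a", "b")])
    # direct check of the insert-absorb algorithm
    cl <- compactLetters(c("A", "B", "C"),
        data.frame(a = c("A", "A", "B"), b = c("B", "C", "C")),
        significant = c(TRUE, FALSE, FALSE),
        means = c(A = 3, B = 1, C = 2))
    expect_false(any(strsplit(cl["A"], "")[[1]] %in%
        strsplit(cl["B"], "")[[1]]))
    expect_true(any(strsplit(cl["C"], "")[[1]] %in% strsplit(cl["A"], "")[[1]]))
    expect_true(any(strsplit(cl["C"], "")[[1]] %in% strsplit(cl["B"], "")[[1]]))
})

test_that("Kruskal-Wallis H matches the rank-sum formula with and without ties", {
    vals <- c(7, 1, 4, 9, 2, 6, 8, 3, 5) # no ties
    grp <- rep(c("a", "b", "c"), each = 3)
    res <- kruskalWallis(vals, grp)
    r <- rank(vals); N <- 9
    rbar <- tapply(r, grp, mean)
    hOracle <- 12 / (N * (N + 1)) * sum(3 * rbar^2) - 3 * (N + 1)
    expect_equal(unname(res@statistic), hOracle, tolerance = 1e-10)
    expect_equal(res@pValue, pchisq(hOracle, 2, lower.tail = FALSE),
        tolerance = 1e-10)
    # heavy ties: correction divisor 1 - sum(t^3 - t) / (N^3 - N)
    vals2 <- c(1, 1, 2, 2, 2, 3, 3, 1, 2)
    res2 <- kruskalWallis(vals2, grp)
    r2 <- rank(vals2); rbar2 <- tapply(r2, grp, mean)
    h0 <- 12 / (N * (N + 1)) * sum(3 * rbar2^2) - 3 * (N + 1)
    tie <- table(vals2)
    hTie <- h0 / (1 - sum(tie^3 - tie) / (N^3 - N))
    expect_equal(unname(res2@statistic), hTie, tolerance = 1e-10)
    # degenerate: all values identical
    flat <- kruskalWallis(rep(2, 9), grp)
    expect_equal(unname(flat@statistic), 0)
    expect_equal(flat@pValue, 1)
})

test_that("Dunn z statistics use the tie-corrected rank variance", {
    set.seed(5)
    vals <- round(rnorm(24), 1)
    grp <- rep(c("a", "b", "c", "d"), each = 6)
    res <- kruskalWallis(vals, grp)
    r <- rank(vals); N <- 24
    tie <- table(vals)
    sig2 <- N * (N + 1) / 12 - sum(tie^3 - tie) / (12 * (N - 1))
    rbar <- tapply(r, grp, mean)
    for (k in seq_len(nrow(res@pairwise))) {
        a <- res@pairwise$group_a[k]; b <- res@pairwise$group_b[k]
        zo <- (rbar[a] - rbar[b]) / sqrt(sig2 * (2 / 6))
        expect_equal(res@pairwise$z[k], unname(zo), tolerance = 1e-10)
    }
    expect_equal(res@pairwise$adjusted_p, p.adjust(res@pairwise$p, "BH"))
})

test_that("Welch t matches its closed form and handles degenerate input", {
    a <- c(3.1, 2.8, 3.6, 3.0, 2.5)
    b <- c(4.0, 4.4, 3.9, 4.8)
    res <- welchT(a, b)
    se2 <- var(a) / 5 + var(b) / 4
    tOracle <- (mean(a) - mean(b)) / sqrt(se2)
    dfOracle <- se2^2 / ((var(a) / 5)^2 / 4 + (var(b) / 4)^2 / 3)
    expect_equal(unname(res@statistic), tOracle, tolerance = 1e-10)
    expect_equal(unname(res@parameter), dfOracle, tolerance = 1e-8)
    expect_equal(res@pValue, 2 * pt(-abs(tOracle), dfOracle),
        tolerance = 1e-10)
    same <- welchT(rep(2, 5), rep(2, 5))
    expect_equal(unname(same@statistic), 0)
    expect_equal(same@pValue, 1)
})

test_that("the comparison battery holds its type-I error on null surveys", {
    reps <- 500
    rej <- matrix(FALSE, reps, 3,
        dimnames = list(NULL, c("anova", "kw", "welch")))
    base <- surveyConfig(nSpecies = 5L, nIndividuals = 6L, nSegments = 8L,
        taxonPool = c("A", "B", "C", "D"))
    for (i in seq_len(reps)) {
        sv <- generateSurvey(nullConfig(base, seed = 20000L + i))
        cr <- colonizationRate(sv)
        rej[i, "anova"] <-
            anovaOneway(cr$colonization_rate, cr$plant_species)@pValue < 0.05
        rej[i, "kw"] <- kruskalWallis(cr$colonization_rate, cr$plant_species,
            posthoc = FALSE)@pValue < 0.05
        rej[i, "welch"] <- welchT(
            cr$colonization_rate[cr$tissue == "stem"],
            cr$colonization_rate[cr$tissue == "root"])@pValue < 0.05
    }
    bound <- 2.576 * sqrt(0.05 * 0.95 / reps)
    for (tst in colnames(rej))
        expect_lt(abs(mean(rej[, tst]) - 0.05), bound + 1e-12)
})
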