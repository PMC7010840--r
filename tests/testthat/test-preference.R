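test_that("label shuffling preserves profiles, counts, and column totals", {
    set.seed(12)
    pres <- matrix(rbinom(8 * 5, 1, 0.5), nrow = 8)
    stm <- presence_stm(pres, rep(c("X", "Y"), each = 4))
    ens <- shuffleNull(stm, nPermutations = 50, seed = 4)
    obsCols <- colSums(abundances(ens@observed))
    for (i in seq_len(50)) {
        slm <- ens@pairCounts[, , i]
        expect_equal(colSums(slm), obsCols)       # column sums invariant
        expect_true(all(slm <= sampleCounts(ens@observed)[rownames(slm)]))
    }
    expect_error(shuffleNull(stm, nPermutations = 1), "at least 2")
    expect_error(shuffleNull(presence_stm(pres, rep("X", 8)), 10),
        "two plant species")
})

test_that("shuffle ensembles are reproducible from the seed", {
    set.seed(3)
    pres <- matrix(rbinom(40, 1, 0.5), nrow = 8)
    stm <- presence_stm(pres, rep(c("X", "Y"), each = 4))
    a <- shuffleNull(stm, 30, seed = 11)
    b <- shuffleNull(stm, 30, seed = 11)
    c <- shuffleNull(stm, 30, seed = 12)
    expect_identical(a@pairCounts, b@pairCounts)
    expect_false(identical(a@pairCounts, c@pairCounts))
})

test_that("identical sample profiles give a fully degenerate null", {
    pres <- matrix(1, nrow = 6, ncol = 3)
    stm <- presence_stm(pres, rep(c("X", "Y", "Z"), each = 2))
    ens <- shuffleNull(stm, 20, seed = 1)
    pp <- twoDimensionalPreference(ens, minOccurrence = 0)
    expect_true(all(pp$flag == "degenerate_null"))
    expect_true(all(pp$two_dp == 0))
    expect_true(all(is.na(pp$p_perm)))
})

test_that("a taxon present in every sample is degenerate under shuffling", {
    set.seed(21)
    pres <- cbind(1, matrix(rbinom(12 * 3, 1, 0.5), nrow = 12))
    stm <- presence_stm(pres, rep(c("X", "Y", "Z"), each = 4))
    pp <- twoDimensionalPreference(shuffleNull(stm, 30, seed = 2),
        minOccurrence = 0)
    ubiq <- pp[pp$taxon == "t1", ]
    expect_true(all(ubiq$flag == "degenerate_null"))
})

test_that("shuffle-null moments match exhaustive enumeration on a 4-sample toy", {
    pres <- rbind(
        c(1, 1, 0), c(1, 0, 0), c(0, 1, 1), c(0, 0, 1))
    species <- c("X", "X", "Y", "Y")
    stm <- presence_stm(pres, species)
    # exact null: every permutation of the label vector, equally likely
    perms <- perms_of(4)
    exCounts <- array(0, dim = c(2, 3, nrow(perms)))
    exD <- matrix(NA_real_, nrow(perms), 2)
    for (i in seq_len(nrow(perms))) {
        lab <- species[perms[i, ]]
        slm <- rowsum(pres, factor(lab, levels = c("X", "Y")))
        exCounts[, , i] <- slm
        exD[i, ] <- dPrime(slm)$d_prime
    }
    popsd <- function(x) sqrt(mean((x - mean(x))^2))
    exMean <- apply(exCounts, c(1, 2), mean)
    exSd <- apply(exCounts, c(1, 2), popsd)
    ens <- shuffleNull(stm, nPermutations = 20000, seed = 99)
    shMean <- apply(ens@pairCounts, c(1, 2), mean)
    shSd <- apply(ens@pairCounts, c(1, 2), sd)
    expect_lt(max(abs(shMean - exMean) / pmax(exMean, 0.1)), 0.02)
    nz <- exSd > 0
    expect_lt(max(abs(shSd[nz] - exSd[nz]) / exSd[nz]), 0.02)
    expect_equal(shSd[!nz], exSd[!nz]) # degenerate cells are exactly 0
    # d' null moments agree too
    expect_lt(max(abs(colMeans(ens@dPlant) - colMeans(exD)) /
        pmax(colMeans(exD), 0.1)), 0.02)
    # and the package z equals the z recomputed from the ensemble slots
    pp <- twoDimensionalPreference(ens, minOccurrence = 0)
    obs <- abundances(ens@observed)
    k <- which(pp$plant_species == "X" & pp$taxon == "t1")
    expect_equal(pp$two_dp[k],
        (obs["X", "t1"] - mean(ens@pairCounts["X", "t1", ])) /
            sd(ens@pairCounts["X", "t1", ]))
})

test_that("standardized d' is zero when observed equals the null mean", {
    set.seed(8)
    pres <- matrix(rbinom(60, 1, 0.5), nrow = 12)
    stm <- presence_stm(pres, rep(c("X", "Y", "Z"), each = 4))
    ens <- shuffleNull(stm, 200, seed = 5)
    rec <- standardizedDPrime(ens, "plant", minOccurrence = 0)
    obs <- dPrime(ens@observed)$d_prime
    for (j in which(rec$flag == "ok")) {
        expect_equal(unname(rec$d_prime_std[j]),
            (obs[j] - mean(ens@dPlant[, j])) / sd(ens@dPlant[, j]))
    }
    # permutation p is the add-one rank
    j <- which(rec$flag == "ok")[1]
    expect_equal(rec$p_perm[j],
        (1 + sum(ens@dPlant[, j] >= obs[j] - 1e-12)) / (1 + 200))
    expect_true(all(rec$p_perm > 0 & rec$p_perm <= 1, na.rm = TRUE))
})

test_that("Benjamini-Hochberg adjustment follows the step-up formula", {
    expect_equal(fdrAdjust(rep(0.01, 10)), rep(0.01, 10))
    expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(fdrAdjust(0.0123), 0.0123)
    p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.6)
    expect_equal(fdrAdjust(p),
        pmin(1, rev(cummin(rev(p * 6 / seq_len(6))))))
    expect_equal(fdrAdjust(c(0.02, NA, 0.04)),
        c(0.04, NA, 0.04)) # missing entries don't count toward the family
})

test_that("planted avoidances give symmetric negative 2DP signals", {
    zs <- ps <- numeric(8)
    for (i in 1:8) {
        cfg <- nullConfig(surveyConfig(seed = 70L + i))
        cfg <- plantPreference(cfg, "taxon_01", "plant_02", weight = 0.02)
        pr <- preferenceAnalysis(generateSurvey(cfg), nPermutations = 300,
            seed = i)
        p <- as.data.frame(pairPreferences(pr))
        k <- p$plant_species == "plant_02" & p$taxon == "taxon_01"
        zs[i] <- p$two_dp[k]; ps[i] <- p$p_fdr[k]
    }
    expect_true(all(zs < 0))        # avoidance always shows a deficit
    expect_lt(median(zs), -2.5)     # and a strong one
    expect_gte(mean(ps < 0.05), 0.75)
})

test_that("the preference wrapper records its parameters and writes outputs", {
    sv <- generateSurvey(surveyConfig(nSpecies = 4L, nIndividuals = 5L,
        taxonPool = sprintf("tx%02d", 1:6), seed = 14L))
    pr <- preferenceAnalysis(sv, nPermutations = 50, seed = 9,
        sampleUnit = "individual")
    expect_equal(pr@params$n_permutations, 50L)
    expect_equal(pr@params$seed, 9L)
    expect_equal(pr@params$sample_unit, "individual")
    expect_equal(nrow(dPrimeRecords(pr, "plant")), 4L)
    m <- twoDPMatrix(pr)
    expect_equal(dim(m), c(4L, length(taxa(sv))))
    dir <- withr::local_tempdir()
    path <- file.path(dir, "pref.tsv")
    writePreference(pr, path)
    expect_true(file.exists(path))
    expect_true(file.exists(file.path(dir, "pref.plant_dprime.tsv")))
    side <- jsonlite::read_json(file.path(dir, "pref.json"))
    expect_equal(side$seed, 9L)
    expect_equal(side$n_permutations, 50L)
})
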