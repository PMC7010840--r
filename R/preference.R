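#' Label-shuffling permutation null for preference statistics
#'
#' Builds the null ensemble behind the standardized d' and 2DP statistics:
#' in each permutation the plant-species labels of the sample rows are
#' shuffled (a permutation of the label vector, so per-species sample counts
#' are preserved and every sample keeps its own taxon profile), the shuffled
#' samples are re-aggregated into a randomized species-level matrix, and the
#' randomized pair counts and d' values on both axes are recorded.
#'
#' @param x a presence-mode [SampleTaxonMatrix] with at least two plant
#'   species
#' @param nPermutations number of permutations R (>= 2; default 1000)
#' @param seed RNG seed for the shuffles
#' @return a [NullEnsemble]
#' @export
shuffleNull <- function(x, nPermutations = 1000L, seed = 1L) {
    stopifnot(is(x, "SampleTaxonMatrix"))
    if (!identical(metadata(x)$mode, "presence"))
        stop("shuffleNull needs a presence-mode matrix; see binarize()")
    nPermutations <- as.integer(nPermutations)
    if (nPermutations < 2L) stop("need at least 2 permutations (SD undefined)")
    labels <- plantSpecies(x)
    spLevels <- unique(labels)
    if (length(spLevels) < 2L) stop("need at least two plant species")
    obs <- speciesLevelMatrix(x)
    pres <- t(assay(x, "abundance"))   # samples x taxa
    S <- length(spLevels); K <- ncol(pres)
    fac <- factor(labels, levels = spLevels)
    pairCounts <- array(0L, dim = c(S, K, nPermutations),
        dimnames = list(spLevels, colnames(pres), NULL))
    dPlant <- matrix(NA_real_, nPermutations, S, dimnames = list(NULL, spLevels))
    dTaxon <- matrix(NA_real_, nPermutations, K,
        dimnames = list(NULL, colnames(pres)))
    withr::with_seed(as.integer(seed), {
        for (i in seq_len(nPermutations)) {
            permFac <- fac[sample.int(length(fac))]
            slm <- rowsum(pres, permFac)
            pairCounts[, , i] <- slm
            dPlant[i, ] <- cpp_dfun_rows(slm)[, "d_prime"]
            dTaxon[i, ] <- cpp_dfun_rows(t(slm))[, "d_prime"]
        }
    })
    new("NullEnsemble", observed = obs, pairCounts = pairCounts,
        dPlant = dPlant, dTaxon = dTaxon,
        nPermutations = nPermutations, seed = as.integer(seed))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment of a family of p-values. Missing entries (e.g.
#' degenerate-null tests) are left missing and do not count toward the
#' family size.
#'
#' @param p numeric vector of p-values
#' @return adjusted p-values, same length and order
#' @export
fdrAdjust <- function(p) stats::p.adjust(p, method = "BH")

std_records <- function(entity, dObs, dNull, pMode, rare = NULL) {
    R <- nrow(dNull)
    nullMean <- colMeans(dNull, na.rm = TRUE)
    nullSd <- apply(dNull, 2, stats::sd, na.rm = TRUE)
    nValid <- colSums(!is.na(dNull))
    z <- (dObs - nullMean) / nullSd
    flag <- rep("ok", length(entity))
    flag[is.na(dObs)] <- "undefined"
    deg <- !is.na(dObs) & (!is.finite(nullSd) | nullSd == 0)
    flag[deg] <- "degenerate_null"
    z[flag != "ok"] <- NA_real_
    pPerm <- pPermTwo <- rep(NA_real_, length(entity))
    for (j in seq_along(entity)) {
        if (is.na(dObs[j]) || nValid[j] < 2) next
        v <- dNull[, j]
        pPerm[j] <- (1 + sum(v >= dObs[j] - 1e-12, na.rm = TRUE)) / (1 + nValid[j])
        if (flag[j] == "ok") {
            dev <- abs(dObs[j] - nullMean[j])
            pPermTwo[j] <- (1 + sum(abs(v - nullMean[j]) >= dev - 1e-12,
                na.rm = TRUE)) / (1 + nValid[j])
        }
    }
    pNorm <- 2 * stats::pnorm(-abs(z))
    if (!is.null(rare)) flag[flag == "ok" & rare] <- "rare"
    pUse <- if (pMode == "normal") pNorm else pPerm
    pUse[flag != "ok"] <- NA_real_  # only untroubled tests enter the family
    DataFrame(entity = entity, d_prime_obs = dObs,
        null_mean = nullMean, null_sd = nullSd,
        d_prime_std = z, p_perm = pPerm, p_perm_two = pPermTwo,
        p_norm = pNorm, p_fdr = fdrAdjust(pUse), flag = flag)
}

#' Standardized d' against the permutation null
#'
#' Standardizes each observed d' value against the label-shuffling null:
#' `standardized d' = (d'_observed - Mean(d'_randomized)) / SD(d'_randomized)`
#' (SD with denominator n-1). Permutation p-values are rank-based with
#' add-one correction, one-sided toward specialization (`p_perm`, reported
#' with a two-sided variant); `p_norm` is the two-sided normal-tail p of the
#' z-score. The FDR adjustment is applied within this axis's family, on the
#' p-value kind selected by `pMode`.
#'
#' @param ensemble a [NullEnsemble] from [shuffleNull()]
#' @param axis `"plant"` (per plant species) or `"taxon"` (per fungal taxon)
#' @param pMode p-value fed to the FDR adjustment: `"normal"` (default;
#'   reproduces the |z| > ~2.5 <-> P_FDR < 0.05 correspondence) or
#'   `"permutation"`
#' @param minOccurrence frequency floor for the taxon axis: taxa present in
#'   fewer samples overall are scored but flagged `"rare"` and kept out of
#'   the FDR family, because the shuffled distribution of such sparse
#'   profiles is too discrete for a trustworthy z-score. Default: 5 percent
#'   of the samples (a conventional prevalence filter)
#' @return DataFrame of standardized d' records; entities with an undefined
#'   d', a zero-variance null, or a rare profile are flagged and excluded
#'   from the FDR family
#' @export
standardizedDPrime <- function(ensemble, axis = c("plant", "taxon"),
                               pMode = c("normal", "permutation"),
                               minOccurrence = NULL) {
    stopifnot(is(ensemble, "NullEnsemble"))
    axis <- match.arg(axis)
    pMode <- match.arg(pMode)
    minOccurrence <- minOccurrence %||%
        ceiling(0.05 * sum(sampleCounts(ensemble@observed)))
    obs <- dPrime(ensemble@observed, axis = axis)
    dNull <- if (axis == "plant") ensemble@dPlant else ensemble@dTaxon
    rare <- if (axis == "taxon")
        colSums(abundances(ensemble@observed)) < minOccurrence else NULL
    std_records(obs$entity, obs$d_prime, dNull, pMode, rare = rare)
}

#' Two-dimensional preference (2DP) of plant-fungus pairs
#'
#' For every (plant species i, fungal taxon j) pair, compares the observed
#' number of samples exhibiting the combination with its distribution under
#' the label-shuffling null:
#' `2DP(i, j) = (N_observed - Mean(N_randomized)) / SD(N_randomized)`.
#' Positive values indicate the pair occurs more often than expected
#' (preference), negative values less often (avoidance). Two-sided
#' permutation p-values use the add-one rank rule; `p_norm` is the two-sided
#' normal tail of the z-score. Pairs whose count is invariant under
#' shuffling (`SD = 0`) are flagged `degenerate_null` with `2DP = 0` and no
#' p-value.
#'
#' @inheritParams standardizedDPrime
#' @param taxaFilter `"observed"` keeps taxa seen at least once overall
#'   (default); `"all"` keeps every column of the matrix
#' @param minOccurrence frequency floor: pairs of taxa present in fewer
#'   samples overall are scored but flagged `"rare"` and excluded from the
#'   FDR family (their shuffled cell counts are a discrete mass on a few
#'   values, so tail probabilities are unreliable)
#' @return DataFrame of pair records (plant_species, taxon, n_observed,
#'   null_mean, null_sd, two_dp, p_perm, p_norm, p_fdr, flag)
#' @export
twoDimensionalPreference <- function(ensemble,
                                     pMode = c("normal", "permutation"),
                                     taxaFilter = c("observed", "all"),
                                     minOccurrence = NULL) {
    stopifnot(is(ensemble, "NullEnsemble"))
    pMode <- match.arg(pMode)
    taxaFilter <- match.arg(taxaFilter)
    minOccurrence <- minOccurrence %||%
        ceiling(0.05 * sum(sampleCounts(ensemble@observed)))
    obs <- abundances(ensemble@observed)
    keep <- if (taxaFilter == "observed") colSums(obs) > 0 else
        rep(TRUE, ncol(obs))
    pc <- ensemble@pairCounts[, keep, , drop = FALSE]
    obs <- obs[, keep, drop = FALSE]
    S <- nrow(obs); K <- ncol(obs); R <- dim(pc)[3]
    flat <- matrix(pc, nrow = S * K, ncol = R)   # pairs x permutations
    nullMean <- rowMeans(flat)
    nullSd <- apply(flat, 1, stats::sd)
    nObs <- as.vector(obs)
    deg <- nullSd == 0
    z <- ifelse(deg, 0, (nObs - nullMean) / nullSd)
    dev <- abs(nObs - nullMean)
    ge <- rowSums(abs(flat - nullMean) >= dev - 1e-12)
    pPerm <- ifelse(deg, NA_real_, (1 + ge) / (1 + R))
    pNorm <- ifelse(deg, NA_real_, 2 * stats::pnorm(-abs(z)))
    flag <- ifelse(deg, "degenerate_null", "ok")
    rare <- rep(colSums(obs) < minOccurrence, each = S)
    flag[flag == "ok" & rare] <- "rare"
    pUse <- if (pMode == "normal") pNorm else pPerm
    pUse[flag != "ok"] <- NA_real_
    DataFrame(
        plant_species = rep(rownames(obs), times = K),
        taxon = rep(colnames(obs), each = S),
        n_observed = as.integer(nObs),
        null_mean = nullMean, null_sd = nullSd, two_dp = z,
        p_perm = pPerm, p_norm = pNorm, p_fdr = fdrAdjust(pUse),
        flag = flag)
}

#' Host-preference analysis of an isolation survey
#'
#' End-to-end wrapper for the permutation preference machinery: binarizes
#' the sample x taxon matrix, builds the label-shuffling null, and returns
#' standardized d' records for both axes together with pairwise 2DP
#' records. FDR control is applied separately within the three families
#' (plant-level d', fungus-level d', pairwise 2DP).
#'
#' @param x a [SurveyTable] or a [SampleTaxonMatrix]
#' @param sampleUnit sample unit when `x` is a survey:
#'   `"individual_x_tissue"` (default) or `"individual"`
#' @param nPermutations number of label shuffles (default 1000)
#' @param seed RNG seed
#' @param pMode p-value kind fed to FDR control; see [standardizedDPrime()]
#' @param minOccurrence frequency floor for taxon-axis and pairwise tests;
#'   see [twoDimensionalPreference()]
#' @return a [PreferenceResult]
#' @export
preferenceAnalysis <- function(x, sampleUnit = c("individual_x_tissue", "individual"),
                               nPermutations = 1000L, seed = 1L,
                               pMode = c("normal", "permutation"),
                               minOccurrence = NULL) {
    sampleUnit <- match.arg(sampleUnit)
    pMode <- match.arg(pMode)
    stm <- if (is(x, "SurveyTable"))
        sampleTaxonMatrix(x, sampleUnit = sampleUnit, mode = "presence")
    else binarize(x)
    ens <- shuffleNull(stm, nPermutations = nPermutations, seed = seed)
    new("PreferenceResult",
        plantDPrime = standardizedDPrime(ens, "plant", pMode,
            minOccurrence = minOccurrence),
        taxonDPrime = standardizedDPrime(ens, "taxon", pMode,
            minOccurrence = minOccurrence),
        pairs = twoDimensionalPreference(ens, pMode,
            minOccurrence = minOccurrence),
        params = list(n_permutations = as.integer(nPermutations),
            seed = as.integer(seed),
            min_occurrence = minOccurrence %||%
                ceiling(0.05 * ncol(stm)),
            sample_unit = if (is(x, "SurveyTable")) sampleUnit else
                metadata(stm)$sample_unit,
            p_mode = pMode))
}

#' Matrix of 2DP values for heatmap export
#'
#' @param result a [PreferenceResult]
#' @return plant species x taxon matrix of 2DP z-scores
#' @export
twoDPMatrix <- function(result) {
    stopifnot(is(result, "PreferenceResult"))
    p <- result@pairs
    sp <- unique(p$plant_species); tx <- unique(p$taxon)
    m <- matrix(NA_real_, length(sp), length(tx), dimnames = list(sp, tx))
    m[cbind(p$plant_species, p$taxon)] <- p$two_dp
    m
}

#' Write preference results as TSV with a JSON sidecar
#'
#' Writes the pairwise 2DP table to `path`, the two d' tables alongside
#' (suffixes `.plant_dprime.tsv`, `.taxon_dprime.tsv`), and a `.json`
#' sidecar recording seed, permutation count, sample unit and package
#' version.
#'
#' @param result a [PreferenceResult]
#' @param path output path of the pair table
#' @return `path`, invisibly
#' @export
writePreference <- function(result, path) {
    stopifnot(is(result, "PreferenceResult"))
    wr <- function(d, p) utils::write.table(as.data.frame(d), p, sep = "\t",
        quote = FALSE, row.names = FALSE)
    wr(result@pairs, path)
    base <- sub("\\.tsv$", "", path)
    wr(result@plantDPrime, paste0(base, ".plant_dprime.tsv"))
    wr(result@taxonDPrime, paste0(base, ".taxon_dprime.tsv"))
    meta <- c(result@params,
        list(package_version = as.character(utils::packageVersion("endosurvey"))))
    jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE)
    invisible(path)
}
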