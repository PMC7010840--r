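#' Configure a synthetic isolation survey
#'
#' The defaults emulate a 10 plant species x 10 individuals x 2 tissue types
#' (stem, root) x 8 segments design (1600 incubated segments). Per-segment
#' colonization probabilities default to species-specific values spanning
#' 0.075-0.8375 in stems and 0.3375-0.975 in roots, the ranges reported for
#' desert halophyte surveys of this design; the taxon pool defaults to 36
#' fungal taxa with geometrically decaying base weights (a few dominant taxa,
#' a long tail of rare ones) and neutral preference weights.
#'
#' @param nSpecies number of plant species
#' @param nIndividuals individuals per species
#' @param tissues tissue type labels
#' @param nSegments segments per individual and tissue
#' @param colonizationProb species x tissue probability matrix, or a scalar
#'   recycled to all cells; `NULL` for the defaults above
#' @param taxonPool fungal taxon labels
#' @param baseWeight positive per-taxon weights of the categorical taxon
#'   draw; `NULL` for a 0.85 geometric decay over the pool
#' @param preferenceWeight taxon x species x tissue array of positive
#'   multipliers; `NULL` for all 1 (no host or tissue structure)
#' @param speciesNames plant species labels
#' @param seed integer seed governing the whole survey
#' @return a [SurveyConfig]
#' @export
surveyConfig <- function(nSpecies = 10L, nIndividuals = 10L,
                         tissues = c("stem", "root"), nSegments = 8L,
                         colonizationProb = NULL,
                         taxonPool = sprintf("taxon_%02d", seq_len(36)),
                         baseWeight = NULL, preferenceWeight = NULL,
                         speciesNames = sprintf("plant_%02d", seq_len(nSpecies)),
                         seed = 1L) {
    nSpecies <- as.integer(nSpecies)
    nIndividuals <- as.integer(nIndividuals)
    nSegments <- as.integer(nSegments)
    nT <- length(tissues)
    if (is.null(colonizationProb)) {
        if (identical(tissues, c("stem", "root")) && nSpecies >= 1L) {
            colonizationProb <- cbind(
                stem = seq(0.075, 0.8375, length.out = nSpecies),
                root = seq(0.3375, 0.975, length.out = nSpecies))
        } else {
            colonizationProb <- matrix(0.65, nSpecies, nT)
        }
    } else if (length(colonizationProb) == 1L) {
        colonizationProb <- matrix(colonizationProb, nSpecies, nT)
    }
    colonizationProb <- as.matrix(colonizationProb)
    dimnames(colonizationProb) <- list(speciesNames, tissues)
    if (is.null(baseWeight)) baseWeight <- 0.85^(seq_along(taxonPool) - 1)
    if (is.null(preferenceWeight))
        preferenceWeight <- array(1, dim = c(length(taxonPool), nSpecies, nT))
    preferenceWeight <- array(preferenceWeight,
        dim = c(length(taxonPool), nSpecies, nT),
        dimnames = list(taxonPool, speciesNames, tissues))
    new("SurveyConfig", nSpecies = nSpecies, nIndividuals = nIndividuals,
        tissues = as.character(tissues), nSegments = nSegments,
        colonizationProb = colonizationProb,
        taxonPool = as.character(taxonPool),
        baseWeight = as.numeric(baseWeight),
        preferenceWeight = preferenceWeight, seed = as.integer(seed))
}

#' Null counterpart of a survey configuration
#'
#' Returns a copy of `config` with all preference weights set to 1 and the
#' colonization probability constant (the mean of the input matrix) across
#' species and tissues, so the generated surveys carry no true host or
#' tissue structure. Used to study type-I error of the preference and
#' comparison machinery.
#'
#' @param config a [SurveyConfig]
#' @param seed optional replacement seed
#' @return a [SurveyConfig] with no built-in structure
#' @export
nullConfig <- function(config, seed = config@seed) {
    stopifnot(is(config, "SurveyConfig"))
    config@colonizationProb[] <- mean(config@colonizationProb)
    config@preferenceWeight[] <- 1
    config@seed <- as.integer(seed)
    validObject(config)
    config
}

#' Plant a host/tissue preference into a configuration
#'
#' Multiplies the preference weight of one taxon on the given species (and
#' optionally tissue) by `weight`; `weight > 1` plants a preference,
#' `weight < 1` an avoidance.
#'
#' @param config a [SurveyConfig]
#' @param taxon taxon label in the pool
#' @param species plant species label (or index)
#' @param tissue optional tissue label; default applies to all tissues
#' @param weight positive multiplier (10 = strong preference)
#' @return the modified [SurveyConfig]
#' @export
plantPreference <- function(config, taxon, species, tissue = NULL, weight = 10) {
    stopifnot(is(config, "SurveyConfig"), weight > 0)
    if (is.null(tissue)) tissue <- config@tissues
    config@preferenceWeight[taxon, species, tissue] <-
        config@preferenceWeight[taxon, species, tissue] * weight
    validObject(config)
    config
}

#' Generate a synthetic isolation survey
#'
#' Each incubated segment is colonized with probability
#' `colonizationProb[species, tissue]`; a colonized segment yields exactly
#' one taxon, drawn from the pool with probability proportional to
#' `baseWeight * preferenceWeight[taxon, species, tissue]`. Uncolonized
#' segments carry the sentinel taxon `"none"`. The draw is fully reproducible
#' from `config@seed` and leaves the caller's RNG state untouched.
#'
#' @param config a [SurveyConfig]
#' @return a [SurveyTable] with
#'   `nSpecies * nIndividuals * length(tissues) * nSegments` records
#' @export
generateSurvey <- function(config) {
    stopifnot(is(config, "SurveyConfig"))
    validObject(config)
    sp <- rownames(config@colonizationProb)
    nS <- config@nSpecies; nI <- config@nIndividuals
    tis <- config@tissues; nSeg <- config@nSegments
    grid <- expand.grid(
        segment_index = seq_len(nSeg),
        tissue = tis,
        individual_id = sprintf("ind_%02d", seq_len(nI)),
        plant_species = sp,
        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[, rev(seq_along(grid))]
    taxon <- rep(NONE_LABEL, nrow(grid))
    withr::with_seed(config@seed, {
        for (s in seq_len(nS)) {
            for (t in seq_along(tis)) {
                idx <- which(grid$plant_species == sp[s] & grid$tissue == tis[t])
                col <- stats::runif(length(idx)) < config@colonizationProb[s, t]
                if (any(col)) {
                    w <- config@baseWeight * config@preferenceWeight[, s, t]
                    taxon[idx[col]] <- sample(config@taxonPool, sum(col),
                        replace = TRUE, prob = w)
                }
            }
        }
    })
    grid$taxon <- taxon
    surveyTable(grid, speciesList = sp)
}
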