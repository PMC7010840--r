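#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assayNames colData rowData
#' @useDynLib endosurvey, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

TISSUES_DEFAULT <- c("stem", "root")
NONE_LABEL <- "none"

#' SurveyConfig: generative parameters of a synthetic isolation survey
#'
#' Describes a segment-based isolation survey of culturable endophytic fungi:
#' its dimensions (plant species x individuals x tissue types x segments per
#' tissue), per-(species, tissue) colonization probabilities, and a
#' categorical taxon model with per-taxon base weights modulated by
#' (taxon, species, tissue) preference multipliers.
#'
#' @slot nSpecies number of plant species surveyed
#' @slot nIndividuals individuals sampled per species
#' @slot tissues tissue type labels (default stem, root)
#' @slot nSegments incubated segments per individual and tissue
#' @slot colonizationProb species x tissue matrix of per-segment colonization
#'   probabilities in `[0, 1]`
#' @slot taxonPool fungal taxon labels available to the generator
#' @slot baseWeight per-taxon positive base weight of the categorical draw
#' @slot preferenceWeight taxon x species x tissue array of positive
#'   multiplicative preference weights (1 = neutral)
#' @slot seed integer seed governing the whole survey
#' @exportClass SurveyConfig
setClass("SurveyConfig",
    representation(
        nSpecies = "integer",
        nIndividuals = "integer",
        tissues = "character",
        nSegments = "integer",
        colonizationProb = "matrix",
        taxonPool = "character",
        baseWeight = "numeric",
        preferenceWeight = "array",
        seed = "integer"
    )
)

setValidity("SurveyConfig", function(object) {
    msg <- character()
    if (object@nSpecies < 1L || object@nIndividuals < 1L || object@nSegments < 1L)
        msg <- c(msg, "dimensions must be >= 1")
    if (length(object@tissues) < 1L || anyDuplicated(object@tissues))
        msg <- c(msg, "tissues must be non-empty and unique")
    cp <- object@colonizationProb
    if (!identical(dim(cp), c(object@nSpecies, length(object@tissues))))
        msg <- c(msg, "colonizationProb must be nSpecies x length(tissues)")
    if (any(is.na(cp)) || any(cp < 0) || any(cp > 1))
        msg <- c(msg, "colonization probabilities must lie in [0, 1]")
    if (length(object@taxonPool) < 1L || anyDuplicated(object@taxonPool))
        msg <- c(msg, "taxonPool must be non-empty and unique")
    if (NONE_LABEL %in% object@taxonPool)
        msg <- c(msg, sprintf("'%s' is reserved for uncolonized segments", NONE_LABEL))
    if (length(object@baseWeight) != length(object@taxonPool) ||
        any(!is.finite(object@baseWeight)) || any(object@baseWeight <= 0))
        msg <- c(msg, "baseWeight must be positive, one per taxon")
    pw <- object@preferenceWeight
    if (!identical(dim(pw),
        c(length(object@taxonPool), object@nSpecies, length(object@tissues))))
        msg <- c(msg, "preferenceWeight must be taxon x species x tissue")
    else if (any(!is.finite(pw)) || any(pw <= 0))
        msg <- c(msg, "preference weights must be positive and finite")
    if (length(msg)) msg else TRUE
})

#' SurveyTable: validated segment-level isolation records
#'
#' One row per incubated tissue segment; `taxon` is the recovered fungal
#' taxon or the sentinel `"none"` for an uncolonized segment. The
#' (plant_species, individual_id, tissue, segment_index) key is unique.
#'
#' @slot records data.frame with columns plant_species, individual_id,
#'   tissue, segment_index, taxon (extra columns are carried along untouched)
#' @slot speciesList ordered plant species labels
#' @slot taxonList ordered fungal taxon labels, excluding the sentinel
#' @exportClass SurveyTable
setClass("SurveyTable",
    representation(
        records = "data.frame",
        speciesList = "character",
        taxonList = "character"
    )
)

REQ_COLS <- c("plant_species", "individual_id", "tissue", "segment_index", "taxon")

setValidity("SurveyTable", function(object) {
    rec <- object@records
    msg <- character()
    miss <- setdiff(REQ_COLS, names(rec))
    if (length(miss))
        return(paste("missing record columns:", paste(miss, collapse = ", ")))
    if (nrow(rec)) {
        chr <- c("plant_species", "individual_id", "tissue", "taxon")
        for (cl in chr) {
            v <- rec[[cl]]
            if (!is.character(v)) return(sprintf("column '%s' must be character", cl))
            if (any(is.na(v)) || any(!nzchar(v)))
                msg <- c(msg, sprintf("column '%s' has empty or missing values", cl))
        }
        if (!is.numeric(rec$segment_index) || any(rec$segment_index < 1) ||
            any(rec$segment_index != round(rec$segment_index)))
            msg <- c(msg, "segment_index must be integers >= 1")
        key <- paste(rec$plant_species, rec$individual_id, rec$tissue,
            rec$segment_index, sep = "\r")
        dup <- duplicated(key)
        if (any(dup))
            msg <- c(msg, sprintf(
                "duplicated (species, individual, tissue, segment) key, e.g. record %d",
                which(dup)[1]))
        if (!all(rec$plant_species %in% object@speciesList))
            msg <- c(msg, "record plant_species not all present in speciesList")
        tx <- setdiff(unique(rec$taxon), NONE_LABEL)
        if (!all(tx %in% object@taxonList))
            msg <- c(msg, "record taxa not all present in taxonList")
    }
    if (NONE_LABEL %in% object@taxonList)
        msg <- c(msg, sprintf("taxonList must not contain '%s'", NONE_LABEL))
    if (length(msg)) msg else TRUE
})

#' SampleTaxonMatrix: sample x fungal taxon abundance container
#'
#' A `SummarizedExperiment` holding one assay named `"abundance"` with fungal
#' taxa as rows and samples as columns (Bioconductor orientation; delimited
#' exports transpose to samples-as-rows). `colData` carries plant_species,
#' individual_id and, when the sample unit resolves tissues, tissue.
#' `metadata(x)$mode` records whether entries are segment counts or 0/1
#' presence indicators.
#'
#' @exportClass SampleTaxonMatrix
setClass("SampleTaxonMatrix", contains = "SummarizedExperiment")

setValidity("SampleTaxonMatrix", function(object) {
    msg <- character()
    if (!"abundance" %in% SummarizedExperiment::assayNames(object))
        return("assay 'abundance' is required")
    a <- assay(object, "abundance")
    if (any(is.na(a)) || any(a < 0) || any(a != round(a)))
        msg <- c(msg, "abundance entries must be non-negative integers")
    mode <- metadata(object)$mode
    if (is.null(mode) || !mode %in% c("count", "presence"))
        msg <- c(msg, "metadata(x)$mode must be 'count' or 'presence'")
    else if (mode == "presence" && nrow(a) && any(a > 1))
        msg <- c(msg, "presence mode entries must be 0/1")
    need <- c("plant_species", "individual_id")
    if (!all(need %in% colnames(colData(object))))
        msg <- c(msg, "colData must contain plant_species and individual_id")
    if (length(msg)) msg else TRUE
})

#' SpeciesLevelMatrix: plant species x fungal taxon co-occurrence counts
#'
#' Cell (i, j) counts the samples of plant species i in which fungal taxon j
#' was present; the aggregation of a presence-mode [SampleTaxonMatrix].
#'
#' @slot values integer matrix, plant species as rows, taxa as columns
#' @slot nSamples per-species number of contributing samples
#' @exportClass SpeciesLevelMatrix
setClass("SpeciesLevelMatrix",
    representation(values = "matrix", nSamples = "integer")
)

setValidity("SpeciesLevelMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "values must have species rownames and taxon colnames")
    if (any(v < 0) || any(v != round(v)))
        msg <- c(msg, "cells must be non-negative integers")
    if (length(object@nSamples) != nrow(v))
        msg <- c(msg, "nSamples must align with rows")
    else if (any(v > object@nSamples))
        msg <- c(msg, "a cell exceeds the sample count of its species")
    if (length(msg)) msg else TRUE
})

#' NullEnsemble: permutation null for host-preference statistics
#'
#' Holds, for R label-shuffling permutations of a presence-mode sample x
#' taxon matrix, the randomized species-level pair counts and the d'
#' specialization values on both axes, plus the observed quantities they are
#' compared against.
#'
#' @slot observed the observed [SpeciesLevelMatrix]
#' @slot pairCounts species x taxon x R array of randomized pair counts
#' @slot dPlant R x nSpecies matrix of randomized plant-axis d' values
#' @slot dTaxon R x nTaxa matrix of randomized fungus-axis d' values
#' @slot nPermutations number of permutations R
#' @slot seed RNG seed used for the shuffles
#' @exportClass NullEnsemble
setClass("NullEnsemble",
    representation(
        observed = "SpeciesLevelMatrix",
        pairCounts = "array",
        dPlant = "matrix",
        dTaxon = "matrix",
        nPermutations = "integer",
        seed = "integer"
    )
)

#' PreferenceResult: host/tissue preference statistics
#'
#' Results of the permutation preference analysis: per-plant and per-fungus
#' standardized d' records and per-pair two-dimensional preference (2DP)
#' z-scores, each with permutation and normal-tail p-values and an
#' FDR-adjusted p-value within its own family.
#'
#' @slot plantDPrime DataFrame of plant-axis standardized d' records
#' @slot taxonDPrime DataFrame of fungus-axis standardized d' records
#' @slot pairs DataFrame of per-(species, taxon) 2DP records
#' @slot params list: n_permutations, seed, sample_unit, p_mode
#' @exportClass PreferenceResult
setClass("PreferenceResult",
    representation(
        plantDPrime = "DataFrame",
        taxonDPrime = "DataFrame",
        pairs = "DataFrame",
        params = "list"
    )
)

#' CCAResult: canonical correspondence analysis fit
#'
#' @slot eigenvalues constrained eigenvalues, non-increasing
#' @slot totalInertia total inertia of the chi-square transformed matrix
#' @slot siteScores samples x axes linear-combination scores, orthonormal
#'   under the row-weight inner product
#' @slot siteScoresWA samples x axes weighted-average scores
#' @slot speciesScores taxa x axes scores
#' @slot rowWeights sample weights used in the fit
#' @slot rank rank of the constrained solution
#' @exportClass CCAResult
setClass("CCAResult",
    representation(
        eigenvalues = "numeric",
        totalInertia = "numeric",
        siteScores = "matrix",
        siteScoresWA = "matrix",
        speciesScores = "matrix",
        rowWeights = "numeric",
        rank = "integer"
    )
)

#' PermanovaResult: distance-based multivariate ANOVA table
#'
#' @slot terms data.frame: term, df, sum_of_squares, r_squared, pseudo_f,
#'   p_value (residual and total rows carry NA statistics)
#' @slot nPermutations number of permutations used (0 for exact enumeration)
#' @slot exact TRUE when p-values come from exhaustive enumeration
#' @slot distance distance index used
#' @slot seed RNG seed for sampled permutations
#' @exportClass PermanovaResult
setClass("PermanovaResult",
    representation(
        terms = "data.frame",
        nPermutations = "integer",
        exact = "logical",
        distance = "character",
        seed = "integer"
    )
)

#' ComparisonResult: a univariate group-comparison test
#'
#' @slot test label of the test performed
#' @slot statistic named test statistic
#' @slot parameter named df or group sizes
#' @slot pValue p-value of the omnibus test
#' @slot pairwise data.frame of pairwise follow-ups (possibly empty)
#' @slot letters named compact letter display (possibly empty)
#' @slot note diagnostics, e.g. applied transformations
#' @exportClass ComparisonResult
setClass("ComparisonResult",
    representation(
        test = "character",
        statistic = "numeric",
        parameter = "numeric",
        pValue = "numeric",
        pairwise = "data.frame",
        letters = "character",
        note = "character"
    )
)
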