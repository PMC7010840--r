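#' Segment-level records of a survey
#' @param x a [SurveyTable]
#' @return data.frame of isolation records
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname records
#' @export
setMethod("records", "SurveyTable", function(x) x@records)

#' Plant species labels of a survey or matrix
#' @param x a [SurveyTable], [SampleTaxonMatrix] or [SpeciesLevelMatrix]
#' @return character vector of plant species labels
#' @export
setGeneric("plantSpecies", function(x) standardGeneric("plantSpecies"))

#' @rdname plantSpecies
#' @export
setMethod("plantSpecies", "SurveyTable", function(x) x@speciesList)

#' @rdname plantSpecies
#' @export
setMethod("plantSpecies", "SampleTaxonMatrix",
    function(x) as.character(colData(x)$plant_species))

#' @rdname plantSpecies
#' @export
setMethod("plantSpecies", "SpeciesLevelMatrix", function(x) rownames(x@values))

#' Fungal taxon labels
#' @param x a [SurveyTable], [SampleTaxonMatrix] or [SpeciesLevelMatrix]
#' @return character vector of taxon labels (never contains the
#'   uncolonized sentinel)
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @rdname taxa
#' @export
setMethod("taxa", "SurveyTable", function(x) x@taxonList)

#' @rdname taxa
#' @export
setMethod("taxa", "SampleTaxonMatrix", function(x) rownames(x))

#' @rdname taxa
#' @export
setMethod("taxa", "SpeciesLevelMatrix", function(x) colnames(x@values))

#' Abundance matrix in the spec'd samples x taxa orientation
#' @param x a [SampleTaxonMatrix] or [SpeciesLevelMatrix]
#' @return base matrix; samples (or plant species) as rows, taxa as columns
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname abundances
#' @export
setMethod("abundances", "SampleTaxonMatrix",
    function(x) t(assay(x, "abundance")))

#' @rdname abundances
#' @export
setMethod("abundances", "SpeciesLevelMatrix", function(x) x@values)

#' Per-species number of samples behind a species-level matrix
#' @param x a [SpeciesLevelMatrix]
#' @return named integer vector
#' @export
setGeneric("sampleCounts", function(x) standardGeneric("sampleCounts"))

#' @rdname sampleCounts
#' @export
setMethod("sampleCounts", "SpeciesLevelMatrix",
    function(x) stats::setNames(x@nSamples, rownames(x@values)))

setMethod("show", "SurveyTable", function(object) {
    rec <- object@records
    nNone <- sum(rec$taxon == NONE_LABEL)
    cat("SurveyTable:", nrow(rec), "segment records\n")
    cat(" ", length(object@speciesList), "plant species,",
        length(object@taxonList), "fungal taxa\n")
    cat("  colonized segments:", nrow(rec) - nNone,
        sprintf("(%.1f%%)\n", 100 * (nrow(rec) - nNone) / max(1, nrow(rec))))
})

setMethod("show", "SurveyConfig", function(object) {
    cat("SurveyConfig:", object@nSpecies, "species x", object@nIndividuals,
        "individuals x", length(object@tissues), "tissues x",
        object@nSegments, "segments\n")
    cat("  taxon pool:", length(object@taxonPool),
        "| mean colonization prob:",
        sprintf("%.3f", mean(object@colonizationProb)),
        "| seed:", object@seed, "\n")
    w <- range(object@preferenceWeight)
    cat("  preference weights in [", w[1], ",", w[2], "]\n")
})

setMethod("show", "SpeciesLevelMatrix", function(object) {
    cat("SpeciesLevelMatrix:", nrow(object@values), "plant species x",
        ncol(object@values), "fungal taxa\n")
    cat("  samples per species:", paste(object@nSamples, collapse = ", "), "\n")
})

setMethod("show", "PreferenceResult", function(object) {
    cat("PreferenceResult (", object@params$n_permutations,
        " permutations, seed ", object@params$seed, ")\n", sep = "")
    sig <- function(d) sum(!is.na(d$p_fdr) & d$p_fdr < 0.05)
    cat("  plant-axis d': ", nrow(object@plantDPrime), " species, ",
        sig(object@plantDPrime), " with P_FDR < 0.05\n", sep = "")
    cat("  fungus-axis d': ", nrow(object@taxonDPrime), " taxa, ",
        sig(object@taxonDPrime), " with P_FDR < 0.05\n", sep = "")
    cat("  pairwise 2DP: ", nrow(object@pairs), " pairs, ",
        sig(object@pairs), " with P_FDR < 0.05\n", sep = "")
})

setMethod("show", "CCAResult", function(object) {
    cat("CCAResult: rank", object@rank, "\n")
    ev <- object@eigenvalues
    cat("  constrained eigenvalues:",
        paste(sprintf("%.4f", ev[seq_len(min(5, length(ev)))]), collapse = " "),
        if (length(ev) > 5) "...\n" else "\n")
    cat(sprintf("  constrained / total inertia: %.4f / %.4f (%.1f%%)\n",
        sum(ev), object@totalInertia,
        100 * sum(ev) / max(object@totalInertia, .Machine$double.eps)))
})

setMethod("show", "PermanovaResult", function(object) {
    cat("PermANOVA (", object@distance, ", ",
        if (object@exact) "exact enumeration" else
            paste(object@nPermutations, "permutations"), ")\n", sep = "")
    print(format(object@terms, digits = 4), row.names = FALSE)
})

setMethod("show", "ComparisonResult", function(object) {
    cat(object@test, ": ", names(object@statistic), " = ",
        sprintf("%.4g", object@statistic), ", p = ",
        sprintf("%.4g", object@pValue), "\n", sep = "")
    if (length(object@letters)) {
        cat("  letters:",
            paste(names(object@letters), object@letters, sep = ":", collapse = " "),
            "\n")
    }
    if (length(object@note) && nzchar(object@note[1]))
        cat("  note:", object@note[1], "\n")
})

#' Eigenvalues of an ordination fit
#' @param x a [CCAResult]
#' @return numeric vector of constrained eigenvalues
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname eigenvalues
#' @export
setMethod("eigenvalues", "CCAResult", function(x) x@eigenvalues)

#' Fraction of total inertia captured by the constraints
#' @param x a [CCAResult]
#' @return scalar in `[0, 1]`
#' @export
setGeneric("constrainedFraction", function(x) standardGeneric("constrainedFraction"))

#' @rdname constrainedFraction
#' @export
setMethod("constrainedFraction", "CCAResult", function(x) {
    if (x@totalInertia <= 0) return(0)
    sum(x@eigenvalues) / x@totalInertia
})

#' Pairwise 2DP records of a preference analysis
#' @param x a [PreferenceResult]
#' @return DataFrame with one row per (plant species, fungal taxon) pair
#' @export
setGeneric("pairPreferences", function(x) standardGeneric("pairPreferences"))

#' @rdname pairPreferences
#' @export
setMethod("pairPreferences", "PreferenceResult", function(x) x@pairs)

#' Standardized d' records of a preference analysis
#' @param x a [PreferenceResult]
#' @param axis "plant" for per-species records, "taxon" for per-fungus
#' @return DataFrame of standardized d' records
#' @export
setGeneric("dPrimeRecords",
    function(x, axis = c("plant", "taxon")) standardGeneric("dPrimeRecords"))

#' @rdname dPrimeRecords
#' @export
setMethod("dPrimeRecords", "PreferenceResult", function(x, axis = c("plant", "taxon")) {
    axis <- match.arg(axis)
    if (axis == "plant") x@plantDPrime else x@taxonDPrime
})
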