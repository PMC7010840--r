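#' Build a SurveyTable from segment records
#'
#' Validates segment-level isolation records and derives the ordered species
#' and taxon lists. Labels are trimmed of surrounding whitespace at
#' construction; matching is otherwise exact and case-sensitive so that
#' distinct labels are never silently merged.
#'
#' @param records data.frame with columns `plant_species`, `individual_id`,
#'   `tissue`, `segment_index`, `taxon`; the taxon of an uncolonized segment
#'   is the literal `"none"`. Extra columns are preserved untouched.
#' @param speciesList,taxonList optional explicit label orders; defaults to
#'   order of first appearance. `taxonList` must exclude `"none"`.
#' @return a [SurveyTable]
#' @export
surveyTable <- function(records, speciesList = NULL, taxonList = NULL) {
    stopifnot(is.data.frame(records))
    records <- as.data.frame(records, stringsAsFactors = FALSE)
    miss <- setdiff(REQ_COLS, names(records))
    if (length(miss))
        stop("records are missing columns: ", paste(miss, collapse = ", "))
    for (cl in c("plant_species", "individual_id", "tissue", "taxon"))
        records[[cl]] <- trimws(as.character(records[[cl]]))
    records$segment_index <- as.integer(records$segment_index)
    if (is.null(speciesList)) speciesList <- unique(records$plant_species)
    if (is.null(taxonList))
        taxonList <- setdiff(unique(records$taxon), NONE_LABEL)
    new("SurveyTable", records = records,
        speciesList = as.character(speciesList),
        taxonList = as.character(taxonList))
}

#' Read an isolation survey from delimited text
#'
#' Expects a header naming the five record fields (`plant_species`,
#' `individual_id`, `tissue`, `segment_index`, `taxon`); unknown columns are
#' kept as opaque metadata. Duplicate segment keys and empty labels are
#' rejected with an informative error.
#'
#' @param path path to the survey file
#' @param sep field delimiter; `"\t"` (default) or `","`
#' @return a [SurveyTable]
#' @export
readSurvey <- function(path, sep = "\t") {
    if (!file.exists(path)) stop("survey file not found: ", path)
    rec <- tryCatch(
        utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
            colClasses = "character", check.names = FALSE,
            stringsAsFactors = FALSE, comment.char = "", fill = FALSE),
        error = function(e) stop("malformed survey file '", path, "': ",
            conditionMessage(e), call. = FALSE))
    miss <- setdiff(REQ_COLS, names(rec))
    if (length(miss))
        stop("survey file '", path, "' lacks required columns: ",
            paste(miss, collapse = ", "))
    si <- suppressWarnings(as.numeric(rec$segment_index))
    bad <- which(is.na(si) | si < 1 | si != round(si))
    if (length(bad))
        stop("survey file '", path, "': invalid segment_index at data line ",
            bad[1])
    rec$segment_index <- as.integer(si)
    surveyTable(rec)
}

#' Write a survey to delimited text
#'
#' @param survey a [SurveyTable]
#' @param path output path
#' @param sep field delimiter
#' @return `path`, invisibly
#' @export
writeSurvey <- function(survey, path, sep = "\t") {
    stopifnot(is(survey, "SurveyTable"))
    utils::write.table(records(survey), path, sep = sep, quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' Aggregate a survey into a sample x taxon matrix
#'
#' Each sample unit (an individual plant, or an individual x tissue
#' combination) becomes one sample; cell values count the segments of that
#' sample yielding each taxon (`mode = "count"`) or indicate presence
#' (`mode = "presence"`). Uncolonized segments contribute to no taxon.
#'
#' @param survey a [SurveyTable]
#' @param sampleUnit `"individual_x_tissue"` (default; tissue-resolved
#'   samples) or `"individual"` (whole plants)
#' @param mode `"count"` or `"presence"`
#' @return a [SampleTaxonMatrix]
#' @export
sampleTaxonMatrix <- function(survey,
                              sampleUnit = c("individual_x_tissue", "individual"),
                              mode = c("count", "presence")) {
    stopifnot(is(survey, "SurveyTable"))
    sampleUnit <- match.arg(sampleUnit)
    mode <- match.arg(mode)
    rec <- records(survey)
    if (!nrow(rec)) stop("survey has no records")
    taxaAll <- taxa(survey)
    if (sampleUnit == "individual_x_tissue") {
        sid <- paste(rec$plant_species, rec$individual_id, rec$tissue, sep = "|")
    } else {
        sid <- paste(rec$plant_species, rec$individual_id, sep = "|")
    }
    sampleIds <- unique(sid)
    counts <- matrix(0L, nrow = length(taxaAll), ncol = length(sampleIds),
        dimnames = list(taxaAll, sampleIds))
    hit <- rec$taxon != NONE_LABEL
    if (any(hit)) {
        tb <- table(factor(rec$taxon[hit], levels = taxaAll),
                    factor(sid[hit], levels = sampleIds))
        counts[] <- as.integer(tb)
    }
    if (mode == "presence") counts[] <- as.integer(counts > 0L)
    first <- !duplicated(sid)
    cd <- DataFrame(
        plant_species = rec$plant_species[first],
        individual_id = rec$individual_id[first],
        row.names = sampleIds)
    if (sampleUnit == "individual_x_tissue")
        cd$tissue <- rec$tissue[first]
    se <- SummarizedExperiment(assays = list(abundance = counts), colData = cd)
    metadata(se)$mode <- mode
    metadata(se)$sample_unit <- sampleUnit
    new("SampleTaxonMatrix", se)
}

#' Binarize a sample x taxon matrix
#'
#' @param x a [SampleTaxonMatrix]
#' @return `x` in presence mode
#' @export
binarize <- function(x) {
    stopifnot(is(x, "SampleTaxonMatrix"))
    if (identical(metadata(x)$mode, "presence")) return(x)
    a <- assay(x, "abundance")
    SummarizedExperiment::assay(x, "abundance") <- matrix(
        as.integer(a > 0L), nrow = nrow(a), dimnames = dimnames(a))
    metadata(x)$mode <- "presence"
    x
}

#' Aggregate samples into a species-level matrix
#'
#' Collapses a presence-mode sample x taxon matrix over plant species: cell
#' (i, j) is the number of samples of species i in which taxon j occurred.
#' A count-mode input is binarized first (with a message).
#'
#' @param x a [SampleTaxonMatrix]
#' @param speciesOrder optional ordering of plant species rows
#' @return a [SpeciesLevelMatrix]
#' @export
speciesLevelMatrix <- function(x, speciesOrder = NULL) {
    stopifnot(is(x, "SampleTaxonMatrix"))
    if (!identical(metadata(x)$mode, "presence")) {
        message("speciesLevelMatrix: binarizing count-mode matrix")
        x <- binarize(x)
    }
    sp <- plantSpecies(x)
    if (is.null(speciesOrder)) speciesOrder <- unique(sp)
    pres <- t(assay(x, "abundance"))          # samples x taxa
    agg <- rowsum(pres, group = factor(sp, levels = speciesOrder))
    agg <- matrix(as.integer(agg), nrow = nrow(agg), dimnames = dimnames(agg))
    ns <- as.integer(table(factor(sp, levels = speciesOrder)))
    new("SpeciesLevelMatrix", values = agg, nSamples = ns)
}

#' Export a matrix with leading label column
#'
#' Writes a [SampleTaxonMatrix] (samples as rows) or [SpeciesLevelMatrix]
#' (plant species as rows) as headered TSV, first column the row label.
#'
#' @param x matrix container to export
#' @param path output path
#' @param labelName header of the label column
#' @return `path`, invisibly
#' @export
writeMatrixTSV <- function(x, path, labelName = "sample") {
    m <- abundances(x)
    df <- data.frame(label = rownames(m), m, check.names = FALSE,
        stringsAsFactors = FALSE)
    names(df)[1] <- labelName
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
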