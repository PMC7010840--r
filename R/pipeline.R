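log_msg <- function(quiet, ...) if (!quiet) message("[endosurvey] ", ...)

config_to_survey_config <- function(sim, seed) {
    cp <- sim$colonization_prob
    if (!is.null(cp) && is.list(cp)) cp <- do.call(rbind, cp)
    args <- list(
        nSpecies = sim$n_species %||% 10L,
        nIndividuals = sim$n_individuals %||% 10L,
        tissues = unlist(sim$tissues) %||% c("stem", "root"),
        nSegments = sim$n_segments %||% 8L,
        colonizationProb = cp,
        seed = seed)
    if (!is.null(sim$taxon_pool)) args$taxonPool <- unlist(sim$taxon_pool)
    if (!is.null(sim$base_weight)) args$baseWeight <- unlist(sim$base_weight)
    cfg <- do.call(surveyConfig, args)
    for (pref in sim$preferences) {
        cfg <- plantPreference(cfg, pref$taxon, pref$species,
            tissue = pref$tissue, weight = pref$weight %||% 10)
    }
    cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

comparison_to_list <- function(cr) {
    list(test = cr@test, statistic = as.list(cr@statistic),
        parameter = as.list(cr@parameter), p_value = cr@pValue,
        letters = as.list(cr@letters), note = cr@note)
}

#' Run the survey analysis pipeline
#'
#' Orchestrates simulate (or load) -> metrics -> ordination -> preference
#' from a single configuration (a YAML file path or an equivalent nested
#' list), writing each stage's outputs as TSV/JSON under `out_dir` together
#' with a `manifest.json` recording the configuration snapshot, all seeds,
#' the package version, per-stage outputs and wall-clock times. Re-running
#' with the same configuration and seed reproduces the outputs.
#'
#' @param config YAML file path or list. Recognized top-level keys:
#'   `out_dir`, `seed`, `survey` (path to an existing survey TSV) or
#'   `simulate` (generator parameters), `stages` (subset of metrics,
#'   ordination, preference), and per-stage parameter blocks.
#' @param outDir overrides `config$out_dir`
#' @param seed overrides `config$seed`
#' @param quiet suppress progress messages
#' @return the manifest, invisibly
#' @export
runPipeline <- function(config, outDir = NULL, seed = NULL, quiet = FALSE) {
    if (is.character(config)) {
        if (!file.exists(config)) stop("config file not found: ", config)
        config <- yaml::read_yaml(config)
    }
    stopifnot(is.list(config))
    outDir <- outDir %||% config$out_dir %||% "."
    seed <- as.integer(seed %||% config$seed %||% 1L)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    stages <- unlist(config$stages) %||% c("metrics", "ordination", "preference")
    manifest <- list(seed = seed, stages = as.list(stages),
        package_version = as.character(utils::packageVersion("endosurvey")),
        config = config, outputs = list(), timing_s = list())
    tstage <- function(name, expr) {
        t0 <- proc.time()[["elapsed"]]
        v <- tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
        manifest$timing_s[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
        v
    }
    surveyPath <- file.path(outDir, "survey.tsv")
    if (!is.null(config$survey)) {
        log_msg(quiet, "loading survey from ", config$survey)
        survey <- tstage("load", readSurvey(config$survey))
        surveyPath <- config$survey
    } else {
        log_msg(quiet, "simulating survey (seed ", seed, ")")
        survey <- tstage("simulate", {
            cfg <- config_to_survey_config(config$simulate %||% list(), seed)
            s <- generateSurvey(cfg)
            writeSurvey(s, surveyPath)
            s
        })
        manifest$outputs$survey <- surveyPath
    }
    if ("metrics" %in% stages) {
        log_msg(quiet, "stage metrics -> ", outDir)
        tstage("metrics", {
            cr <- colonizationRate(survey)
            crPath <- file.path(outDir, "colonization_rate.tsv")
            utils::write.table(cr, crPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
            stm <- sampleTaxonMatrix(survey, mode = "count")
            rich <- taxonRichness(stm)
            richPath <- file.path(outDir, "richness.tsv")
            utils::write.table(rich, richPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
            ra <- relativeAbundance(stm, by = "tissue")
            raPath <- file.path(outDir, "relative_abundance.tsv")
            utils::write.table(ra, raPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
            cmp <- list(
                colonization_anova_species =
                    comparison_to_list(anovaOneway(cr$colonization_rate,
                        cr$plant_species)),
                colonization_anova_tissue =
                    comparison_to_list(anovaOneway(cr$colonization_rate,
                        cr$tissue)),
                colonization_tukey_species =
                    comparison_to_list(tukeyHsd(cr$colonization_rate,
                        cr$plant_species)),
                richness_kruskal_tissue =
                    comparison_to_list(kruskalWallis(rich$richness,
                        rich$tissue, posthoc = FALSE)))
            cmpPath <- file.path(outDir, "comparisons.json")
            jsonlite::write_json(cmp, cmpPath, auto_unbox = TRUE, digits = NA)
            manifest$outputs$metrics <- list(colonization_rate = crPath,
                richness = richPath, relative_abundance = raPath,
                comparisons = cmpPath)
        })
    }
    if ("ordination" %in% stages) {
        ocfg <- config$ordination %||% list()
        log_msg(quiet, "stage ordination -> ", outDir)
        tstage("ordination", {
            stm <- sampleTaxonMatrix(survey, mode = "count")
            facNames <- unlist(ocfg$factors) %||% c("tissue", "plant_species")
            fac <- as.data.frame(colData(stm))[, facNames, drop = FALSE]
            cca <- ccaOrdination(stm, fac)
            pmv <- permanova(stm, fac,
                distance = ocfg$distance %||% "bray_curtis",
                nPermutations = ocfg$permutations %||% 999L, seed = seed)
            ordPath <- file.path(outDir, "ordination.json")
            jsonlite::write_json(list(
                cca = list(eigenvalues = eigenvalues(cca),
                    total_inertia = cca@totalInertia,
                    constrained_fraction = constrainedFraction(cca)),
                permanova = pmv@terms,
                distance = pmv@distance, seed = seed),
                ordPath, auto_unbox = TRUE, digits = NA, dataframe = "columns")
            manifest$outputs$ordination <- ordPath
        })
    }
    if ("preference" %in% stages) {
        pcfg <- config$preference %||% list()
        log_msg(quiet, "stage preference -> ", outDir)
        tstage("preference", {
            pref <- preferenceAnalysis(survey,
                sampleUnit = pcfg$sample_unit %||% "individual_x_tissue",
                nPermutations = pcfg$permutations %||% 1000L,
                seed = seed, pMode = pcfg$p_mode %||% "normal")
            prefPath <- file.path(outDir, "preference.tsv")
            writePreference(pref, prefPath)
            manifest$outputs$preference <- prefPath
        })
    }
    manifestPath <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
        digits = NA, null = "null")
    log_msg(quiet, "manifest written to ", manifestPath)
    invisible(manifest)
}
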