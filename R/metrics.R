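#' Colonization rate per group
#'
#' The colonization rate is the number of tissue segments infected by fungi
#' (taxon other than `"none"`) divided by the number of segments incubated,
#' computed within each group of the grouping columns.
#'
#' @param survey a [SurveyTable]
#' @param by record columns defining the groups; default one row per
#'   (plant species, individual, tissue)
#' @return data.frame with the grouping columns, `n_incubated`, `n_infected`
#'   and `colonization_rate`
#' @export
colonizationRate <- function(survey,
        by = c("plant_species", "individual_id", "tissue")) {
    stopifnot(is(survey, "SurveyTable"))
    rec <- records(survey)
    if (!nrow(rec)) stop("survey has no records")
    bad <- setdiff(by, names(rec))
    if (length(bad)) stop("unknown grouping columns: ", paste(bad, collapse = ", "))
    g <- interaction(rec[by], drop = TRUE, lex.order = TRUE, sep = "\r")
    inf <- rec$taxon != NONE_LABEL
    nInc <- tapply(inf, g, length)
    nInf <- tapply(inf, g, sum)
    keys <- do.call(rbind, strsplit(names(nInc), "\r", fixed = TRUE))
    out <- data.frame(keys, stringsAsFactors = FALSE)
    names(out) <- by
    out$n_incubated <- as.integer(nInc)
    out$n_infected <- as.integer(nInf)
    out$colonization_rate <- as.numeric(nInf / nInc)
    rownames(out) <- NULL
    out
}

#' Per-sample fungal richness
#'
#' Richness is the number of distinct fungal taxa recovered from a sample.
#'
#' @param x a [SampleTaxonMatrix]
#' @return data.frame with sample metadata and a `richness` column
#' @export
taxonRichness <- function(x) {
    stopifnot(is(x, "SampleTaxonMatrix"))
    a <- assay(x, "abundance")
    out <- as.data.frame(colData(x))
    out$sample <- colnames(x)
    out$richness <- as.integer(colSums(a > 0))
    rownames(out) <- NULL
    out[, c("sample", setdiff(names(out), c("sample", "richness")), "richness")]
}

#' Relative abundance of taxa per group
#'
#' The relative abundance of a taxon is its number of isolates divided by
#' the total number of isolates of all taxa within the group. Groups with
#' zero isolates are dropped with a warning.
#'
#' @param x a [SampleTaxonMatrix] in count mode
#' @param by sample metadata columns defining the groups, or `NULL` for a
#'   single overall group
#' @return data.frame of (group columns, taxon, n_isolates, proportion);
#'   proportions sum to 1 within each group
#' @export
relativeAbundance <- function(x, by = NULL) {
    stopifnot(is(x, "SampleTaxonMatrix"))
    if (!identical(metadata(x)$mode, "count"))
        warning("relative abundance computed from presence indicators, not counts")
    counts <- t(assay(x, "abundance"))  # samples x taxa
    cd <- as.data.frame(colData(x))
    if (is.null(by)) {
        groups <- factor(rep("all", nrow(counts)))
        keyDf <- data.frame(group = "all", stringsAsFactors = FALSE)
    } else {
        bad <- setdiff(by, names(cd))
        if (length(bad)) stop("unknown grouping columns: ", paste(bad, collapse = ", "))
        groups <- interaction(cd[by], drop = TRUE, lex.order = TRUE, sep = "\r")
        keyDf <- data.frame(
            do.call(rbind, strsplit(levels(groups), "\r", fixed = TRUE)),
            stringsAsFactors = FALSE)
        names(keyDf) <- by
    }
    tot <- rowsum(counts, groups)
    out <- do.call(rbind, lapply(seq_len(nrow(tot)), function(i) {
        n <- sum(tot[i, ])
        if (n == 0) return(NULL)
        keyRow <- keyDf[i, , drop = FALSE]
        rownames(keyRow) <- NULL
        cbind(keyRow,
            data.frame(taxon = colnames(tot), n_isolates = as.integer(tot[i, ]),
                proportion = as.numeric(tot[i, ] / n), row.names = NULL,
                stringsAsFactors = FALSE))
    }))
    dropped <- rowSums(tot) == 0
    if (any(dropped))
        warning("groups without isolates omitted: ",
            paste(gsub("\r", "/", rownames(tot)[dropped]), collapse = ", "))
    rownames(out) <- NULL
    out
}

levene_p <- function(values, group) {
    # Brown-Forsythe: ANOVA on absolute deviations from group medians
    dev <- abs(values - stats::ave(values, group, FUN = stats::median))
    if (stats::var(dev) == 0) return(1)
    stats::anova(stats::lm(dev ~ group))$`Pr(>F)`[1]
}

#' One-way analysis of variance
#'
#' Classical one-way ANOVA of a survey metric over a grouping factor, with
#' optional square-root transformation of the response and reported
#' normality (Shapiro-Wilk on residuals) and homogeneity (Brown-Forsythe)
#' diagnostics. The function never switches tests on its own; the
#' diagnostics are reported so the caller can choose a nonparametric
#' alternative.
#'
#' @param values numeric response
#' @param group grouping factor (>= 2 levels, each with >= 2 observations)
#' @param sqrtTransform apply `sqrt(values)` before testing
#' @return a [ComparisonResult] with the F statistic, df and p-value
#' @export
anovaOneway <- function(values, group, sqrtTransform = FALSE) {
    group <- droplevels(as.factor(group))
    if (nlevels(group) < 2) stop("need at least two groups")
    if (any(table(group) < 2)) stop("each group needs at least two observations")
    if (sqrtTransform) {
        if (any(values < 0)) stop("square-root transform needs non-negative values")
        values <- sqrt(values)
    }
    if (stats::var(values) == 0) { # no variation at all: F defined as 0
        return(new("ComparisonResult", test = "one-way ANOVA",
            statistic = c(F = 0),
            parameter = c(df1 = nlevels(group) - 1,
                df2 = length(values) - nlevels(group)),
            pValue = 1, pairwise = data.frame(), letters = character(),
            note = "degenerate: all values identical"))
    }
    fit <- stats::lm(values ~ group)
    an <- stats::anova(fit)
    f <- an$`F value`[1]
    if (is.na(f)) { # zero residual and between variance
        f <- 0; p <- 1
    } else p <- an$`Pr(>F)`[1]
    sw <- tryCatch(stats::shapiro.test(stats::residuals(fit))$p.value,
        error = function(e) NA_real_)
    note <- sprintf("shapiro_p=%.4g; levene_p=%.4g%s", sw,
        levene_p(values, group), if (sqrtTransform) "; sqrt-transformed" else "")
    new("ComparisonResult", test = "one-way ANOVA",
        statistic = c(F = f),
        parameter = c(df1 = an$Df[1], df2 = an$Df[2]),
        pValue = p, pairwise = data.frame(), letters = character(),
        note = note)
}

#' Tukey honest significant difference post hoc test
#'
#' All pairwise comparisons after a one-way ANOVA, with studentized-range
#' adjusted p-values and a compact letter display (groups that share no
#' letter differ at the given alpha). Ties in the display are broken
#' alphabetically by group label.
#'
#' @param values numeric response
#' @param group grouping factor
#' @param alpha significance level of the letter display
#' @param sqrtTransform apply `sqrt(values)` first
#' @return a [ComparisonResult]; `@pairwise` has columns group_a, group_b,
#'   difference, adjusted_p; `@letters` is the letter display
#' @export
tukeyHsd <- function(values, group, alpha = 0.05, sqrtTransform = FALSE) {
    group <- droplevels(as.factor(group))
    if (sqrtTransform) values <- sqrt(values)
    if (stats::var(values) == 0) {
        lv <- levels(group)
        cmb <- utils::combn(lv, 2)
        return(new("ComparisonResult", test = "Tukey HSD",
            statistic = c(F = 0),
            parameter = c(df1 = length(lv) - 1,
                df2 = length(values) - length(lv)),
            pValue = 1,
            pairwise = data.frame(group_a = cmb[2, ], group_b = cmb[1, ],
                difference = 0, adjusted_p = 1, stringsAsFactors = FALSE),
            letters = stats::setNames(rep("a", length(lv)), lv),
            note = "degenerate: all values identical"))
    }
    fit <- stats::aov(values ~ group)
    tk <- stats::TukeyHSD(fit)$group
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    pw <- data.frame(
        group_a = vapply(nm, `[`, "", 1L),
        group_b = vapply(nm, `[`, "", 2L),
        difference = tk[, "diff"],
        adjusted_p = tk[, "p adj"],
        row.names = NULL, stringsAsFactors = FALSE)
    pw$adjusted_p[is.nan(pw$adjusted_p)] <- 1 # all-identical degenerate case
    means <- tapply(values, group, mean)
    letters <- compactLetters(levels(group),
        pw[, c("group_a", "group_b")], pw$adjusted_p < alpha, means)
    an <- stats::anova(fit)
    f <- an$`F value`[1]; p <- an$`Pr(>F)`[1]
    if (is.na(f)) { f <- 0; p <- 1 }
    new("ComparisonResult", test = "Tukey HSD",
        statistic = c(F = f),
        parameter = c(df1 = an$Df[1], df2 = an$Df[2]),
        pValue = p, pairwise = pw, letters = letters, note = "")
}

#' Kruskal-Wallis rank test with Dunn follow-up
#'
#' Tie-corrected Kruskal-Wallis H with chi-square p-value, followed (when
#' `posthoc`) by Dunn's pairwise z comparisons with Benjamini-Hochberg
#' adjustment and a compact letter display.
#'
#' @param values numeric response
#' @param group grouping factor
#' @param posthoc run Dunn's pairwise comparisons
#' @param alpha significance level of the letter display
#' @return a [ComparisonResult] with `statistic` H and chi-square df
#' @export
kruskalWallis <- function(values, group, posthoc = TRUE, alpha = 0.05) {
    group <- droplevels(as.factor(group))
    if (nlevels(group) < 2) stop("need at least two groups")
    if (stats::var(values) == 0) { # all observations tied: no rank variation
        return(new("ComparisonResult", test = "Kruskal-Wallis",
            statistic = c(H = 0),
            parameter = c(df = nlevels(group) - 1),
            pValue = 1, pairwise = data.frame(), letters = character(),
            note = "degenerate: all values identical"))
    }
    kt <- stats::kruskal.test(values, group)
    pw <- data.frame(); letters <- character()
    if (posthoc && nlevels(group) > 2) {
        r <- rank(values)
        N <- length(values)
        tiesTab <- table(values)
        Tcorr <- sum(tiesTab^3 - tiesTab)
        sigma2 <- N * (N + 1) / 12 - Tcorr / (12 * (N - 1))
        rbar <- tapply(r, group, mean)
        n <- tapply(r, group, length)
        cmb <- utils::combn(levels(group), 2)
        z <- apply(cmb, 2, function(ab) {
            (rbar[ab[1]] - rbar[ab[2]]) /
                sqrt(sigma2 * (1 / n[ab[1]] + 1 / n[ab[2]]))
        })
        praw <- 2 * stats::pnorm(-abs(z))
        padj <- stats::p.adjust(praw, "BH")
        pw <- data.frame(group_a = cmb[1, ], group_b = cmb[2, ],
            z = as.numeric(z), p = praw, adjusted_p = padj,
            stringsAsFactors = FALSE)
        letters <- compactLetters(levels(group),
            pw[, c("group_a", "group_b")], pw$adjusted_p < alpha, rbar)
    }
    new("ComparisonResult", test = "Kruskal-Wallis",
        statistic = c(H = unname(kt$statistic)),
        parameter = c(df = unname(kt$parameter)),
        pValue = kt$p.value, pairwise = pw, letters = letters, note = "")
}

#' Welch two-sample t test
#'
#' @param valuesA,valuesB numeric vectors for the two groups (e.g. the same
#'   metric in stems vs roots of one plant species)
#' @return a [ComparisonResult] with the Welch t statistic,
#'   Welch-Satterthwaite df and two-sided p-value
#' @export
welchT <- function(valuesA, valuesB) {
    if (stats::var(valuesA) + stats::var(valuesB) == 0 &&
        mean(valuesA) == mean(valuesB)) {
        return(new("ComparisonResult", test = "Welch t",
            statistic = c(t = 0), parameter = c(df = NA_real_), pValue = 1,
            pairwise = data.frame(), letters = character(),
            note = "degenerate: both groups constant and equal"))
    }
    tt <- stats::t.test(valuesA, valuesB)
    new("ComparisonResult", test = "Welch t",
        statistic = c(t = unname(tt$statistic)),
        parameter = c(df = unname(tt$parameter)),
        pValue = tt$p.value, pairwise = data.frame(), letters = character(),
        note = "")
}

#' Compact letter display from pairwise significance
#'
#' Insert-and-absorb algorithm: starts from one letter covering all groups,
#' splits any letter whose member pair is significantly different, drops
#' letters that are subsets of others, and labels the sets `a`, `b`, ... in
#' descending order of group mean (alphabetically among equal means).
#'
#' @param groups group labels
#' @param pairs two-column data.frame of compared pairs
#' @param significant logical, one entry per pair
#' @param means named group means (display ordering only)
#' @return named character vector of letter strings
#' @export
compactLetters <- function(groups, pairs, significant, means = NULL) {
    sets <- list(groups)
    for (k in which(significant)) {
        a <- pairs[k, 1]; b <- pairs[k, 2]
        i <- 1
        while (i <= length(sets)) {
            s <- sets[[i]]
            if (a %in% s && b %in% s) {
                sets[[i]] <- setdiff(s, a)
                sets[[length(sets) + 1]] <- setdiff(s, b)
            }
            i <- i + 1
        }
        # absorb: drop sets contained in another
        keep <- rep(TRUE, length(sets))
        for (i in seq_along(sets)) {
            for (j in seq_along(sets)) {
                if (i != j && keep[j] &&
                    all(sets[[i]] %in% sets[[j]]) &&
                    (length(sets[[i]]) < length(sets[[j]]) || i > j)) {
                    keep[i] <- FALSE
                    break
                }
            }
        }
        sets <- sets[keep]
    }
    if (is.null(means)) means <- stats::setNames(rep(0, length(groups)), groups)
    ord <- order(-means[vapply(sets, function(s)
        s[which.max(means[s])], "")],
        vapply(sets, function(s) sort(s)[1], ""))
    sets <- sets[ord]
    out <- stats::setNames(rep("", length(groups)), groups)
    for (i in seq_along(sets))
        for (g in sets[[i]]) out[g] <- paste0(out[g], letters[i])
    out[!nzchar(out)] <- "?" # group significantly different from itself: impossible
    vapply(out, function(s) paste(sort(strsplit(s, "")[[1]]), collapse = ""), "")
}
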