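# Independent oracles and small fixture builders shared across tests.
# Everything here is deliberately naive (enumeration, double loops) and
# written without reference to the package internals it checks.

# all permutations of 1..n as an n! x n matrix
perms_of <- function(n) {
    if (n == 1) return(matrix(1L, 1, 1))
    sub <- perms_of(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) {
        rest <- seq_len(n)[-k]
        cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
    }))
}

# all compositions of total A into k non-negative parts (rows)
compositions_of <- function(A, k) {
    if (k == 1) return(matrix(A, 1, 1))
    do.call(rbind, lapply(0:A, function(b)
        cbind(b, compositions_of(A - b, k - 1L))))
}

# brute-force d' per row: KL against observed marginals; d_min by full
# enumeration of integer reallocations of the row total (column totals
# follow the allocation); d_max = ln(m / A_i)
brute_dprime <- function(M) {
    M <- as.matrix(M)
    m <- sum(M)
    colTot <- colSums(M)
    t(apply(M, 1, function(a) {
        A <- sum(a)
        if (A == 0) return(c(d_raw = NA, d_min = NA, d_max = NA, d_prime = NA))
        p <- a / A
        q <- colTot / m
        draw <- sum(ifelse(p > 0, p * log(p / q), 0))
        cExcl <- colTot - a
        comps <- compositions_of(A, ncol(M))
        P <- comps / A
        Cm <- matrix(cExcl, nrow(comps), ncol(M), byrow = TRUE)
        terms <- ifelse(comps > 0,
            P * log(P * m / (Cm + comps)), 0)
        dAll <- rowSums(terms)
        dmin <- min(dAll)
        dmax <- log(m / A)
        dp <- if (ncol(M) < 2 || dmax - dmin <= 1e-12) NA else
            (draw - dmin) / (dmax - dmin)
        c(d_raw = draw, d_min = dmin, d_max = dmax, d_prime = dp)
    }))
}

# exact one-factor PermANOVA pseudo-F via the classic group-sum identity:
# SS_total = sum_{i<j} d2 / n, SS_within = sum_g sum_{i<j in g} d2 / n_g
brute_pseudo_f <- function(D2, groups) {
    n <- nrow(D2)
    g <- as.factor(groups)
    ssT <- sum(D2[upper.tri(D2)]) / n
    ssW <- 0
    for (lv in levels(g)) {
        idx <- which(g == lv)
        ssW <- ssW + sum(D2[idx, idx][upper.tri(D2[idx, idx])]) / length(idx)
    }
    ssB <- ssT - ssW
    dfB <- nlevels(g) - 1L
    dfW <- n - nlevels(g)
    (ssB / dfB) / (ssW / dfW)
}

# tiny survey data.frame: one record per entry of `taxa` (a named list
# species -> list(individual -> list(tissue -> character vector of taxa)))
toy_records <- function(...) {
    entries <- list(...)
    do.call(rbind, lapply(entries, function(e)
        data.frame(plant_species = e[[1]], individual_id = e[[2]],
            tissue = e[[3]], segment_index = as.integer(e[[4]]),
            taxon = e[[5]], stringsAsFactors = FALSE)))
}

# presence-mode SampleTaxonMatrix built directly from a samples x taxa 0/1
# matrix and a species label vector (one individual per sample, stem tissue)
presence_stm <- function(pres, species) {
    pres <- as.matrix(pres)
    if (is.null(colnames(pres)))
        colnames(pres) <- paste0("t", seq_len(ncol(pres)))
    recs <- do.call(rbind, lapply(seq_len(nrow(pres)), function(i) {
        tx <- colnames(pres)[pres[i, ] > 0]
        if (!length(tx)) tx <- "none"
        data.frame(plant_species = species[i],
            individual_id = sprintf("i%02d", i), tissue = "stem",
            segment_index = seq_along(tx), taxon = tx,
            stringsAsFactors = FALSE)
    }))
    sv <- surveyTable(recs, taxonList = colnames(pres))
    binarize(sampleTaxonMatrix(sv, sampleUnit = "individual", mode = "count"))
}
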