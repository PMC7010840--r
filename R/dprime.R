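#' Kullback-Leibler interaction specialization index d'
#'
#' For each row of a plant x fungus interaction matrix (or each column, via
#' `axis = "taxon"`), computes the raw specialization
#' `d = sum_j p'_j * ln(p'_j / q_j)` of the row's interaction frequencies
#' `p'_j` against overall partner availability `q_j` (column totals over the
#' grand total), and the normalized `d' = (d - d_min) / (d_max - d_min)` in
#' `[0, 1]`. The theoretical maximum is `d_max = ln(m / A_i)` (`m` grand
#' total, `A_i` row total); `d_min` is the exact discrete minimum over
#' integer reallocations of the row total, found by a greedy unit-filling
#' procedure (each column's objective is convex in its allocation, so the
#' greedy increment is optimal).
#'
#' @param x a [SpeciesLevelMatrix] or a non-negative integer matrix
#' @param axis `"plant"` scores rows (plant species), `"taxon"` scores
#'   columns (fungal taxa)
#' @return data.frame with columns entity, d_raw, d_min, d_max, d_prime,
#'   flag. Rows with zero total are flagged `"empty"`; rows where
#'   `d_max <= d_min` (e.g. a single-column matrix) are flagged
#'   `"undefined"` with `d_prime = NA`.
#' @export
dPrime <- function(x, axis = c("plant", "taxon")) {
    axis <- match.arg(axis)
    M <- if (is(x, "SpeciesLevelMatrix")) abundances(x) else as.matrix(x)
    if (axis == "taxon") M <- t(M)
    if (is.null(rownames(M))) rownames(M) <- paste0("row", seq_len(nrow(M)))
    res <- cpp_dfun_rows(M)
    flag <- rep("ok", nrow(M))
    flag[rowSums(M) == 0] <- "empty"
    flag[flag == "ok" & is.na(res[, "d_prime"])] <- "undefined"
    data.frame(entity = rownames(M),
        d_raw = res[, "d_raw"], d_min = res[, "d_min"],
        d_max = res[, "d_max"], d_prime = res[, "d_prime"],
        flag = flag, row.names = NULL, stringsAsFactors = FALSE)
}
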