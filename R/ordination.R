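#' Canonical correspondence analysis
#'
#' Constrained ordination of a sample x taxon abundance matrix on a table of
#' explanatory factors, computed from first principles: the count matrix is
#' chi-square standardized (`(P - r c') / sqrt(r c')` with `P` the relative
#' frequency matrix and `r`, `c` its marginals), the standardized matrix is
#' projected, under row weights `r`, onto the dummy-coded constraint design,
#' and the projection is decomposed by singular value decomposition. The
#' constrained eigenvalues are the squared singular values; their sum over
#' the total inertia is the fraction of community variation the constraints
#' explain.
#'
#' @param x a [SampleTaxonMatrix] or a samples x taxa count matrix
#' @param constraints data.frame of explanatory factors, one row per sample
#' @return a [CCAResult]. Site scores are linear-combination scores,
#'   orthonormal under the row-weight inner product; `siteScoresWA` are
#'   weighted averages of the species scores.
#' @export
ccaOrdination <- function(x, constraints) {
    Y <- if (is(x, "SampleTaxonMatrix")) abundances(x) else as.matrix(x)
    if (sum(Y) <= 0) stop("all-zero abundance matrix")
    constraints <- as.data.frame(constraints)
    if (nrow(constraints) != nrow(Y))
        stop("constraints must have one row per sample")
    keepR <- rowSums(Y) > 0; keepC <- colSums(Y) > 0
    if (!all(keepR) || !all(keepC)) {
        warning(sprintf("dropping %d empty sample(s) and %d unseen taxa",
            sum(!keepR), sum(!keepC)))
        Y <- Y[keepR, keepC, drop = FALSE]
        constraints <- constraints[keepR, , drop = FALSE]
    }
    if (nrow(Y) < 2) stop("need at least two non-empty samples")
    constraints[] <- lapply(constraints, function(v)
        if (is.numeric(v)) v else droplevels(as.factor(v)))
    tot <- sum(Y)
    P <- Y / tot
    r <- rowSums(P); cc <- colSums(P)
    Q <- (P - outer(r, cc)) / sqrt(outer(r, cc))
    totalInertia <- sum(Q^2)
    # single-level factors carry no information; drop them so the dummy
    # coding is well defined (a constant constraint then has rank 0)
    informative <- vapply(constraints, function(v)
        is.numeric(v) || nlevels(v) >= 2L, TRUE)
    constraints <- constraints[, informative, drop = FALSE]
    X <- if (ncol(constraints))
        stats::model.matrix(~ ., data = constraints)[, -1, drop = FALSE]
    else matrix(0, nrow(Y), 0)
    Xc <- sweep(X, 2, colSums(r * X))      # weighted column centering
    Xw <- Xc * sqrt(r)
    qrX <- qr(Xw)
    rk <- qrX$rank
    if (rk < ncol(Xw))
        warning("rank-deficient constraints: rank ", rk, " < ", ncol(Xw))
    if (rk == 0) {
        return(new("CCAResult", eigenvalues = numeric(0),
            totalInertia = totalInertia,
            siteScores = matrix(0, nrow(Y), 0, dimnames = list(rownames(Y), NULL)),
            siteScoresWA = matrix(0, nrow(Y), 0, dimnames = list(rownames(Y), NULL)),
            speciesScores = matrix(0, ncol(Y), 0, dimnames = list(colnames(Y), NULL)),
            rowWeights = r, rank = 0L))
    }
    Qfit <- qr.fitted(qrX, Q)
    sv <- svd(Qfit)
    tol <- max(dim(Q)) * max(sv$d, 0) * .Machine$double.eps * 100
    pos <- which(sv$d > max(tol, 1e-12))
    nax <- length(pos)
    ev <- sv$d[pos]^2
    ax <- paste0("CCA", seq_len(nax))
    U <- sv$u[, pos, drop = FALSE]
    V <- sv$v[, pos, drop = FALSE]
    site <- U / sqrt(r)
    spec <- V / sqrt(cc)
    siteWA <- (P / r) %*% spec
    dimnames(site) <- list(rownames(Y), ax)
    dimnames(siteWA) <- list(rownames(Y), ax)
    dimnames(spec) <- list(colnames(Y), ax)
    new("CCAResult", eigenvalues = ev, totalInertia = totalInertia,
        siteScores = site, siteScoresWA = siteWA, speciesScores = spec,
        rowWeights = r, rank = as.integer(min(rk, nax)))
}

all_permutations <- function(n) {
    # n! x n matrix of index permutations, lexicographic
    if (n == 1) return(matrix(1L, 1, 1))
    sub <- all_permutations(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) {
        rest <- seq_len(n)[-k]
        cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
    }))
}

#' Distance-based permutational multivariate ANOVA
#'
#' Partitions a Gower-centered distance matrix by sequential (Type I) sums
#' of squares over the given factors, forms the pseudo-F statistic of each
#' term against the residual, and assesses it by permuting sample labels:
#' `p = (1 + #[F_perm >= F_obs]) / (1 + n_permutations)`. With
#' `exact = TRUE` all `n!` row permutations are enumerated instead and the
#' p-value is the exact fraction of permutations reaching `F_obs`.
#'
#' @param x a [SampleTaxonMatrix] or samples x taxa matrix
#' @param factors data.frame of factors, one row per sample; terms are
#'   fitted sequentially in column order
#' @param distance `"bray_curtis"` (on counts) or `"jaccard"`
#'   (presence/absence)
#' @param nPermutations number of random permutations (ignored when exact)
#' @param seed RNG seed for the permutations
#' @param exact enumerate all permutations (samples must be few; n <= 9)
#' @return a [PermanovaResult]
#' @export
permanova <- function(x, factors, distance = c("bray_curtis", "jaccard"),
                      nPermutations = 999L, seed = 1L, exact = FALSE) {
    distance <- match.arg(distance)
    Y <- if (is(x, "SampleTaxonMatrix")) abundances(x) else as.matrix(x)
    factors <- as.data.frame(factors)
    if (nrow(factors) != nrow(Y))
        stop("factors must have one row per sample")
    keepR <- rowSums(Y) > 0
    if (!all(keepR)) {
        warning(sprintf(
            "dropping %d sample(s) without isolates (distance undefined)",
            sum(!keepR)))
        Y <- Y[keepR, , drop = FALSE]
        factors <- factors[keepR, , drop = FALSE]
    }
    if (nrow(Y) < 3) stop("need at least three non-empty samples")
    factors[] <- lapply(factors, function(v)
        if (is.numeric(v)) v else droplevels(as.factor(v)))
    for (nm in names(factors))
        if (is.factor(factors[[nm]]) && nlevels(factors[[nm]]) < 2)
            stop("factor '", nm, "' has fewer than two levels")
    D <- as.matrix(switch(distance,
        bray_curtis = vegan::vegdist(Y, method = "bray"),
        jaccard = vegan::vegdist(Y, method = "jaccard", binary = TRUE)))
    n <- nrow(D)
    Cm <- diag(n) - matrix(1 / n, n, n)
    G <- Cm %*% (-0.5 * D^2) %*% Cm
    ssTotal <- sum(diag(G))
    terms <- names(factors)
    hats <- vector("list", length(terms) + 1L)
    hats[[1]] <- matrix(1 / n, n, n)
    dfs <- integer(length(terms))
    for (k in seq_along(terms)) {
        fml <- stats::as.formula(paste("~", paste(terms[seq_len(k)], collapse = "+")))
        Xk <- stats::model.matrix(fml, data = factors)
        qk <- qr(Xk)
        Hk <- tcrossprod(qr.Q(qk)[, seq_len(qk$rank), drop = FALSE])
        dfs[k] <- qk$rank - sum(dfs) - 1L
        hats[[k + 1]] <- Hk
    }
    Hdiff <- lapply(seq_along(terms), function(k) hats[[k + 1]] - hats[[k]])
    Hres <- diag(n) - hats[[length(hats)]]
    dfRes <- n - 1L - sum(dfs)
    if (dfRes < 1) stop("no residual degrees of freedom")
    ssFun <- function(Gm) {
        ssT <- vapply(Hdiff, function(H) sum(H * Gm), 0)
        ssR <- sum(Hres * Gm)
        f <- (ssT / dfs) / (ssR / dfRes)
        list(ss = ssT, ssRes = ssR, f = f)
    }
    obs <- ssFun(G)
    eps <- 1e-12
    fObs <- obs$f
    fObs[!is.finite(fObs)] <- 0   # degenerate: zero residual variation
    if (exact) {
        if (n > 9) stop("exact enumeration limited to 9 samples")
        perms <- all_permutations(n)
        ge <- numeric(length(terms))
        for (i in seq_len(nrow(perms))) {
            fp <- ssFun(G[perms[i, ], perms[i, ]])$f
            fp[!is.finite(fp)] <- 0
            ge <- ge + (fp >= fObs - eps)
        }
        p <- ge / nrow(perms)
        nP <- 0L
    } else {
        nP <- as.integer(nPermutations)
        if (nP < 1) stop("nPermutations must be >= 1")
        ge <- numeric(length(terms))
        withr::with_seed(as.integer(seed), {
            for (i in seq_len(nP)) {
                pr <- sample.int(n)
                fp <- ssFun(G[pr, pr])$f
                fp[!is.finite(fp)] <- 0
                ge <- ge + (fp >= fObs - eps)
            }
        })
        p <- (1 + ge) / (1 + nP)
    }
    if (ssTotal <= 1e-12) {
        warning("degenerate distance matrix: no multivariate variation; R2 set to 0")
        r2 <- c(rep(0, length(terms) + 1L), 1)
    } else {
        r2 <- c(obs$ss, obs$ssRes, ssTotal) / ssTotal
    }
    tab <- data.frame(
        term = c(terms, "residual", "total"),
        df = c(dfs, dfRes, n - 1L),
        sum_of_squares = c(obs$ss, obs$ssRes, ssTotal),
        r_squared = r2,
        pseudo_f = c(fObs, NA, NA),
        p_value = c(p, NA, NA),
        stringsAsFactors = FALSE)
    new("PermanovaResult", terms = tab, nPermutations = nP,
        exact = isTRUE(exact), distance = distance, seed = as.integer(seed))
}
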