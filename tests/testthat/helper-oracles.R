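# Independent brute-force oracles used to freeze expected values.

# Benjamini-Hochberg step-up by direct definition: q_i = min_{j >= i} p_(j) n / j
bhOracle <- function(p) {
    n <- length(p)
    o <- order(p)
    q_sorted <- pmin(rev(cummin(rev(p[o] * n / seq_len(n)))), 1)
    q <- numeric(n)
    q[o] <- q_sorted
    q
}

# Two-sided Fisher exact p by hypergeometric tail enumeration on the table
# [[a, b], [c, d]] (rows: significant yes/no; cols: predicted yes/no).
fisherOracle <- function(a, b, c, d) {
    m <- a + c           # predicted
    n <- b + d           # not predicted
    k <- a + b           # significant
    x <- max(0, k - n):min(k, m)
    probs <- dhyper(x, m, n, k)
    p_obs <- dhyper(a, m, n, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact null distribution of PC-score numerators by exhaustive enumeration of
# all equally likely per-column assignments (positions x value orderings).
# effects: small miRNA x protein matrix. Returns a list with `numerators`
# (matrix: enumeration cases x miRNAs) and `prob` (case probabilities).
enumNullOracle <- function(effects) {
    M <- nrow(effects)
    col_cases <- lapply(seq_len(ncol(effects)), function(j) {
        v <- effects[effects[, j] != 0, j]
        k <- length(v)
        if (k == 0L)
            return(list(list(rows = integer(), vals = numeric())))
        pos <- utils::combn(M, k, simplify = FALSE)
        perms <- unique(allPerms(v))
        out <- list()
        for (p in pos) for (vv in perms)
            out[[length(out) + 1L]] <- list(rows = p, vals = vv)
        out
    })
    idx <- do.call(expand.grid, lapply(col_cases, seq_along))
    numerators <- matrix(0, nrow(idx), M)
    for (r in seq_len(nrow(idx))) {
        for (j in seq_along(col_cases)) {
            cs <- col_cases[[j]][[idx[r, j]]]
            numerators[r, cs$rows] <- numerators[r, cs$rows] + cs$vals
        }
    }
    list(numerators = numerators, prob = rep(1 / nrow(idx), nrow(idx)))
}

allPerms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
        for (rest in allPerms(v[-i]))
            out[[length(out) + 1L]] <- c(v[i], rest)
    out
}

# Hand-buildable EffectTable from log2fc and qvalue matrices
# (proteins x miRNAs).
makeEffectTable <- function(lfc, qv, missing = NULL) {
    if (is.null(missing)) missing <- is.na(lfc)
    new("EffectTable", SummarizedExperiment::SummarizedExperiment(
        assays = S4Vectors::SimpleList(
            log2fc = lfc, pvalue = qv, qvalue = qv,
            nobs = matrix(6L, nrow(lfc), ncol(lfc), dimnames = dimnames(lfc)),
            missing = missing)))
}

makeAnnotation <- function(...) {
    df <- data.frame(...)
    PathwayAnnotation(df)
}

# Minimal spot-level screen: one protein row per antibody, signals given as a
# named list condition -> per-replicate signal vectors (one spot each).
makeTinyScreen <- function(signals, blocks = NULL, total_protein = 1,
                           normalized = FALSE) {
    recs <- list()
    for (cond in names(signals)) {
        mat <- signals[[cond]]   # antibodies x replicates
        for (r in seq_len(ncol(mat))) {
            recs[[length(recs) + 1L]] <- data.frame(
                sample_id = paste0(cond, ".r", r),
                condition = cond, replicate = r, spot = 1L,
                block = if (is.null(blocks)) "B1" else blocks[[cond]][r],
                round = "R1",
                antibody_id = rownames(mat),
                signal = mat[, r],
                total_protein = total_protein,
                is_control = cond %in% c("ctrl1", "ctrl2"),
                control_kind = if (cond %in% c("ctrl1", "ctrl2")) cond
                               else "none")
        }
    }
    ScreenExperiment(do.call(rbind, recs), normalized = normalized)
}

# 2 miRNAs x 4 proteins toy: every role x direction combination plus a
# non-significant and a missing cell, with the expected signed pathway
# effects applied by hand.
toyNetworkFixture <- function() {
    prots <- c("ACT1", "ACT2", "REP1", "REP2")
    mirs <- c("m1", "m2")
    lfc <- matrix(c(-0.8, 0.5, -0.6, 0.7,     # m1 on ACT1 ACT2 REP1 REP2
                    -0.4, NA, 0.3, -0.2),     # m2
                  nrow = 4, dimnames = list(prots, mirs))
    qv <- matrix(c(1e-4, 1e-4, 1e-4, 1e-4,
                   0.01, NA, 1e-4, 1e-4),
                 nrow = 4, dimnames = list(prots, mirs))
    ann <- makeAnnotation(protein = prots, pathway = "WNT",
                          role = c("activator", "activator",
                                   "repressor", "repressor"))
    # hand-applied rules: down(act) -> -1, up(act) -> +1,
    #                     down(rep) -> +1, up(rep) -> -1
    expected <- rbind(m1 = c(ACT1 = -1, ACT2 = 1, REP1 = 1, REP2 = -1),
                      m2 = c(ACT1 = 0, ACT2 = 0, REP1 = -1, REP2 = 1))
    list(et = makeEffectTable(lfc, qv), ann = ann, expected = expected)
}
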