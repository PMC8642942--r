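# Method-of-moments fit of the scaled F model s^2 ~ s0^2 * F(d, d0),
# used to set the empirical-Bayes prior for variance shrinkage.
# Returns list(d0, s0sq); d0 = Inf means full shrinkage to s0sq.
.fitVariancePrior <- function(s2, d) {
    s2 <- s2[is.finite(s2) & s2 > 0]
    if (length(s2) < 3L)
        return(list(d0 = Inf, s0sq = if (length(s2)) mean(s2) else NA_real_))
    m1 <- mean(s2)
    cv2 <- stats::var(s2) / m1^2
    d <- max(1, stats::median(d))
    # cv2 = 2 (d + d0 - 2) / (d (d0 - 4)) solved for d0
    denom <- cv2 * d - 2
    if (denom <= 0)
        return(list(d0 = Inf, s0sq = m1))
    d0 <- (4 * cv2 * d + 2 * d - 4) / denom
    if (!is.finite(d0) || d0 > 1e6) return(list(d0 = Inf, s0sq = m1))
    d0 <- max(d0, 1)
    s0sq <- if (d0 > 2) m1 * (d0 - 2) / d0 else m1
    list(d0 = d0, s0sq = s0sq)
}

# Collapse spot-level log2 signals to one value per biological sample.
.sampleLevelLog2 <- function(object) {
    sig <- assay(object, "signal")
    l2 <- log2(ifelse(!is.na(sig) & sig > 0, sig, NA))
    cd <- colData(object)
    key <- paste(cd$round, cd$condition, cd$replicate, sep = "\r")
    samples <- unique(key)
    agg <- vapply(samples, function(k) {
        rowMeans(l2[, key == k, drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(l2)))
    agg[!is.finite(agg)] <- NA_real_
    agg <- matrix(agg, nrow = nrow(l2),
                  dimnames = list(rownames(l2), samples))
    first <- !duplicated(key)
    list(log2 = agg,
         condition = cd$condition[first],
         round = cd$round[first],
         is_control = cd$is_control[first],
         control_kind = cd$control_kind[first])
}

#' Differential protein effects of each miRNA versus negative controls
#'
#' For every (miRNA, protein) pair, contrasts the log2 normalized signals of
#' the miRNA-transfected samples against the mimic negative-control samples
#' of the same transfection round (both control conditions pooled by
#' default), yielding a log2 fold change, a two-sided p-value and a
#' Benjamini-Hochberg q-value.
#'
#' Two tests are offered. \code{"moderated"} (default) uses an
#' empirical-Bayes moderated t: per round, each protein's residual variance
#' across all conditions is shrunk towards a pooled prior
#' \eqn{\tilde{s}^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)}, with \eqn{d_0} and
#' \eqn{s_0^2} estimated by method of moments from the per-protein variance
#' distribution; the t statistic then has \eqn{d_0 + d} degrees of freedom.
#' \code{"welch"} performs a per-pair unequal-variance Welch t with
#' Satterthwaite degrees of freedom. Pairs with fewer than two usable
#' observations on either side are flagged missing; pairs with zero standard
#' error are reported with p = 1.
#'
#' @param object a normalized \linkS4class{ScreenExperiment}.
#' @param alphaQ significance threshold recorded in the result's metadata
#'   (default 0.001); it does not affect the statistics.
#' @param method \code{"moderated"} (default) or \code{"welch"}.
#' @param controlPooling \code{"pooled"} (default; both negative-control
#'   kinds form one reference group) or \code{"per-control"} (each control
#'   kind is contrasted separately and the two log2FCs and p-values are
#'   averaged / combined by Stouffer's method).
#' @param bhScope \code{"global"} (default; one BH correction across all
#'   pairs in the dataset) or \code{"per-protein"}.
#' @param ... unused.
#' @return An \linkS4class{EffectTable} (proteins x miRNAs) with assays
#'   \code{log2fc}, \code{pvalue}, \code{qvalue}, \code{nobs},
#'   \code{missing}.
#' @examples
#' sim <- simulateScreen(simConfig(nMirnas = 8, nPlantedPerPathway = 1, seed = 1))
#' et <- differentialEffects(normalizeSignals(sim$signals))
#' @export
setMethod("differentialEffects", "ScreenExperiment", function(object,
        alphaQ = 0.001, method = c("moderated", "welch"),
        controlPooling = c("pooled", "per-control"),
        bhScope = c("global", "per-protein"), ...) {
    method <- match.arg(method)
    controlPooling <- match.arg(controlPooling)
    bhScope <- match.arg(bhScope)
    if (!isNormalized(object))
        stop("signals must be normalized first (see normalizeSignals)")
    if (length(unique(colData(object)$control_kind[colData(object)$is_control])) < 2L)
        stop("design error: fewer than two negative-control kinds present")
    sl <- .sampleLevelLog2(object)
    proteins <- rownames(sl$log2)
    mirnas <- sort(unique(sl$condition[!sl$is_control]))
    P <- length(proteins); M <- length(mirnas)
    lfc <- pv <- matrix(NA_real_, P, M, dimnames = list(proteins, mirnas))
    nobs <- matrix(0L, P, M, dimnames = list(proteins, mirnas))
    for (r in unique(sl$round)) {
        in_r <- sl$round == r
        x <- sl$log2[, in_r, drop = FALSE]
        cond <- sl$condition[in_r]
        isctl <- sl$is_control[in_r]
        kind <- sl$control_kind[in_r]
        mirs_r <- sort(unique(cond[!isctl]))
        if (!length(mirs_r)) next
        if (sum(isctl) < 4L)
            stop("design error: round ", r, " has fewer than 4 control samples")
        # per-protein residual variance across all conditions in the round
        grp <- factor(cond)
        gm <- t(apply(x, 1L, function(v) tapply(v, grp, mean, na.rm = TRUE)))
        fitted <- gm[, as.integer(grp), drop = FALSE]
        resid <- x - fitted
        d_p <- apply(x, 1L, function(v) {
            n_g <- tapply(!is.na(v), grp, sum)
            sum(pmax(n_g - 1L, 0L))
        })
        ss <- rowSums(resid^2, na.rm = TRUE)
        s2 <- ifelse(d_p > 0, ss / d_p, NA_real_)
        prior <- .fitVariancePrior(s2, d_p)
        s2_mod <- if (is.infinite(prior$d0)) rep(prior$s0sq, P) else
            (prior$d0 * prior$s0sq + d_p * s2) / (prior$d0 + d_p)
        df_mod <- if (is.infinite(prior$d0)) rep(1e6, P) else prior$d0 + d_p
        if (controlPooling == "pooled") {
            ctl_groups <- list(all = isctl)
        } else {
            kinds <- unique(kind[isctl])
            ctl_groups <- lapply(kinds, function(k) isctl & kind == k)
            names(ctl_groups) <- kinds
        }
        for (m in mirs_r) {
            jm <- cond == m & !isctl
            xm <- x[, jm, drop = FALSE]
            n1 <- rowSums(!is.na(xm))
            m1 <- rowMeans(xm, na.rm = TRUE)
            res <- lapply(ctl_groups, function(jc) {
                xc <- x[, jc, drop = FALSE]
                n0 <- rowSums(!is.na(xc))
                m0 <- rowMeans(xc, na.rm = TRUE)
                delta <- m1 - m0
                if (method == "moderated") {
                    se <- sqrt(s2_mod * (1 / n1 + 1 / n0))
                    tt <- delta / se
                    p <- 2 * stats::pt(-abs(tt), df = df_mod)
                } else {
                    v1 <- apply(xm, 1L, stats::var, na.rm = TRUE)
                    v0 <- apply(xc, 1L, stats::var, na.rm = TRUE)
                    se2 <- v1 / n1 + v0 / n0
                    tt <- delta / sqrt(se2)
                    df_w <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) +
                                     v0^2 / (n0^2 * (n0 - 1)))
                    p <- 2 * stats::pt(-abs(tt), df = df_w)
                }
                p[is.finite(delta) & !is.finite(p)] <- 1  # zero-variance pairs
                list(delta = delta, p = p, n0 = n0)
            })
            if (length(res) == 1L) {
                delta <- res[[1L]]$delta; p <- res[[1L]]$p; n0 <- res[[1L]]$n0
            } else {
                delta <- rowMeans(do.call(cbind, lapply(res, `[[`, "delta")))
                z <- do.call(cbind, lapply(res, function(e)
                    stats::qnorm(pmin(pmax(e$p / 2, 1e-300), 1 - 1e-16)) *
                        -sign(e$delta)))
                zc <- rowSums(z) / sqrt(ncol(z))
                p <- 2 * stats::pnorm(-abs(zc))
                n0 <- rowSums(do.call(cbind, lapply(res, `[[`, "n0")))
            }
            usable <- n1 >= 2L & n0 >= 2L & is.finite(delta)
            lfc[usable, m] <- delta[usable]
            pv[usable, m] <- p[usable]
            nobs[, m] <- as.integer(n1 + n0)
        }
    }
    missing <- is.na(lfc)
    qv <- matrix(NA_real_, P, M, dimnames = dimnames(pv))
    if (bhScope == "global") {
        qv[!missing] <- stats::p.adjust(pv[!missing], method = "BH")
    } else {
        for (i in seq_len(P)) {
            ok <- !missing[i, ]
            qv[i, ok] <- stats::p.adjust(pv[i, ok], method = "BH")
        }
    }
    et <- new("EffectTable", SummarizedExperiment(
        assays = SimpleList(log2fc = lfc, pvalue = pv, qvalue = qv,
                            nobs = nobs, missing = missing)))
    metadata(et) <- list(alphaQ = alphaQ, method = method,
                         controlPooling = controlPooling, bhScope = bhScope)
    validObject(et)
    et
})
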