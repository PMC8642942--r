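test_that("sign rules match the hand-enumerated rule table over all cells", {
    fx <- toyNetworkFixture()
    net <- buildNetworkEffects(fx$et, fx$ann, alphaQ = 0.001)[["WNT"]]
    expect_equal(effectsMatrix(net), fx$expected[rownames(effectsMatrix(net)),
                                                 colnames(effectsMatrix(net))])
    # m2/ACT1 is the threshold case (q = 0.01 > 0.001): zero effect
    expect_equal(effectsMatrix(net)["m2", "ACT1"], 0)
    # m2/ACT2 is missing: unmeasured, and excluded from the denominator
    expect_false(measuredMatrix(net)["m2", "ACT2"])
    expect_equal(unname(nMeasured(net)), c(4L, 3L))
    # significant downregulation of a repressor is a positive pathway effect
    expect_equal(effectsMatrix(net)["m1", "REP1"], 1)
})

test_that("degenerate zero log2fc with significant q contributes zero", {
    lfc <- matrix(c(0, -0.5), 2, 1, dimnames = list(c("A", "B"), "m1"))
    qv <- matrix(1e-5, 2, 1, dimnames = dimnames(lfc))
    ann <- makeAnnotation(protein = c("A", "B"), pathway = "W",
                          role = "activator")
    net <- buildNetworkEffects(makeEffectTable(lfc, qv), ann)[["W"]]
    expect_equal(unname(effectsMatrix(net)["m1", ]), c(0, -1))
})

test_that("PC score equals the weighted signed sum with frozen hand cases", {
    # 4 measured proteins; down 2 activators, up 1 repressor:
    # effects (-1, -1, -1, 0) -> score -0.75
    prots <- c("A1", "A2", "R1", "A3")
    lfc <- matrix(c(-0.6, -0.7, 0.4, 0.1), 4, 1,
                  dimnames = list(prots, "m1"))
    qv <- matrix(c(1e-4, 1e-4, 1e-4, 0.9), 4, 1, dimnames = dimnames(lfc))
    ann <- makeAnnotation(protein = prots, pathway = "W",
                          role = c("activator", "activator", "repressor",
                                   "activator"))
    net <- buildNetworkEffects(makeEffectTable(lfc, qv), ann)[["W"]]
    expect_equal(unname(computePCScores(net)), -0.75)

    # no significant interaction -> score 0
    qv2 <- matrix(0.9, 4, 1, dimnames = dimnames(lfc))
    net0 <- buildNetworkEffects(makeEffectTable(lfc, qv2), ann)[["W"]]
    expect_equal(unname(computePCScores(net0)), 0)

    # fully consistent repression attains the lower bound -1
    lfc3 <- matrix(c(-0.6, -0.7, 0.4, -0.5), 4, 1,
                   dimnames = list(prots, "m1"))
    qv3 <- matrix(1e-4, 4, 1, dimnames = dimnames(lfc))
    net3 <- buildNetworkEffects(makeEffectTable(lfc3, qv3), ann)[["W"]]
    expect_equal(unname(computePCScores(net3)), -1)
})

test_that("scores equal a brute-force re-evaluation on random small matrices", {
    set.seed(7)
    for (rep in 1:20) {
        M <- sample(2:6, 1); P <- sample(2:5, 1)
        prots <- sprintf("P%d", seq_len(P))
        mirs <- sprintf("m%d", seq_len(M))
        lfc <- matrix(rnorm(M * P), P, M, dimnames = list(prots, mirs))
        qv <- matrix(sample(c(1e-4, 0.5), M * P, TRUE), P, M,
                     dimnames = list(prots, mirs))
        miss <- matrix(runif(M * P) < 0.2, P, M, dimnames = list(prots, mirs))
        lfc[miss] <- NA
        roles <- sample(c("activator", "repressor"), P, TRUE)
        ann <- makeAnnotation(protein = prots, pathway = "W", role = roles)
        net <- buildNetworkEffects(makeEffectTable(lfc, qv, miss), ann)[["W"]]
        sc <- computePCScores(net)
        for (m in mirs) {
            npos <- nneg <- nmeas <- 0
            for (p in prots) {
                if (miss[p, m]) next
                nmeas <- nmeas + 1
                if (qv[p, m] > 0.001 || lfc[p, m] == 0) next
                dir <- sign(lfc[p, m])
                role <- roles[match(p, prots)]
                eff <- if (role == "activator") dir else -dir
                if (eff > 0) npos <- npos + 1 else nneg <- nneg + 1
            }
            expected <- if (nmeas > 0) (npos - nneg) / nmeas else NA_real_
            expect_equal(unname(sc[m]), expected)
            if (nmeas > 0) expect_lte(abs(sc[m]), 1)  # boundedness
        }
    }
})

test_that("PC scores are antisymmetric under effect negation and role swap", {
    fx <- toyNetworkFixture()
    sc <- computePCScores(buildNetworkEffects(fx$et, fx$ann)[["WNT"]])
    neg <- fx$et
    assay(neg, "log2fc") <- -assay(neg, "log2fc")
    sc_neg <- computePCScores(buildNetworkEffects(neg, fx$ann)[["WNT"]])
    expect_equal(c(sc_neg), c(-sc))
    swapped <- makeAnnotation(
        protein = fx$ann$protein, pathway = fx$ann$pathway,
        role = ifelse(fx$ann$role == "activator", "repressor", "activator"))
    sc_swap <- computePCScores(buildNetworkEffects(fx$et, swapped)[["WNT"]])
    expect_equal(c(sc_swap), c(-sc))
})

test_that("an added negative interaction never increases the score numerator", {
    fx <- toyNetworkFixture()
    net <- buildNetworkEffects(fx$et, fx$ann)[["WNT"]]
    num_before <- computePCScores(net) * nMeasured(net)
    # make m2/ACT1 significant: downregulated activator -> negative effect
    et2 <- fx$et
    assay(et2, "qvalue")["ACT1", "m2"] <- 1e-5
    net2 <- buildNetworkEffects(et2, fx$ann)[["WNT"]]
    num_after <- computePCScores(net2) * nMeasured(net2)
    expect_true(all(num_after <= num_before))
})

test_that("permutation replicates preserve per-protein effect multisets", {
    # single-column instances expose the whole reassigned multiset
    for (v in list(c(1, 1, -1), c(-1, -1), c(1))) {
        M <- 5
        eff <- matrix(0, M, 1, dimnames = list(sprintf("m%d", 1:M), "P1"))
        eff[seq_along(v), 1] <- v
        net <- new("NetworkEffects", pathway = "W", effects = eff,
                   measured = matrix(TRUE, M, 1, dimnames = dimnames(eff)),
                   nMeasured = rep(1L, M))
        null <- permutationNull(net, B = 200, seed = 3)
        for (b in seq_len(ncol(null))) {
            got <- null[, b] * nMeasured(net)
            expect_equal(sort(unname(got[got != 0])), sort(v))
        }
    }
    # multi-column totals are conserved in every replicate
    fx <- toyNetworkFixture()
    net <- buildNetworkEffects(fx$et, fx$ann)[["WNT"]]
    null <- permutationNull(net, B = 100, seed = 4)
    tot <- sum(effectsMatrix(net))
    expect_equal(unname(colSums(null * nMeasured(net))), rep(tot, 100))
})

test_that("the resampling stream is reproducible and B is validated", {
    fx <- toyNetworkFixture()
    net <- buildNetworkEffects(fx$et, fx$ann)[["WNT"]]
    n1 <- permutationNull(net, B = 50, seed = 99)
    n2 <- permutationNull(net, B = 50, seed = 99)
    expect_identical(n1, n2)
    expect_error(permutationNull(net, B = 0), "B must be >= 1")
    # all-zero effect matrices give an all-zero null
    eff <- matrix(0, 3, 2, dimnames = list(c("a", "b", "c"), c("P1", "P2")))
    net0 <- new("NetworkEffects", pathway = "W", effects = eff,
                measured = matrix(TRUE, 3, 2, dimnames = dimnames(eff)),
                nMeasured = rep(2L, 3))
    expect_true(all(permutationNull(net0, B = 20, seed = 1) == 0))
})

test_that("empirical p-values agree with exhaustive enumeration", {
    # 3 miRNAs x 1 protein, one +1 effect: a miRNA's null score is +1/n_meas
    # with probability 1/3, else 0
    eff <- matrix(c(1, 0, 0), 3, 1, dimnames = list(c("m1", "m2", "m3"), "P1"))
    net <- new("NetworkEffects", pathway = "W", effects = eff,
               measured = matrix(TRUE, 3, 1, dimnames = dimnames(eff)),
               nMeasured = rep(1L, 3))
    B <- 10000
    null <- permutationNull(net, B = B, seed = 17)
    hit_freq <- mean(null["m1", ] != 0)
    expect_lt(abs(hit_freq - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / B))
    obs <- computePCScores(net)
    res <- empiricalFdr(obs, null, alpha = 0.05)
    p_exact <- (1 + B / 3) / (B + 1)
    mc_se <- 3 * B * sqrt((1 / 3) * (2 / 3) / B) / (B + 1)
    expect_lt(abs(res$p_emp[res$mirna == "m1"] - p_exact), mc_se)

    # richer instance: 5 miRNAs x 3 proteins with mixed-sign columns,
    # exact tail probabilities from full enumeration of all assignments
    mirs <- sprintf("m%d", 1:5)
    eff2 <- matrix(0, 5, 3, dimnames = list(mirs, c("P1", "P2", "P3")))
    eff2[c(1, 2), 1] <- c(1, -1)
    eff2[3, 2] <- -1
    eff2[c(1, 4), 3] <- c(-1, -1)
    net2 <- new("NetworkEffects", pathway = "W", effects = eff2,
                measured = matrix(TRUE, 5, 3, dimnames = dimnames(eff2)),
                nMeasured = rep(3L, 5))
    oracle <- enumNullOracle(eff2)
    null2 <- permutationNull(net2, B = B, seed = 23)
    obs2 <- computePCScores(net2)
    for (i in seq_along(mirs)) {
        tail_exact <- sum(oracle$prob[
            abs(oracle$numerators[, i] / 3) >= abs(obs2[i])])
        p_exact <- (1 + B * tail_exact) / (B + 1)
        mc_se <- 3 * B * sqrt(tail_exact * (1 - tail_exact) / B) / (B + 1)
        p_mc <- (1 + sum(abs(null2[i, ]) >= abs(obs2[i]))) / (B + 1)
        expect_lt(abs(p_mc - p_exact), max(mc_se, 1e-12))
    }
})

test_that("classification requires FDR significance with a matching sign", {
    sim <- simulateScreen(simConfig(nMirnas = 25, seed = 31))
    et <- differentialEffects(normalizeSignals(sim$signals))
    res <- pcScore(et, sim$annotation, B = 500, alphaFdr = 0.05, seed = 5)
    expect_setequal(unique(res$pathway), c("WNT", "MET", "ITG"))
    cls <- res$classification
    expect_true(all(res$qvalue[cls != "none"] <= 0.05))
    expect_true(all(res$score[cls == "repressor"] < 0))
    expect_true(all(res$score[cls == "activator"] > 0))
    expect_true(all(res$p_emp >= 1 / 501, na.rm = TRUE))
    # a zero observed score can never be significant
    expect_true(all(cls[res$score == 0] == "none"))
    # per-pathway BH: q-values recompute from p within each pathway
    for (pw in unique(res$pathway)) {
        i <- res$pathway == pw & !is.na(res$p_emp)
        expect_equal(res$qvalue[i], bhOracle(res$p_emp[i]), tolerance = 1e-12)
    }
    expect_error(empiricalFdr(setNames(0.5, "mX"),
                              matrix(0, 1, 5, dimnames = list("mY", NULL))),
                 "different miRNA sets")
})

test_that("overlap summary enumerates Venn regions by direction", {
    res <- S4Vectors::DataFrame(
        mirna = c("a", "b", "c", "b", "c", "c", "x"),
        pathway = c("W", "W", "W", "M", "M", "I", "I"),
        classification = c(rep("repressor", 6), "activator"))
    ov <- overlapSummary(res)
    triple <- ov[ov$direction == "repressor" & ov$pathways == "I&M&W", ]
    expect_equal(triple$count, 1L)
    expect_equal(triple$members, "c")
    expect_equal(ov[ov$pathways == "M&W", "count"], 1L)  # b
    expect_equal(ov[ov$direction == "activator", "pathways"], "I")
    # disjoint single-pathway sets: no multi-pathway regions
    res2 <- S4Vectors::DataFrame(
        mirna = c("a", "b"), pathway = c("W", "M"),
        classification = "repressor")
    ov2 <- overlapSummary(res2)
    expect_false(any(grepl("&", ov2$pathways)))
})
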