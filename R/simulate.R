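#' Configuration for a synthetic miRNA RPPA screen
#'
#' Defaults describe a desk-scale version of a genome-wide miRNA
#' gain-of-function RPPA screen: three pathways with the role composition
#' WNT 7 activators + 7 repressors, MET 14 + 3 and ITG 18 + 3; two
#' biological replicates per condition; two distinct mimic negative controls
#' with two replicates each; technical-triplicate spotting; Gaussian
#' spot-level noise on the log2 scale; and planted miRNAs that coordinately
#' shift all (a fraction \code{plantedCoverage} of) proteins of one pathway
#' in a role-consistent direction, with mild mean effects of -0.54 log2FC
#' for protein downregulations and +0.49 for upregulations.
#'
#' \code{plantedDirection = "mixed"} plants an 80/20 repress/activate split
#' per pathway, which under the default role composition reproduces the
#' roughly 2:1 down:up imbalance of significant effects seen in real
#' screens of this design.
#'
#' @param nMirnas number of library miRNAs (default 200).
#' @param pathways named list; each element \code{c(activators, repressors)}.
#' @param nPlantedPerPathway planted regulator miRNAs per pathway (default 5).
#' @param plantedDirection \code{"repress"}, \code{"activate"} or
#'   \code{"mixed"} (default).
#' @param plantedCoverage fraction of a pathway's proteins each planted
#'   miRNA perturbs (default 0.8).
#' @param effectMeanDown,effectMeanUp mean true log2FC of planted protein
#'   down-/upregulations (defaults -0.54, +0.49).
#' @param effectSd s.d. of true planted log2FCs around their mean
#'   (default 0.1).
#' @param noiseSd spot-level Gaussian noise s.d. on the log2 scale
#'   (default 0.25).
#' @param replicates biological replicates per condition (default 2).
#' @param spotsPerSample technical printing replicates per sample
#'   (default 3).
#' @param nBlocks spotting blocks (default 4).
#' @param nRounds transfection rounds; miRNAs are split evenly, each round
#'   gets its own control samples (default 1).
#' @param missingRate per-spot missingness probability (default 0.02).
#' @param blockSd s.d. of log2-scale per-(block, antibody) offsets
#'   (default 0.1).
#' @param seed integer RNG seed.
#' @return A classed list (\code{"SimulationConfig"}).
#' @export
simConfig <- function(nMirnas = 200,
                      pathways = list(WNT = c(activators = 7, repressors = 7),
                                      MET = c(activators = 14, repressors = 3),
                                      ITG = c(activators = 18, repressors = 3)),
                      nPlantedPerPathway = 5,
                      plantedDirection = c("mixed", "repress", "activate"),
                      plantedCoverage = 0.8,
                      effectMeanDown = -0.54, effectMeanUp = 0.49,
                      effectSd = 0.1, noiseSd = 0.25,
                      replicates = 2, spotsPerSample = 3, nBlocks = 4,
                      nRounds = 1, missingRate = 0.02, blockSd = 0.1,
                      seed = 1L) {
    cfg <- list(nMirnas = as.integer(nMirnas), pathways = pathways,
                nPlantedPerPathway = as.integer(nPlantedPerPathway),
                plantedDirection = match.arg(plantedDirection),
                plantedCoverage = plantedCoverage,
                effectMeanDown = effectMeanDown, effectMeanUp = effectMeanUp,
                effectSd = effectSd, noiseSd = noiseSd,
                replicates = as.integer(replicates),
                spotsPerSample = as.integer(spotsPerSample),
                nBlocks = as.integer(nBlocks), nRounds = as.integer(nRounds),
                missingRate = missingRate, blockSd = blockSd,
                seed = as.integer(seed))
    if (cfg$nPlantedPerPathway * length(pathways) > cfg$nMirnas)
        stop("more planted miRNAs than library miRNAs")
    if (!(cfg$plantedCoverage > 0 && cfg$plantedCoverage <= 1))
        stop("plantedCoverage must lie in (0, 1]")
    if (cfg$noiseSd <= 0) stop("noiseSd must be positive")
    if (!(cfg$missingRate >= 0 && cfg$missingRate < 1))
        stop("missingRate must lie in [0, 1)")
    if (any(vapply(pathways, sum, numeric(1)) < 1))
        stop("every pathway needs at least one protein")
    class(cfg) <- "SimulationConfig"
    cfg
}

#' @export
print.SimulationConfig <- function(x, ...) {
    cat(sprintf(paste0("SimulationConfig: %d miRNAs, %d pathways, ",
                       "%d planted/pathway (%s), seed %d\n"),
                x$nMirnas, length(x$pathways), x$nPlantedPerPathway,
                x$plantedDirection, x$seed))
    invisible(x)
}

#' Simulate a miRNA gain-of-function RPPA screen with ground truth
#'
#' Draws control wells from a per-protein log-normal baseline, shifts the
#' log2 means of planted-miRNA wells by the true planted log2FCs on
#' role-consistent pathway proteins (repressor-planting shifts activators
#' down and repressors up; mirrored for activator-planting), adds per-spot
#' Gaussian noise, multiplicative per-(block, antibody) offsets and a mildly
#' varying per-spot total-protein factor, and applies spot-level
#' missingness. All randomness flows from \code{cfg$seed}, so a given
#' configuration reproduces byte-identical output.
#'
#' @param cfg a \code{\link{simConfig}} object.
#' @return A list: \code{signals} (raw \linkS4class{ScreenExperiment}),
#'   \code{annotation} (\linkS4class{PathwayAnnotation}), and \code{truth} —
#'   itself a list with \code{classes} (data.frame over all (mirna, pathway)
#'   pairs: \code{true_class} in repressor/activator/none and the
#'   comma-joined \code{perturbed_proteins}) and \code{effects} (data.frame
#'   mirna, protein, pathway, \code{true_log2fc} for planted pairs).
#' @export
simulateScreen <- function(cfg) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    set.seed(cfg$seed)
    mirnas <- sprintf("mir%04d", seq_len(cfg$nMirnas))
    ann_rows <- list()
    for (pw in names(cfg$pathways)) {
        na <- cfg$pathways[[pw]][["activators"]]
        nr <- cfg$pathways[[pw]][["repressors"]]
        ann_rows[[pw]] <- data.frame(
            protein = c(sprintf("%s_A%02d", pw, seq_len(na)),
                        if (nr > 0) sprintf("%s_R%02d", pw, seq_len(nr))),
            pathway = pw,
            role = c(rep("activator", na), rep("repressor", nr)))
    }
    ann_df <- do.call(rbind, ann_rows)
    ann <- PathwayAnnotation(ann_df)
    proteins <- sort(unique(ann_df$protein))
    P <- length(proteins)

    # planted regulators: disjoint across pathways
    n_pl <- cfg$nPlantedPerPathway * length(cfg$pathways)
    planted_mirs <- if (n_pl > 0) sample(mirnas, n_pl) else character()
    plant <- data.frame(mirna = planted_mirs,
                        pathway = rep(names(cfg$pathways),
                                      each = cfg$nPlantedPerPathway),
                        stringsAsFactors = FALSE)
    plant$direction <- vapply(seq_len(nrow(plant)), function(i) {
        k <- (i - 1L) %% cfg$nPlantedPerPathway + 1L
        switch(cfg$plantedDirection,
               repress = "repress", activate = "activate",
               mixed = if (k <= round(0.8 * cfg$nPlantedPerPathway))
                   "repress" else "activate")
    }, character(1))

    true_lfc <- matrix(0, P, cfg$nMirnas, dimnames = list(proteins, mirnas))
    eff_rows <- list()
    pert <- character(nrow(plant))
    for (i in seq_len(nrow(plant))) {
        pw <- plant$pathway[i]
        pw_prot <- ann_df$protein[ann_df$pathway == pw]
        k <- max(1L, round(cfg$plantedCoverage * length(pw_prot)))
        hit <- sort(sample(pw_prot, k))
        role <- ann_df$role[match(hit, ann_df$protein)]
        down <- if (plant$direction[i] == "repress") role == "activator"
                else role == "repressor"
        lfc <- ifelse(down,
                      stats::rnorm(k, cfg$effectMeanDown, cfg$effectSd),
                      stats::rnorm(k, cfg$effectMeanUp, cfg$effectSd))
        true_lfc[hit, plant$mirna[i]] <- lfc
        pert[i] <- paste(hit, collapse = ",")
        eff_rows[[i]] <- data.frame(mirna = plant$mirna[i], protein = hit,
                                    pathway = pw, true_log2fc = lfc)
    }

    classes <- expand.grid(mirna = mirnas, pathway = names(cfg$pathways),
                           stringsAsFactors = FALSE)
    classes$true_class <- "none"
    classes$perturbed_proteins <- ""
    key <- paste(classes$mirna, classes$pathway)
    hit_i <- match(paste(plant$mirna, plant$pathway), key)
    classes$true_class[hit_i] <- ifelse(plant$direction == "repress",
                                        "repressor", "activator")
    classes$perturbed_proteins[hit_i] <- pert

    # sample sheet: per round, its miRNAs plus 2 control kinds x replicates
    round_of <- rep(seq_len(cfg$nRounds), length.out = cfg$nMirnas)
    sheets <- list()
    for (r in seq_len(cfg$nRounds)) {
        conds <- c(mirnas[round_of == r], "ctrl1", "ctrl2")
        sheets[[r]] <- expand.grid(condition = conds,
                                   replicate = seq_len(cfg$replicates),
                                   stringsAsFactors = FALSE)
        sheets[[r]]$round <- paste0("R", r)
    }
    sheet <- do.call(rbind, sheets)
    sheet$is_control <- sheet$condition %in% c("ctrl1", "ctrl2")
    sheet$control_kind <- ifelse(sheet$is_control, sheet$condition, "none")
    sheet$sample_id <- sprintf("%s.%s.rep%d", sheet$round, sheet$condition,
                               sheet$replicate)
    sheet$block <- paste0("B", sample(rep_len(seq_len(cfg$nBlocks),
                                              nrow(sheet))))

    baseline <- stats::rnorm(P, mean = 10, sd = 1)
    block_off <- matrix(stats::rnorm(P * cfg$nBlocks, 0, cfg$blockSd), P,
                        cfg$nBlocks,
                        dimnames = list(proteins,
                                        paste0("B", seq_len(cfg$nBlocks))))
    spots <- sheet[rep(seq_len(nrow(sheet)), each = cfg$spotsPerSample), ]
    spots$spot <- rep(seq_len(cfg$spotsPerSample), times = nrow(sheet))
    n_sp <- nrow(spots)

    shift <- matrix(0, P, n_sp)
    is_mir <- !spots$is_control
    shift[, is_mir] <- true_lfc[, match(spots$condition[is_mir], mirnas)]
    log2sig <- baseline + shift + block_off[, spots$block] +
        matrix(stats::rnorm(P * n_sp, 0, cfg$noiseSd), P, n_sp)
    tp <- matrix(2^stats::rnorm(P * n_sp, 0, 0.15), P, n_sp)
    signal <- 2^log2sig * tp
    if (cfg$missingRate > 0)
        signal[matrix(stats::runif(P * n_sp) < cfg$missingRate, P, n_sp)] <-
            NA_real_

    records <- data.frame(
        sample_id = rep(spots$sample_id, each = P),
        condition = rep(spots$condition, each = P),
        replicate = rep(spots$replicate, each = P),
        spot = rep(spots$spot, each = P),
        block = rep(spots$block, each = P),
        round = rep(spots$round, each = P),
        antibody_id = rep(proteins, times = n_sp),
        signal = as.vector(signal),
        total_protein = as.vector(tp),
        is_control = rep(spots$is_control, each = P),
        control_kind = rep(spots$control_kind, each = P))
    records <- records[!is.na(records$signal), ]
    se <- ScreenExperiment(records)
    list(signals = se, annotation = ann,
         truth = list(classes = classes,
                      effects = if (length(eff_rows))
                          do.call(rbind, eff_rows)
                      else data.frame(mirna = character(),
                                      protein = character(),
                                      pathway = character(),
                                      true_log2fc = numeric())))
}

#' Recovery of planted regulators
#'
#' Confronts PC-score classifications with the generator's ground truth:
#' per pathway (and overall), sensitivity (planted regulators classified
#' with the correct sign), specificity (unplanted miRNAs classified none),
#' and the wrong-sign misclassification rate among planted regulators,
#' reported separately from misses.
#'
#' @param results a PC-score result \linkS4class{DataFrame} (from
#'   \code{\link{pcScore}} / \code{\link{empiricalFdr}}).
#' @param truth the \code{truth$classes} data.frame from
#'   \code{\link{simulateScreen}} (columns mirna, pathway, true_class).
#' @return A data.frame with one row per pathway plus \code{"overall"}:
#'   confusion counts and sensitivity / specificity / wrong-sign rates.
#' @export
recoveryReport <- function(results, truth) {
    res <- as.data.frame(results)[, c("mirna", "pathway", "classification")]
    truth <- as.data.frame(truth)[, c("mirna", "pathway", "true_class")]
    m <- merge(truth, res, by = c("mirna", "pathway"), all.x = TRUE)
    m$classification[is.na(m$classification)] <- "none"
    one <- function(d, label) {
        planted <- d$true_class != "none"
        tp <- sum(planted & d$classification == d$true_class)
        wrong <- sum(planted & d$classification != "none" &
                         d$classification != d$true_class)
        tn <- sum(!planted & d$classification == "none")
        data.frame(
            pathway = label,
            n_planted = sum(planted), n_unplanted = sum(!planted),
            n_recovered = tp, n_wrong_sign = wrong,
            n_missed = sum(planted) - tp - wrong,
            sensitivity = if (any(planted)) tp / sum(planted) else NA_real_,
            specificity = if (any(!planted)) tn / sum(!planted) else NA_real_,
            wrong_sign_rate = if (any(planted)) wrong / sum(planted)
                              else NA_real_)
    }
    parts <- lapply(split(m, m$pathway), function(d) one(d, d$pathway[1L]))
    out <- rbind(do.call(rbind, parts), one(m, "overall"))
    rownames(out) <- NULL
    out
}
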