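#' Canonical temporal module shapes
#'
#' Six unit-scaled time-course archetypes over the seven sampling
#' timepoints: modules 1-2 are progressive down-regulation with troughs
#' at 24 h and 2 d; modules 3-6 are progressive up-regulation peaking at
#' 24 h, 2 d, 7 d and 14 d. Each shape has maximum absolute value 1, so
#' multiplying by an effect size gives that peak log2 fold change.
#'
#' @return 6 x 7 numeric matrix (modules x timepoints).
#' @examples
#' apply(defaultModuleShapes()[3:6, ], 1, which.max)  # peaks 3,4,6,7
#' @export
defaultModuleShapes <- function() {
    m <- rbind(
        c(-0.30, -0.70, -1.00, -0.80, -0.60, -0.40, -0.20),
        c(-0.20, -0.50, -0.80, -1.00, -0.80, -0.50, -0.30),
        c( 0.30,  0.70,  1.00,  0.80,  0.50,  0.30,  0.20),
        c( 0.20,  0.50,  0.80,  1.00,  0.80,  0.50,  0.30),
        c( 0.10,  0.20,  0.40,  0.60,  0.80,  1.00,  0.70),
        c( 0.05,  0.10,  0.20,  0.30,  0.50,  0.80,  1.00))
    dimnames(m) <- list(paste0("module", 1:6), timepointLevels())
    m
}

#' Simulate a temporal label-free proteome with known ground truth
#'
#' Generates a protein x sample intensity matrix over the full
#' 2 groups x 7 timepoints x `nReps` replicates design. Per-protein
#' baseline log2 abundance is drawn as
#' `Normal(baseMeanLog, baseSdLog)`; replicate noise is
#' `Normal(0, noiseSdLog)`. A fraction `deFraction` of proteins is
#' planted as differentially expressed: each is assigned one of the six
#' temporal modules and its treated-group (YB1) values are shifted by
#' `effectLog2FC * shape(timepoint)` on the log2 scale. Values are then
#' left-censored missing-not-at-random: each cell goes missing
#' independently with probability `plogis((cq - x) / censorSteepness)`
#' where `cq` is the `censorQuantile` quantile of all generated log2
#' intensities — a single global detection limit. The returned matrix
#' holds raw intensities `2^x` with `NA` for censored cells.
#'
#' Unique-peptide counts are drawn as `1 + Poisson(2)` with a planted
#' fraction `zeroUniqueFraction` of zero-unique proteins so the
#' identification filter has work to do.
#'
#' @param nProteins number of proteins.
#' @param nReps replicates per group x timepoint cell (>= 2).
#' @param deFraction fraction of proteins with a planted effect
#'   (default 0.4, the scale of effect prevalence the pipeline is
#'   designed for).
#' @param effectLog2FC peak |log2 fold change| of planted effects.
#' @param moduleShapes 6 x 7 unit-scaled shapes
#'   ([defaultModuleShapes()]).
#' @param baseMeanLog,baseSdLog mean/SD of per-protein baseline log2
#'   abundance.
#' @param noiseSdLog replicate noise SD on log2 scale.
#' @param censorQuantile quantile of the global log-intensity marginal
#'   at which the missingness probability is 1/2.
#' @param censorSteepness logistic scale of the censoring curve (log2
#'   units); smaller = sharper detection limit.
#' @param zeroUniqueFraction fraction of proteins with 0 unique
#'   peptides.
#' @param seed integer seed; same seed and parameters give identical
#'   output.
#' @return list with
#'   \describe{
#'     \item{experiment}{a [ProteomeExperiment][ProteomeExperiment-class].}
#'     \item{truth}{list: `deProteins` (ids), `moduleLabel` (named, one
#'       module per DE protein), `trueLog2FC` (proteins x timepoints),
#'       `censoredMask` (logical matrix), `censorPoint` (cq) and
#'       `logIntensity` (the complete pre-censoring log2 matrix).}
#'   }
#' @examples
#' sim <- simulateProteome(nProteins = 100, seed = 1)
#' length(sim$truth$deProteins)
#' @export
simulateProteome <- function(nProteins = 1000L, nReps = 4L,
                             deFraction = 0.4, effectLog2FC = 2,
                             moduleShapes = defaultModuleShapes(),
                             baseMeanLog = 20, baseSdLog = 2,
                             noiseSdLog = 0.5,
                             censorQuantile = 0.15,
                             censorSteepness = 0.5,
                             zeroUniqueFraction = 0.05,
                             seed = 1L) {
    stopifnot(nProteins >= 1, deFraction >= 0, deFraction <= 1,
              baseSdLog >= 0, noiseSdLog >= 0,
              censorQuantile > 0, censorQuantile < 1,
              censorSteepness > 0)
    if (nReps < 2)
        stop("nReps must be >= 2 (presence filter would be degenerate)")
    if (!identical(dim(moduleShapes), c(6L, 7L)))
        stop("moduleShapes must be a 6 x 7 matrix")
    set.seed(seed)

    tps <- timepointLevels()
    design <- expand.grid(replicate = seq_len(nReps), timepoint = tps,
                          group = groupLevels(),
                          KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
    design <- design[, c("group", "timepoint", "replicate")]
    rownames(design) <- with(design, paste(group, timepoint, replicate,
                                           sep = "_"))
    nS <- nrow(design)

    proteins <- sprintf("P%05d", seq_len(nProteins))
    nDE <- round(deFraction * nProteins)
    deProteins <- if (nDE > 0) sample(proteins, nDE) else character(0)
    moduleLabel <- if (nDE > 0)
        stats::setNames(sample.int(6L, nDE, replace = TRUE), deProteins)
    else integer(0)

    trueLFC <- matrix(0, nProteins, 7,
                      dimnames = list(proteins, tps))
    if (nDE > 0)
        trueLFC[deProteins, ] <- effectLog2FC *
            moduleShapes[moduleLabel, , drop = FALSE]

    base <- stats::rnorm(nProteins, baseMeanLog, baseSdLog)
    x <- matrix(base, nProteins, nS) +
        matrix(stats::rnorm(nProteins * nS, sd = noiseSdLog), nProteins, nS)
    isTreated <- design$group == "YB1"
    tpIndex <- match(design$timepoint, tps)
    for (j in which(isTreated))
        x[, j] <- x[, j] + trueLFC[, tpIndex[j]]
    dimnames(x) <- list(proteins, rownames(design))

    cq <- stats::quantile(x, censorQuantile, names = FALSE)
    pMiss <- stats::plogis((cq - x) / censorSteepness)
    censored <- matrix(stats::runif(length(x)) < pMiss,
                       nProteins, nS, dimnames = dimnames(x))

    intensity <- 2^x
    intensity[censored] <- NA_real_

    up <- 1L + stats::rpois(nProteins, 2)
    nZero <- round(zeroUniqueFraction * nProteins)
    if (nZero > 0) up[sample.int(nProteins, nZero)] <- 0L
    names(up) <- proteins

    pe <- ProteomeExperiment(intensity, design, up)
    list(experiment = pe,
         truth = list(deProteins = sort(deProteins),
                      moduleLabel = moduleLabel,
                      trueLog2FC = trueLFC,
                      censoredMask = censored,
                      censorPoint = cq,
                      logIntensity = x))
}
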