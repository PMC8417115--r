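#' Fit the empirical-Bayes variance moderation prior
#'
#' Estimates the prior degrees of freedom `d0` and prior variance
#' `s0^2` of the hierarchical variance model
#' `s_g^2 ~ s0^2 * F(d_g, d0)` by the method of moments on
#' `log(s_g^2)`: with `z_g = log(s_g^2)` and
#' `e_g = z_g - digamma(d_g/2) + log(d_g/2)`, the model implies
#' `E[e_g] = log(s0^2) - digamma(d0/2) + log(d0/2)` and
#' `Var[e_g] = trigamma(d_g/2) + trigamma(d0/2)`. Matching the
#' empirical mean and variance of `e_g` yields `d0` via the inverse
#' trigamma and then `s0^2`. When the spread of `log(s_g^2)` is at or
#' below its expected sampling variance the prior is degenerate:
#' `d0 = Inf` and `s0^2 = mean(s_g^2)`.
#'
#' @param s2 per-protein residual variances.
#' @param df per-protein residual degrees of freedom (recycled);
#'   proteins with `df < 1` are excluded from the fit.
#' @return a [ModerationPrior][ModerationPrior-class].
#' @examples
#' fitModerationPrior(rep(4, 20), df = 6)  # degenerate: d0 = Inf
#' @export
fitModerationPrior <- function(s2, df) {
    df <- rep_len(df, length(s2))
    ok <- is.finite(s2) & s2 > 0 & df >= 1
    if (sum(ok) < 2)
        stop("need >= 2 proteins with positive variance and df >= 1")
    s2 <- s2[ok]; df <- df[ok]

    z <- log(s2)
    e <- z - digamma(df / 2) + log(df / 2)
    ebar <- mean(e)
    n <- length(e)
    evar <- sum((e - ebar)^2) / (n - 1) - mean(trigamma(df / 2))

    if (evar > 0) {
        d0 <- 2 * trigammaInverse(evar)
        s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    } else {
        d0 <- Inf
        s02 <- mean(s2)
    }
    new("ModerationPrior", dfPrior = d0, varPrior = s02)
}

# Newton solve of trigamma(x) = y (y > 0), on the 1/x-convexified scale
trigammaInverse <- function(y) {
    if (y > 1e7) return(1 / sqrt(y))
    if (y < 1e-6) return(1 / y)
    x <- 0.5 + 1 / y
    for (i in 1:50) {
        tri <- trigamma(x)
        dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
        x <- x + dif
        if (abs(dif) / x < 1e-10) break
    }
    x
}

#' Per-timepoint moderated t-test
#'
#' Tests YB1 vs PBS at one timepoint for every testable protein. Per
#' protein: `log2fc = mean(YB1) - mean(PBS)` on the (imputed) glog2
#' scale; the pooled residual variance `s_g^2` (df `n1 + n2 - 2`) is
#' shrunk towards the prior,
#' `s_post^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, and
#' `t = log2fc / (s_post * sqrt(1/n1 + 1/n2))` is referred to a t
#' distribution on `d0 + d_g` degrees of freedom (standard normal when
#' `d0 = Inf`). With `d0 = 0` this is the ordinary pooled two-sample
#' t-test.
#'
#' @param pe a [ProteomeExperiment][ProteomeExperiment-class] with the
#'   assay named by `assayName`, or a bare matrix plus a design
#'   data.frame via `design`.
#' @param timepoint one of [timepointLevels()].
#' @param prior a [ModerationPrior][ModerationPrior-class]; `NULL` fits
#'   the prior from this timepoint's variances.
#' @param proteins protein ids to test (e.g. the testable set from
#'   [filterPresence()]); default all rows.
#' @param assayName assay to test on (default `"imputed"`).
#' @param design for matrix input: data.frame with `group` per column.
#' @return data.frame with columns `protein`, `timepoint`, `log2fc`,
#'   `t`, `df`, `p`, `n1`, `n2`, plus the prior used in
#'   `attr(, "prior")`. Proteins with fewer than 2 values in either
#'   group are skipped and listed in `attr(, "skipped")`.
#' @examples
#' sim <- simulateProteome(nProteins = 60, seed = 1)
#' pe <- imputeQRILC(vsnNormalize(sim$experiment), seed = 1)
#' head(moderatedTTest(pe, "2d"))
#' @export
moderatedTTest <- function(pe, timepoint, prior = NULL, proteins = NULL,
                           assayName = "imputed", design = NULL) {
    if (is(pe, "ProteomeExperiment")) {
        x <- assay(pe, assayName)
        cd <- as.data.frame(colData(pe))
    } else {
        x <- as.matrix(pe)
        if (is.null(design)) stop("design required for matrix input")
        cd <- design
    }
    stopifnot(timepoint %in% cd$timepoint)
    inTP <- cd$timepoint == timepoint
    y <- x[, inTP & cd$group == "YB1", drop = FALSE]
    p <- x[, inTP & cd$group == "PBS", drop = FALSE]
    if (!is.null(proteins)) {
        y <- y[proteins, , drop = FALSE]
        p <- p[proteins, , drop = FALSE]
    }

    n1 <- rowSums(!is.na(y))
    n2 <- rowSums(!is.na(p))
    ok <- n1 >= 2 & n2 >= 2
    skipped <- data.frame(protein = rownames(y)[!ok],
                          reason = sprintf("n1=%d, n2=%d",
                                           n1[!ok], n2[!ok]))
    y <- y[ok, , drop = FALSE]; p <- p[ok, , drop = FALSE]
    n1 <- n1[ok]; n2 <- n2[ok]

    m1 <- rowMeans(y, na.rm = TRUE)
    m2 <- rowMeans(p, na.rm = TRUE)
    ss1 <- rowSums((y - m1)^2, na.rm = TRUE)
    ss2 <- rowSums((p - m2)^2, na.rm = TRUE)
    dg <- n1 + n2 - 2
    s2 <- (ss1 + ss2) / dg

    if (is.null(prior))
        prior <- fitModerationPrior(s2, dg)
    d0 <- dfPrior(prior); s02 <- varPrior(prior)

    s2post <- if (is.infinite(d0)) rep(s02, length(s2))
              else (d0 * s02 + dg * s2) / (d0 + dg)
    lfc <- m1 - m2
    tstat <- lfc / sqrt(s2post * (1 / n1 + 1 / n2))
    dfTotal <- d0 + dg
    pval <- 2 * stats::pt(-abs(tstat), df = dfTotal)

    res <- data.frame(protein = rownames(y), timepoint = timepoint,
                      log2fc = lfc, t = tstat, df = dfTotal, p = pval,
                      n1 = n1, n2 = n2, row.names = NULL)
    attr(res, "prior") <- prior
    attr(res, "skipped") <- skipped
    res
}

#' Call differentially expressed proteins
#'
#' Flags a protein/timepoint as differentially expressed when
#' `p <= pMax` and `|log2fc| >= lfcMin` (defaults 0.05 and 1, i.e. a
#' two-fold change in either direction). Benjamini-Hochberg adjusted
#' p-values are added per timepoint for reporting; the flag itself uses
#' raw p-values. `scale = "natural"` instead applies the one-sided
#' fold-change reading `2^log2fc > lfcThreshold`.
#'
#' @param results data.frame from [moderatedTTest()] (possibly several
#'   timepoints rbound together).
#' @param lfcMin minimum |log2 fold change| (default 1).
#' @param pMax maximum raw p-value (default 0.05).
#' @param scale `"log2"` (default, two-sided) or `"natural"`.
#' @return list with `results` (input plus `p_adj` and `de` columns),
#'   `countsByTimepoint` and `unionCount` (proteins DE at >= 1
#'   timepoint).
#' @examples
#' r <- data.frame(protein = c("a", "b"), timepoint = "2d",
#'                 log2fc = c(2, 0.5), t = c(5, 1), df = 6,
#'                 p = c(0.01, 0.4), n1 = 4, n2 = 4)
#' callDE(r)$unionCount
#' @export
callDE <- function(results, lfcMin = 1, pMax = 0.05,
                   scale = c("log2", "natural")) {
    scale <- match.arg(scale)
    results$p_adj <- stats::ave(results$p, results$timepoint,
                                FUN = function(p)
                                    stats::p.adjust(p, method = "BH"))
    results$de <- if (scale == "log2")
        results$p <= pMax & abs(results$log2fc) >= lfcMin
    else
        results$p < pMax & 2^results$log2fc > lfcMin
    counts <- tapply(results$de, factor(results$timepoint,
                                        levels = timepointLevels()),
                     sum, default = 0L)
    list(results = results,
         countsByTimepoint = counts,
         unionCount = length(unique(results$protein[results$de])))
}

#' Run the full differential-expression cascade
#'
#' Convenience wrapper: unique-peptide filter -> per-timepoint presence
#' filter -> median-ratio/glog2 normalization -> left-censored
#' imputation -> per-timepoint moderated t (prior fit per timepoint) ->
#' DE calling.
#'
#' @param pe a [ProteomeExperiment][ProteomeExperiment-class] with raw
#'   intensities.
#' @param minUnique,minPerGroup filter settings.
#' @param lfcMin,pMax DE thresholds (see [callDE()]).
#' @param seed seed for the imputation draws.
#' @return list with `results` (flagged DE table),
#'   `countsByTimepoint`, `unionCount`, `testable` (logical matrix) and
#'   `experiment` (the processed object with all assays).
#' @examples
#' sim <- simulateProteome(nProteins = 80, seed = 2)
#' de <- runDEPipeline(sim$experiment, seed = 2)
#' de$unionCount
#' @export
runDEPipeline <- function(pe, minUnique = 1L, minPerGroup = 2L,
                          lfcMin = 1, pMax = 0.05, seed = 1L) {
    pe <- filterUniquePeptides(pe, minUnique)
    pres <- filterPresence(pe, minPerGroup)
    pe <- pe[pres$analysisSet, ]
    testable <- pres$testable[pres$analysisSet, , drop = FALSE]
    pe <- vsnNormalize(pe)
    pe <- imputeQRILC(pe, seed = seed)
    res <- lapply(timepointLevels(), function(tp) {
        ids <- rownames(testable)[testable[, tp]]
        if (!length(ids)) return(NULL)
        moderatedTTest(pe, tp, proteins = ids)
    })
    res <- do.call(rbind, res)
    called <- callDE(res, lfcMin = lfcMin, pMax = pMax)
    c(called, list(testable = testable, experiment = pe))
}
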