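#' Left-censored (QRILC-style) imputation
#'
#' Imputes missing log-scale intensities under the
#' missing-not-at-random assumption that a sample's missing values are
#' its left (low-abundance) tail. Per sample, the complete-data normal
#' parameters (mu, sigma) are estimated by quantile regression of the
#' observed order statistics on standard-normal quantiles: if `nMis` of
#' `nTot` values are missing, the k-th smallest observed value is
#' treated as the empirical `(nMis + k - 0.5) / nTot` quantile — the
#' observed upper portion of a censored normal. Each missing cell is
#' then drawn from `Normal(mu, sigma)` truncated above at the sample's
#' `truncationQuantile` point `mu + sigma * qnorm(truncationQuantile)`,
#' i.e. deep left-tail draws. Draws are seeded and made sample by
#' sample, so results are reproducible.
#'
#' @param pe a [ProteomeExperiment][ProteomeExperiment-class] carrying a
#'   `"glog2"` assay (see [vsnNormalize()]), or a bare log-scale matrix.
#' @param truncationQuantile upper truncation quantile of the imputation
#'   distribution (default 0.01).
#' @param seed integer seed.
#' @param assayName assay to impute when `pe` is a
#'   `ProteomeExperiment`.
#' @return for a `ProteomeExperiment`, the object with an `"imputed"`
#'   assay added and the per-sample fits in `metadata(pe)$qrilc`; for a
#'   matrix, a list with `imputed` and `fit` (data.frame with columns
#'   `sample`, `mu`, `sigma`, `truncationPoint`, `nImputed`).
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(400, 20, 2), 100, 4,
#'             dimnames = list(sprintf("p%03d", 1:100), paste0("s", 1:4)))
#' m[m < 19] <- NA
#' fit <- imputeQRILC(m, seed = 1)$fit
#' round(fit$mu, 1)
#' @export
imputeQRILC <- function(pe, truncationQuantile = 0.01, seed = 1L,
                        assayName = "glog2") {
    isPE <- is(pe, "ProteomeExperiment")
    x <- if (isPE) assay(pe, assayName) else as.matrix(pe)
    stopifnot(truncationQuantile > 0, truncationQuantile < 1)
    set.seed(seed)

    out <- x
    fit <- data.frame(sample = colnames(x) %||% as.character(seq_len(ncol(x))),
                      mu = NA_real_, sigma = NA_real_,
                      truncationPoint = NA_real_, nImputed = 0L)
    for (j in seq_len(ncol(x))) {
        col <- x[, j]
        obs <- col[!is.na(col)]
        if (length(obs) < 10)
            stop(sprintf(
                "sample %s has %d observed values (< 10); fit unidentifiable",
                fit$sample[j], length(obs)))
        est <- fitCensoredNormal(obs, nTot = length(col))
        fit$mu[j] <- est[["mu"]]; fit$sigma[j] <- est[["sigma"]]
        trunc <- est[["mu"]] + est[["sigma"]] * stats::qnorm(truncationQuantile)
        fit$truncationPoint[j] <- trunc
        mis <- which(is.na(col))
        fit$nImputed[j] <- length(mis)
        if (length(mis)) {
            # inverse-CDF draws from N(mu, sigma) truncated above at trunc
            u <- stats::runif(length(mis)) * truncationQuantile
            out[mis, j] <- est[["mu"]] + est[["sigma"]] * stats::qnorm(u)
        }
    }

    if (isPE) {
        assay(pe, "imputed") <- out
        metadata(pe)$qrilc <- fit
        pe
    } else {
        list(imputed = out, fit = fit)
    }
}

#' Fit a left-censored normal by order-statistic regression
#'
#' Regresses sorted observed values on the standard-normal quantiles of
#' their plotting positions among the full (observed + censored)
#' sample, assuming all censored values lie below the observed ones.
#'
#' @param obs observed (uncensored) values.
#' @param nTot total number of values including censored ones.
#' @return named numeric: `mu` (intercept) and `sigma` (slope).
#' @keywords internal
fitCensoredNormal <- function(obs, nTot) {
    nMis <- nTot - length(obs)
    stopifnot(nMis >= 0)
    y <- sort(obs)
    p <- (nMis + seq_along(y) - 0.5) / nTot
    q <- stats::qnorm(p)
    cf <- stats::coef(stats::lm(y ~ q))
    sigma <- max(unname(cf[2]), .Machine$double.eps)
    c(mu = unname(cf[1]), sigma = sigma)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
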