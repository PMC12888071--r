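## MacKenzie-Bailey style chi-square goodness of fit with a parametric
## bootstrap null distribution.

## Cells with expected count below `minE` are pooled into one combined
## cell before comparison; returns sum((O - E)^2 / E).
.chisqPooled <- function(O, E, minE = 2) {
  keep <- E > 1e-12
  O <- O[keep]; E <- E[keep]
  if (!length(E)) return(0)
  small <- E < minE
  if (sum(small) > 1) {
    O <- c(O[!small], sum(O[small]))
    E <- c(E[!small], sum(E[small]))
  }
  sum((O - E)^2 / E)
}

#' Observed chi-square discrepancy of an occupancy fit
#'
#' Sites are grouped into cohorts sharing the same detection design row and
#' the same missing-data pattern. Within each cohort the observed counts of
#' the distinct detection histories are compared with their expected counts
#' under the fitted model (all unobserved histories collapse into one
#' remainder cell with observed count 0); expected counts below
#' \code{minExpected} are pooled. The statistic is
#' \eqn{\sum (O - E)^2 / E} over the pooled cells of every cohort.
#'
#' @param fit a converged \code{\linkS4class{OccupancyFit}}.
#' @param history the \code{\linkS4class{DetectionHistory}} it was fitted to.
#' @param minExpected pooling threshold for expected counts (default 2).
#' @return The chi-square statistic (scalar).
#' @export
mbChisq <- function(fit, history, minExpected = 2) {
  y <- detMatrix(history)
  X <- .occuDesign(history, fit@spec, xlevels = fit@xlevels)
  p <- plogis(drop(X %*% fit@beta))
  psi <- fit@psi
  naPat <- apply(is.na(y), 1, paste, collapse = "")
  desRow <- apply(X, 1, paste, collapse = "|")
  cohort <- paste(desRow, naPat, sep = "#")
  stat <- 0
  for (co in unique(cohort)) {
    idx <- which(cohort == co)
    pc <- p[idx[1]]
    obsIdx <- which(!is.na(y[idx[1], ]))
    hs <- apply(y[idx, obsIdx, drop = FALSE], 1, paste, collapse = "")
    tab <- table(hs)
    probs <- vapply(names(tab), function(h) {
      hv <- as.integer(strsplit(h, "")[[1]])
      ph <- prod(ifelse(hv == 1L, pc, 1 - pc))
      psi * ph + (1 - psi) * all(hv == 0L)
    }, 0)
    O <- c(as.numeric(tab), 0)
    E <- length(idx) * c(probs, max(0, 1 - sum(probs)))
    stat <- stat + .chisqPooled(O, E, minE = minExpected)
  }
  stat
}

## Simulate a detection-history matrix from a fitted model, preserving the
## covariates and the NA pattern of the observed data.
.simulateFromFit <- function(fit, history) {
  y <- detMatrix(history)
  X <- .occuDesign(history, fit@spec, xlevels = fit@xlevels)
  p <- plogis(drop(X %*% fit@beta))
  z <- if (fit@spec@psiMode == "free")
    rbinom(nrow(y), 1, fit@psi) else rep(1L, nrow(y))
  sim <- matrix(rbinom(length(y), 1, rep(p * z, ncol(y))),
                nrow(y), ncol(y), dimnames = dimnames(y))
  sim[is.na(y)] <- NA_integer_
  DetectionHistory(sim, siteCovs(history))
}

#' Parametric-bootstrap goodness-of-fit test
#'
#' Simulates \code{nBoot} datasets from the fitted model (same design, same
#' missing-data pattern), refits the model to each, and recomputes the
#' chi-square discrepancy of \code{\link{mbChisq}}. The p-value is the
#' proportion of bootstrap statistics at least as large as the observed
#' one. Deterministic under a fixed seed; replicates whose refit fails are
#' dropped and counted.
#'
#' @param fit a converged \code{\linkS4class{OccupancyFit}}.
#' @param history the fitted \code{\linkS4class{DetectionHistory}}.
#' @param nBoot number of bootstrap replicates (default 1000).
#' @param seed RNG seed (required).
#' @return A \code{\linkS4class{GOFResult}}.
#' @export
gofParboot <- function(fit, history, nBoot = 1000, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (!fit@converged)
    stop("goodness of fit requires a converged fit", call. = FALSE)
  set.seed(seed)
  obs <- mbChisq(fit, history)
  stats <- rep(NA_real_, nBoot)
  for (b in seq_len(nBoot)) {
    simH <- .simulateFromFit(fit, history)
    stats[b] <- tryCatch({
      refit <- suppressWarnings(fitOccu(simH, fit@spec, gradTol = 1e-4))
      mbChisq(refit, simH)
    }, error = function(e) NA_real_)
  }
  ok <- !is.na(stats)
  if (!any(ok))
    stop("all bootstrap refits failed", call. = FALSE)
  if (any(!ok))
    warning(sum(!ok), " bootstrap replicate(s) dropped (refit failure)",
            call. = FALSE)
  new("GOFResult", chisqObs = obs, bootStats = stats[ok],
      pValue = mean(stats[ok] >= obs), nBoot = sum(ok),
      nFailed = sum(!ok), seed = seed)
}
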