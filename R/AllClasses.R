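#' @import methods
#' @importFrom stats aov anova aggregate optim optimHess plogis qlogis qnorm
#'   quantile model.matrix pnorm rbinom rpois runif setNames
#' @importFrom utils read.csv write.csv head modifyList packageVersion
NULL

#' DetectionHistory: sites-by-occasions detection data
#'
#' The sufficient data for a single-season occupancy model: a matrix of
#' detection outcomes (1 = detected, 0 = surveyed but not detected,
#' NA = not surveyed) with one row per survey site and one column per
#' survey occasion, plus a per-site covariate table.
#'
#' @slot y integer matrix over \{1, 0, NA\}; rownames are site ids,
#'   colnames are occasion labels.
#' @slot siteCovs data.frame with one row per site, aligned with the rows
#'   of \code{y}. Must contain a \code{site_id} column and a \code{method}
#'   column (the survey method or method-combination label, e.g. "CT" or
#'   "CT+PAM"); typically also \code{location_id} and \code{habitat}.
#'
#' @seealso \code{\link{buildSensorHistory}}, \code{\link{buildTransectHistory}},
#'   \code{\link{fuseHistories}}, \code{\link{fitOccu}}
#' @export
setClass("DetectionHistory",
  representation(y = "matrix", siteCovs = "data.frame"))

setValidity("DetectionHistory", function(object) {
  y <- object@y
  sc <- object@siteCovs
  msg <- character()
  vals <- y[!is.na(y)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    msg <- c(msg, "matrix cells must be 1, 0 or NA")
  if (nrow(y) != nrow(sc))
    msg <- c(msg, "siteCovs rows must align 1:1 with matrix rows")
  if (nrow(y) > 0 && any(rowSums(!is.na(y)) == 0))
    msg <- c(msg, "every site must have at least one non-NA occasion")
  if (!all(c("site_id", "method") %in% names(sc)))
    msg <- c(msg, "siteCovs must contain 'site_id' and 'method' columns")
  else if (nrow(y) > 0 && !identical(rownames(y), as.character(sc$site_id)))
    msg <- c(msg, "rownames(y) must equal siteCovs$site_id")
  if (length(msg)) msg else TRUE
})

#' Construct a DetectionHistory
#'
#' @param y matrix over \{1, 0, NA\} (sites x occasions).
#' @param siteCovs data.frame with columns \code{site_id}, \code{method} and
#'   optionally \code{location_id}, \code{habitat}; one row per row of
#'   \code{y}.
#' @return A \code{\linkS4class{DetectionHistory}} object.
#' @examples
#' y <- rbind(a = c(1, 0, NA), b = c(0, 0, 1))
#' dh <- DetectionHistory(y, data.frame(site_id = c("a", "b"),
#'                                      method = "CT"))
#' nSites(dh)
#' @export
DetectionHistory <- function(y, siteCovs) {
  y <- as.matrix(y)
  storage.mode(y) <- "integer"
  siteCovs <- as.data.frame(siteCovs, stringsAsFactors = FALSE)
  siteCovs$site_id <- as.character(siteCovs$site_id)
  rownames(y) <- siteCovs$site_id
  if (is.null(colnames(y)) && ncol(y) > 0)
    colnames(y) <- paste0("occ_", seq_len(ncol(y)))
  rownames(siteCovs) <- NULL
  new("DetectionHistory", y = y, siteCovs = siteCovs)
}

setMethod("show", "DetectionHistory", function(object) {
  y <- object@y
  nna <- sum(!is.na(y))
  cat("DetectionHistory:", nrow(y), "sites x", ncol(y), "occasions\n")
  cat("  methods:", paste(unique(object@siteCovs$method), collapse = ", "), "\n")
  if (nna > 0)
    cat(sprintf("  naive detection rate: %d/%d = %.3f\n",
                sum(y == 1L, na.rm = TRUE), nna,
                sum(y == 1L, na.rm = TRUE) / nna))
  invisible(NULL)
})

#' OccupancyModelSpec: detection-covariate structure of a model
#'
#' @slot pFormula one-sided formula for the detection-probability design
#'   (e.g. \code{~method}, \code{~method * habitat}, \code{~1}).
#' @slot psiMode "fixed" (occupancy probability pinned at 1) or "free"
#'   (a single logit-scale occupancy intercept is estimated).
#' @slot referenceLevels named list mapping covariate name to its reference
#'   category for treatment (dummy) coding.
#' @export
setClass("OccupancyModelSpec",
  representation(pFormula = "formula", psiMode = "character",
                 referenceLevels = "list"))

setValidity("OccupancyModelSpec", function(object) {
  if (!object@psiMode %in% c("fixed", "free"))
    return("psiMode must be 'fixed' or 'free'")
  TRUE
})

#' Specify an occupancy detection model
#'
#' @param p one-sided formula for detection covariates; site-level factors
#'   only. The default \code{~1} is the null (constant-p) model.
#' @param psi "fixed" fixes the occupancy probability at 1 (appropriate when
#'   the species is known present at every sampled site); "free" estimates a
#'   single occupancy intercept on the logit scale.
#' @param referenceLevels named list of reference categories used for
#'   treatment coding; defaults to point transects for \code{method} and
#'   forest for \code{habitat}.
#' @return An \code{\linkS4class{OccupancyModelSpec}}.
#' @examples
#' occuModelSpec(~method)
#' @export
occuModelSpec <- function(p = ~1, psi = c("fixed", "free"),
                          referenceLevels = list(method = "PT",
                                                 habitat = "forest")) {
  psi <- match.arg(psi)
  new("OccupancyModelSpec", pFormula = p, psiMode = psi,
      referenceLevels = referenceLevels)
}

setMethod("show", "OccupancyModelSpec", function(object) {
  cat("OccupancyModelSpec: p", deparse(object@pFormula),
      "| psi", object@psiMode, "\n")
  invisible(NULL)
})

#' OccupancyFit: a fitted single-season occupancy model
#'
#' @slot name model label.
#' @slot beta named numeric vector of logit-scale detection coefficients.
#' @slot psi occupancy probability (1 when fixed; the back-transformed
#'   estimate when free).
#' @slot vcov coefficient covariance matrix (inverse observed information);
#'   includes the logit-psi row/column when psi is free.
#' @slot loglik maximized log-likelihood.
#' @slot nParams number of estimated parameters K.
#' @slot nSites number of sites entering the likelihood.
#' @slot aic,aicc information criteria (AICc uses n = number of sites).
#' @slot converged logical convergence flag (optimizer status and gradient
#'   norm).
#' @slot spec the \code{\linkS4class{OccupancyModelSpec}} fitted.
#' @slot xlevels factor levels seen at fit time, used by
#'   \code{\link{predictP}}.
#' @slot sites character vector of site ids used in the fit.
#' @export
setClass("OccupancyFit",
  representation(name = "character", beta = "numeric", psi = "numeric",
                 vcov = "matrix", loglik = "numeric", nParams = "numeric",
                 nSites = "numeric", aic = "numeric", aicc = "numeric",
                 converged = "logical", spec = "OccupancyModelSpec",
                 xlevels = "list", sites = "character"))

setValidity("OccupancyFit", function(object) {
  msg <- character()
  if (length(object@psi) != 1 || object@psi < 0 || object@psi > 1)
    msg <- c(msg, "psi must be a single probability in [0, 1]")
  if (isTRUE(object@converged) && object@aicc < object@aic - 1e-8)
    msg <- c(msg, "aicc must be >= aic")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OccupancyFit", function(object) {
  cat("OccupancyFit:", object@name, "\n")
  cat(sprintf("  psi (%s): %.3f | sites: %d | K: %d\n",
              object@spec@psiMode, object@psi,
              as.integer(object@nSites), as.integer(object@nParams)))
  cat(sprintf("  logLik: %.3f | AICc: %.2f | converged: %s\n",
              object@loglik, object@aicc, object@converged))
  se <- sqrt(pmax(diag(object@vcov)[seq_along(object@beta)], 0))
  print(round(data.frame(Estimate = object@beta, SE = se,
                         z = object@beta / se,
                         row.names = names(object@beta)), 3))
  invisible(NULL)
})

#' GOFResult: parametric-bootstrap goodness-of-fit summary
#'
#' @slot chisqObs observed chi-square discrepancy of the fitted model.
#' @slot bootStats chi-square statistics from datasets simulated under the
#'   fitted model.
#' @slot pValue proportion of bootstrap statistics >= observed.
#' @slot nBoot number of successful bootstrap replicates.
#' @slot nFailed replicates dropped because the refit failed.
#' @slot seed RNG seed used.
#' @export
setClass("GOFResult",
  representation(chisqObs = "numeric", bootStats = "numeric",
                 pValue = "numeric", nBoot = "numeric",
                 nFailed = "numeric", seed = "numeric"))

setValidity("GOFResult", function(object) {
  if (object@pValue < 0 || object@pValue > 1)
    return("pValue must lie in [0, 1]")
  if (length(object@bootStats) != object@nBoot)
    return("bootStats length must equal nBoot")
  TRUE
})

setMethod("show", "GOFResult", function(object) {
  cat(sprintf("Parametric-bootstrap GOF: chisq = %.3f, p = %.3f (%d reps",
              object@chisqObs, object@pValue, as.integer(object@nBoot)))
  if (object@nFailed > 0)
    cat(",", as.integer(object@nFailed), "refits failed")
  cat(")\n")
  invisible(NULL)
})

#' EffortCurve: detectability as a function of survey-window length
#'
#' @slot grid data.frame with one row per window length: \code{window_hours},
#'   \code{mean}, \code{lo}, \code{hi} (percentile interval over replicates),
#'   \code{n_sites}, \code{n_reps}.
#' @slot replicates numeric matrix (replicates x window lengths) of pooled
#'   detection estimates; columns named by window hours.
#' @slot reference named list with the benchmark estimate (typically the
#'   point-transect occupancy estimate at its native survey time):
#'   \code{mean}, \code{lo}, \code{hi}; may be empty.
#' @export
setClass("EffortCurve",
  representation(grid = "data.frame", replicates = "matrix",
                 reference = "list"))

setMethod("show", "EffortCurve", function(object) {
  g <- object@grid
  cat("EffortCurve:", nrow(g), "window lengths,",
      if (nrow(g)) g$n_reps[1] else 0, "replicates each\n")
  if (nrow(g))
    cat(sprintf("  windows %.0f-%.0f h; estimate range %.3f-%.3f\n",
                min(g$window_hours), max(g$window_hours),
                min(g$mean, na.rm = TRUE), max(g$mean, na.rm = TRUE)))
  if (length(object@reference))
    cat(sprintf("  reference: %.3f [%.3f, %.3f]\n", object@reference$mean,
                object@reference$lo, object@reference$hi))
  invisible(NULL)
})
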