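#' Number of sites in a detection history
#' @param object a \code{\linkS4class{DetectionHistory}}.
#' @return integer count.
#' @export
setGeneric("nSites", function(object) standardGeneric("nSites"))

#' @rdname nSites
#' @export
setMethod("nSites", "DetectionHistory", function(object) nrow(object@y))

#' Number of survey occasions in a detection history
#' @param object a \code{\linkS4class{DetectionHistory}}.
#' @return integer count.
#' @export
setGeneric("nOccasions", function(object) standardGeneric("nOccasions"))

#' @rdname nOccasions
#' @export
setMethod("nOccasions", "DetectionHistory", function(object) ncol(object@y))

#' Detection matrix of a history
#' @param object a \code{\linkS4class{DetectionHistory}}.
#' @return integer matrix over \{1, 0, NA\}.
#' @export
setGeneric("detMatrix", function(object) standardGeneric("detMatrix"))

#' @rdname detMatrix
#' @export
setMethod("detMatrix", "DetectionHistory", function(object) object@y)

#' Site covariate table of a history
#' @param object a \code{\linkS4class{DetectionHistory}}.
#' @return data.frame with one row per site.
#' @export
setGeneric("siteCovs", function(object) standardGeneric("siteCovs"))

#' @rdname siteCovs
#' @export
setMethod("siteCovs", "DetectionHistory", function(object) object@siteCovs)

#' @describeIn fitOccu logit-scale detection coefficients of a fit.
#' @export
setMethod("coef", "OccupancyFit", function(object, ...) object@beta)

#' @describeIn fitOccu coefficient covariance matrix.
#' @export
setMethod("vcov", "OccupancyFit", function(object, ...) object@vcov)

#' @describeIn fitOccu maximized log-likelihood (with df = K attribute).
#' @export
setMethod("logLik", "OccupancyFit", function(object, ...) {
  structure(object@loglik, df = object@nParams, class = "logLik")
})
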