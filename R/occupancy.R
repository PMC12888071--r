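## Single-season occupancy likelihood with detection covariates and psi
## fixable at 1; ML fitting, AICc ranking, back-transformed predictions,
## minimum-effort occasion counts.

.occuDesign <- function(history, spec, newdata = NULL, xlevels = NULL) {
  data <- if (is.null(newdata)) siteCovs(history) else newdata
  vars <- all.vars(spec@pFormula)
  for (v in vars) {
    if (!v %in% names(data))
      stop("covariate '", v, "' absent from site covariates", call. = FALSE)
    ref <- spec@referenceLevels[[v]]
    if (is.null(xlevels)) {
      lev <- unique(as.character(data[[v]]))
      if (!is.null(ref)) {
        if (!ref %in% lev)
          stop("reference level '", ref, "' for '", v,
               "' not present in the data", call. = FALSE)
        lev <- c(ref, setdiff(sort(lev), ref))
      } else lev <- sort(lev)
    } else {
      lev <- xlevels[[v]]
      bad <- setdiff(unique(as.character(data[[v]])), lev)
      if (length(bad))
        stop("level(s) not seen at fit time for '", v, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
    }
    data[[v]] <- factor(as.character(data[[v]]), levels = lev)
  }
  X <- model.matrix(spec@pFormula, data)
  attr(X, "xlevels") <- lapply(data[vars], levels)
  X
}

## Core negative log-likelihood on precomputed sufficient statistics:
## k1 = per-site detection count, nObs = per-site non-NA occasion count.
.nllCore <- function(beta, psiLogit, X, k1, nObs, psiMode) {
  eta <- drop(X %*% beta)
  lp <- plogis(eta, log.p = TRUE)        # log(p)
  lq <- plogis(-eta, log.p = TRUE)       # log(1 - p)
  logPH <- k1 * lp + (nObs - k1) * lq
  if (psiMode == "fixed") return(-sum(logPH))
  psi <- plogis(psiLogit)
  L <- psi * exp(logPH) + (1 - psi) * (k1 == 0)
  -sum(log(pmax(L, .Machine$double.xmin)))
}

.histStats <- function(history) {
  y <- detMatrix(history)
  allNA <- rowSums(!is.na(y)) == 0
  if (any(allNA)) {
    warning(sum(allNA), " site(s) with all-NA rows excluded", call. = FALSE)
    y <- y[!allNA, , drop = FALSE]
  }
  list(k1 = rowSums(y == 1L, na.rm = TRUE),
       nObs = rowSums(!is.na(y)),
       keep = !allNA)
}

#' Occupancy negative log-likelihood
#'
#' The single-season occupancy likelihood with site-level detection
#' covariates on the logit scale. For site i with non-missing cells
#' \eqn{h_{ij}} and \eqn{p_i = logit^{-1}(x_i'\beta)}, the contribution is
#' \deqn{\psi \prod_j p_i^{h_{ij}} (1-p_i)^{1-h_{ij}} +
#'       (1-\psi)\, I[\mathrm{all}\ h_{ij}=0],}
#' with NA cells skipped; \code{psi = "fixed"} pins \eqn{\psi = 1}.
#'
#' @param history a \code{\linkS4class{DetectionHistory}}.
#' @param spec an \code{\linkS4class{OccupancyModelSpec}}.
#' @param beta logit-scale detection coefficients, in the design-matrix
#'   column order of \code{spec}.
#' @param psi occupancy probability used when \code{spec@psiMode == "free"};
#'   ignored (taken as 1) when fixed.
#' @return The negative sum of log site contributions (a scalar).
#' @examples
#' dh <- DetectionHistory(rbind(s1 = c(1L, 0L)),
#'                        data.frame(site_id = "s1", method = "CT"))
#' occuNegLogLik(dh, occuModelSpec(~1), beta = 0)  # -log(0.25)
#' @export
occuNegLogLik <- function(history, spec, beta, psi = 1) {
  X <- .occuDesign(history, spec)
  st <- .histStats(history)
  X <- X[st$keep, , drop = FALSE]
  if (length(beta) != ncol(X))
    stop("beta must have length ", ncol(X), call. = FALSE)
  if (!all(is.finite(beta))) stop("non-finite beta", call. = FALSE)
  psiLogit <- if (spec@psiMode == "free") qlogis(psi) else NULL
  .nllCore(beta, psiLogit, X, st$k1, st$nObs, spec@psiMode)
}

#' Small-sample corrected AIC
#'
#' \eqn{AIC = -2\,\ell + 2K}; \eqn{AICc = AIC + 2K(K+1)/(n-K-1)} with n the
#' number of sites in the fit.
#'
#' @param loglik maximized log-likelihood.
#' @param K number of estimated parameters.
#' @param n sample size (number of sites).
#' @return AICc (scalar). Errors when \code{n <= K + 1}, where the
#'   correction is undefined.
#' @examples
#' aicc(-5, 2, 10)  # 14 + 12/7
#' @export
aicc <- function(loglik, K, n) {
  if (n <= K + 1)
    stop("AICc undefined: need n > K + 1 (n = ", n, ", K = ", K, ")",
         call. = FALSE)
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

.numGrad <- function(fn, par, eps = 1e-6) {
  vapply(seq_along(par), function(i) {
    h <- eps * max(1, abs(par[i]))
    pp <- par; pp[i] <- pp[i] + h
    pm <- par; pm[i] <- pm[i] - h
    (fn(pp) - fn(pm)) / (2 * h)
  }, 0)
}

#' Fit a single-season occupancy model
#'
#' Maximum-likelihood fit of the detection model in \code{spec} by
#' quasi-Newton (BFGS) optimization from zero-initialized coefficients,
#' with the coefficient covariance taken as the inverse of the numerically
#' differentiated observed information. Convergence requires optimizer
#' success and a gradient norm below \code{gradTol} (the fit is restarted
#' from the current point up to three times to reach it).
#'
#' A quasi-separated level (all-1 or all-0 cells) yields divergent
#' coefficients; a warning is issued when any coefficient exceeds 10 in
#' absolute value.
#'
#' @param history a \code{\linkS4class{DetectionHistory}}.
#' @param spec an \code{\linkS4class{OccupancyModelSpec}}.
#' @param name model label stored in the fit (default: deparsed formula).
#' @param gradTol gradient-norm convergence threshold (default 1e-6).
#' @param control passed to \code{\link[stats]{optim}}.
#' @param ... unused.
#' @return An \code{\linkS4class{OccupancyFit}}.
#' @examples
#' set.seed(1)
#' y <- matrix(rbinom(60, 1, 0.4), 20, 3)
#' dh <- DetectionHistory(y, data.frame(site_id = paste0("s", 1:20),
#'                                      method = "CT"))
#' fit <- fitOccu(dh, occuModelSpec(~1))
#' predictP(fit, data.frame(method = "CT"))
#' @export
fitOccu <- function(history, spec, name = NULL, gradTol = 1e-6,
                    control = list(), ...) {
  X <- .occuDesign(history, spec)
  xlevels <- attr(X, "xlevels")
  st <- .histStats(history)
  X <- X[st$keep, , drop = FALSE]
  free <- spec@psiMode == "free"
  nBeta <- ncol(X)
  fn <- function(par) {
    .nllCore(par[seq_len(nBeta)],
             if (free) par[nBeta + 1] else NULL,
             X, st$k1, st$nObs, spec@psiMode)
  }
  par <- rep(0, nBeta + free)
  ctrl <- modifyList(list(maxit = 500, reltol = 1e-12), control)
  opt <- optim(par, fn, method = "BFGS", control = ctrl)
  # Newton polish: BFGS under reltol can stall with a gradient norm a few
  # orders above machine scale; a couple of damped Newton steps fix that.
  gnorm <- sqrt(sum(.numGrad(fn, opt$par)^2))
  tries <- 0
  while (gnorm > gradTol && tries < 5) {
    H <- tryCatch(optimHess(opt$par, fn), error = function(e) NULL)
    step <- if (!is.null(H))
      tryCatch(solve(H, .numGrad(fn, opt$par)), error = function(e) NULL)
    else NULL
    if (is.null(step) || !all(is.finite(step))) break
    cand <- opt$par - step
    if (!is.finite(fn(cand)) || fn(cand) > opt$value + 1e-8) break
    opt$par <- cand
    opt$value <- fn(cand)
    gnorm <- sqrt(sum(.numGrad(fn, opt$par)^2))
    tries <- tries + 1
  }
  beta <- setNames(opt$par[seq_len(nBeta)], colnames(X))
  if (any(abs(beta) > 10))
    warning("large coefficient(s): a covariate level may be completely ",
            "separated (all-1 or all-0 cells)", call. = FALSE)
  H <- tryCatch(optimHess(opt$par, fn), error = function(e) NULL)
  V <- if (!is.null(H))
    tryCatch(solve(H), error = function(e) matrix(NA_real_, length(opt$par),
                                                  length(opt$par)))
  else matrix(NA_real_, length(opt$par), length(opt$par))
  pnames <- c(colnames(X), if (free) "psi(logit)")
  dimnames(V) <- list(pnames, pnames)
  K <- nBeta + free
  n <- nrow(X)
  ll <- -opt$value
  conv <- opt$convergence == 0 && is.finite(gnorm) && gnorm <= gradTol
  if (!conv)
    warning("fit did not converge (gradient norm ", signif(gnorm, 3), ")",
            call. = FALSE)
  new("OccupancyFit",
      name = if (is.null(name))
        paste0("p(", deparse(spec@pFormula[[2]]), ") psi(",
               if (free) "." else "=1", ")")
      else name,
      beta = beta,
      psi = if (free) plogis(opt$par[nBeta + 1]) else 1,
      vcov = V, loglik = ll, nParams = K, nSites = n,
      aic = -2 * ll + 2 * K, aicc = aicc(ll, K, n),
      converged = conv, spec = spec, xlevels = xlevels,
      sites = rownames(detMatrix(history))[st$keep])
}

#' Rank occupancy models by AICc
#'
#' Orders fits by AICc, computes differences to the top model, Akaike
#' weights \eqn{w_i = \exp(-\Delta_i/2)/\sum_j \exp(-\Delta_j/2)} and
#' cumulative weights, and flags the parsimonious set (\eqn{\Delta} AICc
#' below \code{deltaMax}). The table carries a \code{"null_delta"}
#' attribute (the intercept-only model's delta, NA if absent) so the check
#' that the null model is firmly outranked is one comparison away.
#'
#' @param fits list of \code{\linkS4class{OccupancyFit}} objects on the same
#'   sites.
#' @param deltaMax parsimony threshold on delta-AICc (default 7).
#' @return data.frame with columns \code{model}, \code{nPar}, \code{aicc},
#'   \code{delta}, \code{weight}, \code{cumWeight}, \code{parsimonious},
#'   sorted ascending by AICc.
#' @export
rankModels <- function(fits, deltaMax = 7) {
  if (is(fits, "OccupancyFit")) fits <- list(fits)
  siteSets <- lapply(fits, function(f) sort(f@sites))
  if (length(unique(vapply(siteSets, paste, "", collapse = "|"))) != 1)
    stop("fits were made on differing site sets", call. = FALSE)
  tab <- data.frame(
    model = vapply(fits, function(f) f@name, ""),
    nPar = vapply(fits, function(f) as.integer(f@nParams), 0L),
    aicc = vapply(fits, function(f) f@aicc, 0),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$aicc), ]
  tab$delta <- tab$aicc - tab$aicc[1]
  w <- exp(-tab$delta / 2)
  tab$weight <- w / sum(w)
  tab$cumWeight <- cumsum(tab$weight)
  tab$parsimonious <- tab$delta < deltaMax
  rownames(tab) <- NULL
  isNull <- vapply(fits, function(f)
    length(all.vars(f@spec@pFormula)) == 0, TRUE)
  attr(tab, "null_delta") <- if (any(isNull))
    min(vapply(fits[isNull], function(f) f@aicc, 0)) - tab$aicc[1]
  else NA_real_
  tab
}

#' Back-transformed detection-probability predictions
#'
#' Response-scale estimates \eqn{p = logit^{-1}(x'\beta)} with delta-method
#' standard errors \eqn{SE_p = p(1-p)\sqrt{x' V x}} and logit-scale Wald
#' intervals transformed to the probability scale.
#'
#' @param fit an \code{\linkS4class{OccupancyFit}}.
#' @param newdata data.frame of covariate rows; every factor level must have
#'   been seen at fit time (extrapolated levels error).
#' @param level confidence level for the interval (default 0.95).
#' @return data.frame: \code{newdata} columns plus \code{p}, \code{se},
#'   \code{lower}, \code{upper}.
#' @export
predictP <- function(fit, newdata, level = 0.95) {
  X <- .occuDesign(NULL, fit@spec, newdata = newdata, xlevels = fit@xlevels)
  eta <- drop(X %*% fit@beta)
  Vb <- fit@vcov[seq_along(fit@beta), seq_along(fit@beta), drop = FALSE]
  seEta <- sqrt(pmax(rowSums((X %*% Vb) * X), 0))
  p <- plogis(eta)
  z <- qnorm(1 - (1 - level) / 2)
  out <- cbind(newdata,
               data.frame(p = p, se = p * (1 - p) * seEta,
                          lower = plogis(eta - z * seEta),
                          upper = plogis(eta + z * seEta)))
  rownames(out) <- NULL
  out
}

#' Minimum number of survey occasions for detection
#'
#' The survey effort needed to detect a present species with confidence
#' \eqn{1 - \alpha} given per-occasion detection probability p:
#' \deqn{N_{min} = \log(\alpha) / \log(1 - p),}
#' returned unrounded.
#'
#' @param p per-occasion detection probability, strictly between 0 and 1
#'   (vectorized).
#' @param alpha miss tolerance (default 0.05, i.e. 95\% confidence).
#' @return Numeric vector of occasion counts.
#' @examples
#' nMin(0.648)  # ~2.87 occasions
#' @export
nMin <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("p must lie strictly between 0 and 1", call. = FALSE)
  log(alpha) / log(1 - p)
}
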