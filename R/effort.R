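## Survey-time equalization: subsample continuous sensor records into three
## short occasions (spaced >= 5 days), estimate detectability per window
## length with replicate intervals, locate crossings against a benchmark,
## and test window-length effects by one-way ANOVA.

#' Window-resampling scheme
#'
#' @param windowHours total survey-window length in hours, split into
#'   \code{nOccasions} equal occasions (the design grid runs in 5-h
#'   increments from 5 h up to 24 days = 576 h).
#' @param nOccasions occasions per window (default 3, matching the three
#'   point-transect visits).
#' @param minGapDays minimum spacing between occasions in days (default 5).
#'   Measured end-of-occasion to start-of-next; set
#'   \code{gapFrom = "start"} for start-to-start spacing.
#' @param nReps number of random-selection replicates (default 1000).
#' @param seed RNG seed.
#' @param gapFrom "end" (default) or "start".
#' @return A validated list ("WindowScheme") of the above fields plus
#'   \code{occasionHours}.
#' @export
windowScheme <- function(windowHours, nOccasions = 3, minGapDays = 5,
                         nReps = 1000, seed = NULL,
                         gapFrom = c("end", "start")) {
  gapFrom <- match.arg(gapFrom)
  if (windowHours <= 0) stop("windowHours must be positive", call. = FALSE)
  structure(list(windowHours = windowHours, nOccasions = nOccasions,
                 occasionHours = windowHours / nOccasions,
                 minGapDays = minGapDays, nReps = nReps, seed = seed,
                 gapFrom = gapFrom),
            class = "WindowScheme")
}

## Effective gap between occasion *starts*.
.startGap <- function(scheme) {
  g <- scheme$minGapDays * 24
  if (scheme$gapFrom == "end") g + scheme$occasionHours else g
}

.schemeFeasible <- function(recordHours, scheme) {
  L <- scheme$occasionHours
  n <- scheme$nOccasions
  recordHours - ((n - 1) * .startGap(scheme) + L) >= 0
}

## Uniform draw of ordered occasion start times over the feasible set:
## sorted uniforms on [0, slack] shifted by multiples of the start gap.
## Exactly uniform on the start-time polytope; uses the current RNG stream.
.drawStarts <- function(recordHours, scheme, n = 1) {
  L <- scheme$occasionHours
  sg <- .startGap(scheme)
  k <- scheme$nOccasions
  slack <- recordHours - ((k - 1) * sg + L)
  if (slack < 0) stop("infeasible scheme for this record", call. = FALSE)
  u <- matrix(runif(n * k, 0, slack), n, k)
  u <- t(apply(u, 1, sort))
  if (k == 1) u <- matrix(u, n, 1)
  sweep(u, 2, (seq_len(k) - 1) * sg, `+`)
}

.deriveSeed <- function(seed, ...) {
  ix <- c(...)
  as.integer((seed + sum(ix * 104729^seq_along(ix))) %% 2147483629)
}

#' Draw random survey occasions within a record
#'
#' Selects \code{scheme$nOccasions} disjoint occasion intervals of equal
#' length inside a continuous sensor record, uniformly over all placements
#' that keep consecutive occasions at least \code{minGapDays} apart.
#' Deterministic given (\code{scheme$seed}, \code{rep}).
#'
#' @param recordHours length of the continuous record in hours.
#' @param scheme a \code{\link{windowScheme}}.
#' @param rep replicate index (used with the scheme seed to fix the draw).
#' @return data.frame with columns \code{start}, \code{end} (hours from the
#'   record start), one row per occasion.
#' @export
drawOccasions <- function(recordHours, scheme, rep = 1) {
  if (!.schemeFeasible(recordHours, scheme))
    stop("record too short for this window scheme (need ",
         (scheme$nOccasions - 1) * .startGap(scheme) + scheme$occasionHours,
         " h, have ", recordHours, " h)", call. = FALSE)
  if (!is.null(scheme$seed))
    set.seed(.deriveSeed(scheme$seed, rep))
  s <- drop(.drawStarts(recordHours, scheme, 1))
  out <- data.frame(start = s, end = s + scheme$occasionHours)
  stopifnot(all(diff(out$start) >= .startGap(scheme) - 1e-9))
  out
}

#' Score one subsampled detection history
#'
#' Codes each drawn occasion 1 if at least one detected event falls inside
#' it, else 0.
#'
#' @param events EventTable rows for one site.
#' @param scheme a \code{\link{windowScheme}}.
#' @param rep replicate index.
#' @param recordStart POSIXct origin of the record (default: first event).
#' @param recordHours record length in hours (default: event extent).
#' @return Integer vector of length \code{scheme$nOccasions}.
#' @export
subsampleHistory <- function(events, scheme, rep = 1,
                             recordStart = min(events$timestamp),
                             recordHours = as.numeric(
                               difftime(max(events$timestamp), recordStart,
                                        units = "hours"))) {
  occ <- drawOccasions(recordHours, scheme, rep)
  t <- as.numeric(difftime(events$timestamp[events$detected], recordStart,
                           units = "hours"))
  t <- sort(t)
  as.integer(findInterval(occ$end - 1e-9, t) - findInterval(occ$start, t) > 0)
}

#' Detectability as a function of survey-window length
#'
#' For each window length in \code{grid}, repeatedly (\code{nReps} times)
#' draws three spaced occasions per feasible site, scores detection, and
#' pools the occasion outcomes across sites into one detection estimate per
#' replicate (the intercept-only MLE under occupancy fixed at 1). Sites
#' whose records are too short for a window are excluded from that grid
#' point (their count is reported); grid points with no feasible site are
#' dropped. Bit-reproducible under a fixed seed.
#'
#' @param events EventTable of detected events for a single method.
#' @param grid vector of window lengths in hours (default 5-h increments
#'   from 5 h to 24 days).
#' @param nReps replicates per window (default 1000).
#' @param seed RNG seed (required).
#' @param coverage optional data.frame \code{site_id}, \code{start},
#'   \code{end} giving each record's active span; defaults to each site's
#'   event extent.
#' @param reference optional list \code{mean}, \code{lo}, \code{hi}: the
#'   benchmark detection estimate (e.g. the point-transect occupancy
#'   estimate at its native 5-h survey time).
#' @param nOccasions,minGapDays,gapFrom see \code{\link{windowScheme}}.
#' @return An \code{\linkS4class{EffortCurve}}.
#' @export
effortCurve <- function(events, grid = seq(5, 576, by = 5), nReps = 1000,
                        seed, coverage = NULL, reference = NULL,
                        nOccasions = 3, minGapDays = 5,
                        gapFrom = c("end", "start")) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  gapFrom <- match.arg(gapFrom)
  events <- .validateEvents(events, checkVisit = FALSE)
  if (length(unique(events$method)) > 1)
    stop("effortCurve expects a single method", call. = FALSE)
  if (is.null(coverage)) {
    ids <- unique(events$site_id)
    coverage <- data.frame(
      site_id = ids,
      start = as.POSIXct(vapply(ids, function(s)
        min(as.numeric(events$timestamp[events$site_id == s])), 0),
        tz = "UTC", origin = "1970-01-01"),
      end = as.POSIXct(vapply(ids, function(s)
        max(as.numeric(events$timestamp[events$site_id == s])), 0),
        tz = "UTC", origin = "1970-01-01"))
  }
  coverage$site_id <- as.character(coverage$site_id)
  spans <- as.numeric(difftime(coverage$end, coverage$start,
                               units = "hours"))
  # per-site sorted detected-event times (hours from the record start)
  evHours <- lapply(seq_len(nrow(coverage)), function(i) {
    s <- coverage$site_id[i]
    sel <- events$site_id == s & events$detected
    sort(as.numeric(difftime(events$timestamp[sel], coverage$start[i],
                             units = "hours")))
  })

  rows <- list()
  reps <- list()
  for (wi in seq_along(grid)) {
    sch <- windowScheme(grid[wi], nOccasions = nOccasions,
                        minGapDays = minGapDays, gapFrom = gapFrom)
    feas <- which(vapply(spans, .schemeFeasible, TRUE, scheme = sch))
    if (!length(feas)) next
    det <- matrix(0L, nReps, length(feas))
    for (j in seq_along(feas)) {
      i <- feas[j]
      set.seed(.deriveSeed(seed, wi, i))
      starts <- .drawStarts(spans[i], sch, nReps)     # nReps x nOccasions
      t <- evHours[[i]]
      hits <- matrix(0L, nReps, nOccasions)
      for (k in seq_len(nOccasions)) {
        hits[, k] <- (findInterval(starts[, k] + sch$occasionHours - 1e-9,
                                   t) -
                        findInterval(starts[, k], t)) > 0
      }
      det[, j] <- rowSums(hits)
    }
    est <- rowSums(det) / (length(feas) * nOccasions)
    rows[[length(rows) + 1]] <- data.frame(
      window_hours = grid[wi],
      mean = mean(est),
      lo = unname(quantile(est, 0.025)),
      hi = unname(quantile(est, 0.975)),
      n_sites = length(feas), n_reps = nReps)
    reps[[length(reps) + 1]] <- est
  }
  if (!length(rows))
    stop("no feasible site at any window length", call. = FALSE)
  gridDf <- do.call(rbind, rows)
  repMat <- do.call(cbind, reps)
  colnames(repMat) <- as.character(gridDf$window_hours)
  new("EffortCurve", grid = gridDf, replicates = repMat,
      reference = if (is.null(reference)) list() else reference)
}

#' Survey hours needed to reach a benchmark detectability
#'
#' Linearly interpolates the mean effort curve to find the first window
#' length at which it reaches (a) the benchmark mean and (b) the benchmark
#' upper interval bound. Returns NA for a level never reached on the grid;
#' a level already met at the first grid point returns that grid point.
#'
#' @param curve an \code{\linkS4class{EffortCurve}} (or its grid
#'   data.frame).
#' @param reference list \code{mean}, \code{hi} (upper bound); defaults to
#'   the curve's own stored reference.
#' @return Named numeric vector \code{c(to_mean, to_upper)} in hours.
#' @export
crossingTime <- function(curve, reference = NULL) {
  g <- if (is(curve, "EffortCurve")) curve@grid else curve
  if (is.null(reference))
    reference <- if (is(curve, "EffortCurve")) curve@reference else NULL
  if (is.null(reference) || !length(reference))
    stop("no reference supplied", call. = FALSE)
  cross1 <- function(level) {
    if (is.null(level) || is.na(level)) return(NA_real_)
    i <- which(g$mean >= level)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1) return(g$window_hours[1])
    x0 <- g$window_hours[i - 1]; x1 <- g$window_hours[i]
    y0 <- g$mean[i - 1]; y1 <- g$mean[i]
    x0 + (level - y0) / (y1 - y0) * (x1 - x0)
  }
  c(to_mean = cross1(reference$mean),
    to_upper = cross1(reference$hi))
}

#' Window-length effect on detectability (one-way ANOVA)
#'
#' Fixed-effects one-way analysis of variance of replicate detection
#' estimates with window length as the factor.
#'
#' @param curve an \code{\linkS4class{EffortCurve}}, or a data.frame with
#'   columns \code{window_hours} and \code{estimate}.
#' @return data.frame with \code{F}, \code{df1}, \code{df2}, \code{p}. When
#'   every group is constant (no within-group variance anywhere) the F
#'   statistic is undefined and returned NA with a warning.
#' @export
anovaWindows <- function(curve) {
  d <- if (is(curve, "EffortCurve")) {
    m <- curve@replicates
    data.frame(window_hours = rep(as.numeric(colnames(m)),
                                  each = nrow(m)),
               estimate = as.vector(m))
  } else curve
  if (length(unique(d$window_hours)) < 2)
    stop("need at least two window lengths", call. = FALSE)
  fit <- aov(estimate ~ factor(window_hours), data = d)
  # degenerate (perfect-fit) cases are classified explicitly below
  tab <- withCallingHandlers(anova(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  if (tab[["Sum Sq"]][1] <= 1e-24)      # no between-group signal at all
    return(data.frame(F = 0, df1 = tab$Df[1], df2 = tab$Df[2], p = 1))
  if (tab[["Mean Sq"]][2] <= 1e-12 * tab[["Mean Sq"]][1] ||
      !is.finite(tab[["F value"]][1])) {
    warning("zero within-group variance: F undefined", call. = FALSE)
    return(data.frame(F = NA_real_, df1 = tab$Df[1], df2 = tab$Df[2],
                      p = NA_real_))
  }
  data.frame(F = tab[["F value"]][1], df1 = tab$Df[1], df2 = tab$Df[2],
             p = tab[["Pr(>F)"]][1])
}
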