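## Raw survey events -> occasion-level detection histories.
##
## Conventions: timezone-naive local timestamps (stored as UTC POSIXct so no
## DST arithmetic applies), day boundaries at 00:00, occasion windows half-open
## [t0 + k*D, t0 + (k+1)*D) anchored at each device's own deployment start.

.METHODS <- c("PT", "CT", "PAM")
.HOUR <- 3600
.DAY <- 86400

.parseTimestamp <- function(x) {
  x <- as.character(x)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
                                   "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"),
                    optional = TRUE)
  out
}

.validateEvents <- function(events, checkVisit = TRUE) {
  req <- c("site_id", "method", "timestamp", "detected")
  miss <- setdiff(req, names(events))
  if (length(miss))
    stop("events table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- !events$method %in% .METHODS
  if (any(bad))
    stop("invalid method value(s) ",
         paste(unique(events$method[bad]), collapse = ", "),
         "; allowed values are ", paste(.METHODS, collapse = ", "),
         call. = FALSE)
  if (!inherits(events$timestamp, "POSIXct"))
    stop("timestamp must be POSIXct", call. = FALSE)
  if (!"visit_index" %in% names(events)) events$visit_index <- NA_integer_
  if (checkVisit) {
    pt <- events$method == "PT"
    if (any(pt & is.na(events$visit_index)))
      stop("PT rows must carry a visit_index", call. = FALSE)
    if (any(!pt & !is.na(events$visit_index)))
      stop("visit_index is only valid for PT rows", call. = FALSE)
  }
  events$site_id <- as.character(events$site_id)
  events$detected <- as.logical(events$detected)
  events
}

#' Read a raw survey-event table from CSV
#'
#' Expected columns: \code{site_id}, \code{method} (PT/CT/PAM),
#' \code{timestamp} (ISO-8601, minute resolution, local clock time),
#' \code{detected} (0/1), and \code{visit_index} (point-transect visits only).
#'
#' @param path CSV file path.
#' @param campaignStart,campaignEnd optional POSIXct bounds; rows outside the
#'   campaign window are dropped and reported via the \code{"rejected"}
#'   attribute of the result.
#' @return A validated event data.frame (the package's EventTable) with
#'   columns \code{site_id}, \code{method}, \code{timestamp} (POSIXct),
#'   \code{detected} (logical), \code{visit_index} (integer or NA).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("site_id,method,timestamp,detected,visit_index",
#'              "s1,CT,2022-12-03 06:10:00,1,",
#'              "s1,CT,2022-12-04 17:45:00,1,"), f)
#' ev <- readEvents(f)
#' nrow(ev)
#' @export
readEvents <- function(path, campaignStart = NULL, campaignEnd = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character")
  req <- c("site_id", "method", "timestamp", "detected")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("events CSV is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  ts <- .parseTimestamp(raw$timestamp)
  if (anyNA(ts))
    stop("unparseable timestamp(s) at data row(s): ",
         paste(head(which(is.na(ts)), 20), collapse = ", "), call. = FALSE)
  ev <- data.frame(site_id = raw$site_id,
                   method = raw$method,
                   timestamp = ts,
                   detected = as.integer(raw$detected) > 0,
                   visit_index = if ("visit_index" %in% names(raw))
                     suppressWarnings(as.integer(raw$visit_index))
                   else NA_integer_,
                   stringsAsFactors = FALSE)
  ev <- .validateEvents(ev)
  rejected <- data.frame()
  if (!is.null(campaignStart) || !is.null(campaignEnd)) {
    lo <- if (is.null(campaignStart)) -Inf else as.numeric(campaignStart)
    hi <- if (is.null(campaignEnd)) Inf else as.numeric(campaignEnd)
    out <- as.numeric(ev$timestamp) < lo | as.numeric(ev$timestamp) >= hi
    if (any(out)) {
      rejected <- ev[out, , drop = FALSE]
      warning(sum(out), " event(s) outside the campaign window were dropped",
              call. = FALSE)
      ev <- ev[!out, , drop = FALSE]
      rownames(ev) <- NULL
    }
  }
  attr(ev, "rejected") <- rejected
  ev
}

#' Write an event table to CSV
#'
#' Inverse of \code{\link{readEvents}}: \code{readEvents(writeEvents(ev, f))}
#' reproduces the data fields exactly.
#'
#' @param events EventTable data.frame.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeEvents <- function(events, path) {
  events <- .validateEvents(events)
  out <- data.frame(site_id = events$site_id,
                    method = events$method,
                    timestamp = format(events$timestamp,
                                       "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                    detected = as.integer(events$detected),
                    visit_index = events$visit_index)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a survey-site covariate table from CSV
#'
#' Expected columns: \code{site_id}, \code{location_id} (sampling location),
#' \code{habitat} (forest/open), \code{method}.
#'
#' @param path CSV file path.
#' @return data.frame with one row per survey site.
#' @export
readSites <- function(path) {
  s <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("site_id", "location_id", "habitat", "method")
  miss <- setdiff(req, names(s))
  if (length(miss))
    stop("sites CSV is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- !s$habitat %in% c("forest", "open")
  if (any(bad))
    stop("invalid habitat value(s) ",
         paste(unique(s$habitat[bad]), collapse = ", "),
         "; allowed values are forest, open", call. = FALSE)
  if (anyDuplicated(s$site_id))
    stop("duplicated site_id in sites table", call. = FALSE)
  s$site_id <- as.character(s$site_id)
  s
}

## Overlap in hours between [a1, a2) and [b1, b2), numeric seconds in.
.overlapHours <- function(a1, a2, b1, b2) {
  pmax(0, pmin(a2, b2) - pmax(a1, b1)) / .HOUR
}

.siteCovsFor <- function(siteIds, sites, method) {
  if (!is.null(sites)) {
    idx <- match(siteIds, sites$site_id)
    if (anyNA(idx))
      stop("site(s) absent from the sites table: ",
           paste(siteIds[is.na(idx)], collapse = ", "), call. = FALSE)
    sc <- sites[idx, c("site_id", "location_id", "habitat", "method"),
                drop = FALSE]
  } else {
    sc <- data.frame(site_id = siteIds, method = method,
                     stringsAsFactors = FALSE)
  }
  rownames(sc) <- NULL
  sc
}

#' Build a sensor (camera-trap or PAM) detection history
#'
#' Divides each device's record into consecutive half-open occasion windows
#' of \code{occasionDays} days, anchored at the device's own deployment
#' start. An occasion scores 1 if at least one detected event falls in the
#' window, 0 if the device was active with no detection, and NA if the
#' device had no (or too little) coverage in the window.
#'
#' Partial-coverage occasions (device active for only part of a window, e.g.
#' battery dropout) are scored from the covered part when coverage is at
#' least \code{minCoverage} of the window, otherwise NA.
#'
#' @param events EventTable rows for CT or PAM sites (a single method).
#' @param occasionDays days per survey occasion (default 5).
#' @param nOccasions number of occasions (default 8, i.e. a 40-day record).
#' @param coverage optional data.frame \code{site_id}, \code{start},
#'   \code{end} (POSIXct) giving each device's active span. When absent the
#'   span is inferred from the event record extent and a warning is issued
#'   if the requested occasions overrun it (trailing occasions become NA).
#' @param start optional POSIXct deployment start: a single value or a
#'   vector named by site_id. Defaults to each site's coverage start (or
#'   first event), truncated to 00:00 local.
#' @param sites optional site covariate table (see \code{\link{readSites}}).
#' @param minCoverage minimum covered fraction of a window for it to be
#'   scored rather than set NA (default 0.5).
#' @return A \code{\linkS4class{DetectionHistory}} with \code{nOccasions}
#'   columns.
#' @examples
#' ev <- data.frame(site_id = "s1", method = "CT",
#'                  timestamp = as.POSIXct("2022-12-07 10:00", tz = "UTC"),
#'                  detected = TRUE)
#' cov <- data.frame(site_id = "s1",
#'                   start = as.POSIXct("2022-12-01 00:00", tz = "UTC"),
#'                   end = as.POSIXct("2023-01-10 00:00", tz = "UTC"))
#' detMatrix(buildSensorHistory(ev, coverage = cov))
#' @export
buildSensorHistory <- function(events, occasionDays = 5, nOccasions = 8,
                               coverage = NULL, start = NULL, sites = NULL,
                               minCoverage = 0.5) {
  events <- .validateEvents(events, checkVisit = FALSE)
  meth <- unique(events$method)
  if (!length(meth)) meth <- NA_character_
  if (length(meth) > 1)
    stop("events must be a single method; got ",
         paste(meth, collapse = ", "), call. = FALSE)
  if (!is.na(meth[1]) && !meth %in% c("CT", "PAM"))
    stop("buildSensorHistory handles CT/PAM streams; use ",
         "buildTransectHistory for PT visits", call. = FALSE)
  siteIds <- if (!is.null(coverage)) unique(as.character(coverage$site_id))
             else unique(events$site_id)
  if (!length(siteIds)) stop("no sites to process", call. = FALSE)
  if (is.null(coverage)) {
    ext <- tapply(as.numeric(events$timestamp), events$site_id, range)
    coverage <- data.frame(site_id = names(ext),
                           start = .POSIXct(vapply(ext, `[`, 0, 1), tz = "UTC"),
                           end = .POSIXct(vapply(ext, `[`, 0, 2), tz = "UTC"),
                           stringsAsFactors = FALSE)
    inferred <- TRUE
  } else inferred <- FALSE
  coverage$site_id <- as.character(coverage$site_id)

  D <- occasionDays * .DAY
  y <- matrix(NA_integer_, length(siteIds), nOccasions,
              dimnames = list(siteIds, paste0("occ_", seq_len(nOccasions))))
  overran <- FALSE
  for (s in siteIds) {
    cov <- coverage[coverage$site_id == s, , drop = FALSE]
    c1 <- as.numeric(cov$start); c2 <- as.numeric(cov$end)
    t0 <- if (is.null(start)) {
      trunc(.POSIXct(min(c1), tz = "UTC"), "days")
    } else if (length(start) > 1 || !is.null(names(start))) {
      if (!s %in% names(start))
        stop("no start given for site ", s, call. = FALSE)
      start[[s]]
    } else start
    t0 <- as.numeric(t0)
    ts <- as.numeric(events$timestamp[events$site_id == s & events$detected])
    for (k in seq_len(nOccasions)) {
      w1 <- t0 + (k - 1) * D
      w2 <- t0 + k * D
      covered <- sum(.overlapHours(w1, w2, c1, c2))
      if (covered <= 0 || covered / (D / .HOUR) < minCoverage) {
        if (inferred && w2 > max(c2)) overran <- TRUE
        next                         # stays NA
      }
      y[s, k] <- as.integer(any(ts >= w1 & ts < w2))
    }
  }
  if (overran)
    warning("requested occasions overrun the event record and no coverage ",
            "metadata was given; trailing occasions set NA", call. = FALSE)
  DetectionHistory(y, .siteCovsFor(siteIds, sites, meth))
}

#' Build a point-transect detection history
#'
#' One column per visit; a cell is the visit's detected flag and a missing
#' visit is NA. A transect scores a detection when the species was seen or
#' heard at any of its sampling points during the visit (between-point
#' detections are excluded upstream, at data entry).
#'
#' @param visits EventTable rows with method PT, one row per visit, carrying
#'   \code{visit_index} and \code{detected}.
#' @param nVisits number of planned visits (default 3).
#' @param sites optional site covariate table.
#' @param minGapDays visits closer together than this trigger a validation
#'   warning (default 5, the design's minimum revisit spacing).
#' @return A \code{\linkS4class{DetectionHistory}} with \code{nVisits}
#'   columns.
#' @export
buildTransectHistory <- function(visits, nVisits = 3, sites = NULL,
                                 minGapDays = 5) {
  visits <- .validateEvents(visits)
  if (nrow(visits) == 0) stop("no visit records", call. = FALSE)
  if (any(visits$method != "PT"))
    stop("buildTransectHistory expects PT visit records only", call. = FALSE)
  siteIds <- unique(visits$site_id)
  y <- matrix(NA_integer_, length(siteIds), nVisits,
              dimnames = list(siteIds, paste0("visit_", seq_len(nVisits))))
  for (s in siteIds) {
    v <- visits[visits$site_id == s, , drop = FALSE]
    if (nrow(v) > nVisits)
      stop("site ", s, " has more than ", nVisits, " visits", call. = FALSE)
    if (anyDuplicated(v$visit_index))
      stop("site ", s, " has duplicated visit_index", call. = FALSE)
    if (any(v$visit_index > nVisits))
      stop("site ", s, " has visit_index above nVisits", call. = FALSE)
    gaps <- diff(sort(floor(as.numeric(v$timestamp) / .DAY)))
    if (length(gaps) && any(gaps < minGapDays))
      warning("site ", s, ": consecutive visits fewer than ", minGapDays,
              " days apart", call. = FALSE)
    y[s, v$visit_index] <- as.integer(v$detected)
  }
  DetectionHistory(y, .siteCovsFor(siteIds, sites, "PT"))
}

#' Re-express point-transect visits on a sensor occasion grid
#'
#' Maps visits onto consecutive \code{occasionDays}-day windows by date so a
#' transect history can be fused with camera-trap/PAM histories occasion by
#' occasion: a window scores 1 if a detected visit falls in it, 0 if a visit
#' occurred without detection, NA if it holds no visit.
#'
#' @param visits EventTable rows with method PT.
#' @param start POSIXct campaign/deployment start anchoring the windows
#'   (single value or named by site_id).
#' @inheritParams buildSensorHistory
#' @return A \code{\linkS4class{DetectionHistory}} with \code{nOccasions}
#'   columns.
#' @export
alignTransectToOccasions <- function(visits, start, occasionDays = 5,
                                     nOccasions = 8, sites = NULL) {
  visits <- .validateEvents(visits)
  if (any(visits$method != "PT"))
    stop("expects PT visit records only", call. = FALSE)
  siteIds <- unique(visits$site_id)
  D <- occasionDays * .DAY
  y <- matrix(NA_integer_, length(siteIds), nOccasions,
              dimnames = list(siteIds, paste0("occ_", seq_len(nOccasions))))
  for (s in siteIds) {
    t0 <- if (length(start) > 1 || !is.null(names(start))) {
      if (!s %in% names(start)) stop("no start for site ", s, call. = FALSE)
      as.numeric(start[[s]])
    } else as.numeric(start)
    v <- visits[visits$site_id == s, , drop = FALSE]
    k <- floor((as.numeric(v$timestamp) - t0) / D) + 1
    keep <- k >= 1 & k <= nOccasions
    for (i in which(keep))
      y[s, k[i]] <- max(y[s, k[i]], as.integer(v$detected[i]), na.rm = TRUE)
  }
  DetectionHistory(y, .siteCovsFor(siteIds, sites, "PT"))
}

.canonicalLabel <- function(methods) {
  parts <- unique(unlist(strsplit(methods, "+", fixed = TRUE)))
  paste(parts[order(match(parts, c("CT", "PAM", "PT")))], collapse = "+")
}

#' Fuse detection histories across survey methods
#'
#' Combines per-method histories for the same sampling points into a
#' multi-method history: an occasion scores detected when at least one
#' method detected the species. Cells combine by OR with NA absorption
#' (1 if any input is 1; 0 if at least one input is 0 and none is 1; NA only
#' when every input is NA). Sites are matched exactly on
#' (\code{location_id}, \code{habitat}); only points surveyed by all input
#' methods are kept.
#'
#' @param histories list of \code{\linkS4class{DetectionHistory}} objects on
#'   the same occasion grid, each with \code{location_id} and \code{habitat}
#'   site covariates.
#' @param label method-combination label for the fused sites; default joins
#'   the input method labels (e.g. "CT+PAM").
#' @return A fused \code{\linkS4class{DetectionHistory}}; a single input
#'   history is returned unchanged.
#' @export
fuseHistories <- function(histories, label = NULL) {
  if (is(histories, "DetectionHistory")) histories <- list(histories)
  if (length(histories) == 1) return(histories[[1]])
  K <- vapply(histories, nOccasions, 0L)
  if (length(unique(K)) != 1)
    stop("histories must share the same occasion grid; occasion counts: ",
         paste(K, collapse = ", "), call. = FALSE)
  keys <- lapply(histories, function(h) {
    sc <- siteCovs(h)
    if (!all(c("location_id", "habitat") %in% names(sc)))
      stop("fusion requires location_id and habitat site covariates",
           call. = FALSE)
    paste(sc$location_id, sc$habitat, sep = "||")
  })
  shared <- Reduce(intersect, keys)
  if (!length(shared))
    stop("no overlapping (location_id, habitat) sites to fuse",
         call. = FALSE)
  if (is.null(label))
    label <- .canonicalLabel(unlist(lapply(histories,
                                           function(h) siteCovs(h)$method)))
  stacks <- lapply(seq_along(histories), function(i) {
    detMatrix(histories[[i]])[match(shared, keys[[i]]), , drop = FALSE]
  })
  any1 <- Reduce(`+`, lapply(stacks, function(m) !is.na(m) & m == 1L)) > 0
  allNA <- Reduce(`+`, lapply(stacks, is.na)) == length(stacks)
  y <- matrix(0L, length(shared), K[1])
  y[any1] <- 1L
  y[allNA] <- NA_integer_
  colnames(y) <- colnames(stacks[[1]])
  parts <- strsplit(shared, "||", fixed = TRUE)
  sc <- data.frame(site_id = paste(vapply(parts, `[`, "", 1),
                                   vapply(parts, `[`, "", 2),
                                   gsub("\\+", "", label), sep = "_"),
                   location_id = vapply(parts, `[`, "", 1),
                   habitat = vapply(parts, `[`, "", 2),
                   method = label, stringsAsFactors = FALSE)
  DetectionHistory(y, sc)
}

#' Stack detection histories into one multi-method dataset
#'
#' Row-binds histories (padding shorter ones with trailing NA occasions) so
#' single-method and fused-method sites enter one occupancy fit, as in a
#' stacked multi-method design. When fused rows reuse sampling points that
#' also appear as single-method rows the stacked data are pseudo-replicated;
#' a warning says so.
#'
#' @param histories list of \code{\linkS4class{DetectionHistory}} objects.
#' @return A single \code{\linkS4class{DetectionHistory}}.
#' @export
stackHistories <- function(histories) {
  K <- max(vapply(histories, nOccasions, 0L))
  ys <- lapply(histories, function(h) {
    y <- detMatrix(h)
    if (ncol(y) < K)
      y <- cbind(y, matrix(NA_integer_, nrow(y), K - ncol(y)))
    colnames(y) <- paste0("occ_", seq_len(K))
    y
  })
  scs <- lapply(histories, siteCovs)
  cols <- Reduce(intersect, lapply(scs, names))
  sc <- do.call(rbind, lapply(scs, `[`, cols))
  if (all(c("location_id", "method") %in% names(sc))) {
    fused <- grepl("+", sc$method, fixed = TRUE)
    if (any(fused) &&
        length(intersect(sc$location_id[fused], sc$location_id[!fused])))
      warning("fused rows share sampling locations with single-method rows: ",
              "the stacked design is pseudo-replicated", call. = FALSE)
  }
  if (anyDuplicated(sc$site_id))
    stop("duplicated site_id across stacked histories", call. = FALSE)
  DetectionHistory(do.call(rbind, ys), sc)
}

#' Naive detection summaries
#'
#' Raw (detection-uncorrected) tallies from one or more histories:
#' occasion-level detection rates by method and habitat, site-level
#' detection by habitat, latency to first detection per method, and pairwise
#' same-occasion overlap between methods on shared sampling points.
#'
#' Latency counts surveyed (non-NA) occasions until the first detection,
#' over sites with at least one detection. Empty strata are reported with
#' zero counts and an NA rate.
#'
#' @param histories a \code{\linkS4class{DetectionHistory}} or list of them
#'   (one per method), each with habitat covariates for stratified rates.
#' @return list with data.frames \code{rates} (method x habitat:
#'   detected/total cells and rate), \code{siteRates} (habitat: sites with
#'   any detection), \code{latency} (method: mean/min/max), and
#'   \code{overlap} (method pairs: both, only_a, only_b counts on shared
#'   location-habitat-occasions).
#' @export
naiveSummary <- function(histories) {
  if (is(histories, "DetectionHistory")) histories <- list(histories)
  if (!length(histories)) stop("no histories", call. = FALSE)

  cells <- do.call(rbind, lapply(histories, function(h) {
    y <- detMatrix(h); sc <- siteCovs(h)
    data.frame(method = rep(sc$method, ncol(y)),
               habitat = if ("habitat" %in% names(sc))
                 rep(sc$habitat, ncol(y)) else NA_character_,
               value = as.vector(y), stringsAsFactors = FALSE)
  }))
  ok <- !is.na(cells$value)
  rates <- aggregate(cbind(detected = value, total = 1L) ~ method + habitat,
                     data = cells[ok, ], FUN = sum, na.action = NULL)
  rates$rate <- ifelse(rates$total > 0, rates$detected / rates$total, NA)

  siteTab <- do.call(rbind, lapply(histories, function(h) {
    y <- detMatrix(h); sc <- siteCovs(h)
    data.frame(habitat = if ("habitat" %in% names(sc)) sc$habitat
               else NA_character_,
               det = rowSums(y == 1L, na.rm = TRUE) > 0)
  }))
  siteRates <- aggregate(cbind(detected_sites = det, total_sites = 1L) ~
                           habitat, data = siteTab, FUN = sum,
                         na.action = NULL)

  latency <- do.call(rbind, lapply(histories, function(h) {
    y <- detMatrix(h); sc <- siteCovs(h)
    lat <- apply(y, 1, function(r) {
      r <- r[!is.na(r)]
      if (!any(r == 1L)) return(NA_real_)
      which(r == 1L)[1]
    })
    lat <- lat[!is.na(lat)]
    data.frame(method = sc$method[1],
               mean = if (length(lat)) mean(lat) else NA_real_,
               min = if (length(lat)) min(lat) else NA_real_,
               max = if (length(lat)) max(lat) else NA_real_)
  }))

  overlap <- NULL
  n <- length(histories)
  if (n >= 2) {
    keyed <- lapply(histories, function(h) {
      sc <- siteCovs(h)
      if (!all(c("location_id", "habitat") %in% names(sc))) return(NULL)
      y <- detMatrix(h)
      key <- outer(paste(sc$location_id, sc$habitat, sep = "||"),
                   seq_len(ncol(y)), paste, sep = "@")
      setNames(as.vector(y), as.vector(key))
    })
    pairs <- list()
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      a <- keyed[[i]]; b <- keyed[[j]]
      if (is.null(a) || is.null(b)) next
      shared <- intersect(names(a), names(b))
      av <- a[shared]; bv <- b[shared]
      ok2 <- !is.na(av) & !is.na(bv)
      pairs[[length(pairs) + 1]] <- data.frame(
        method_a = siteCovs(histories[[i]])$method[1],
        method_b = siteCovs(histories[[j]])$method[1],
        both = sum(av[ok2] == 1 & bv[ok2] == 1),
        only_a = sum(av[ok2] == 1 & bv[ok2] == 0),
        only_b = sum(av[ok2] == 0 & bv[ok2] == 1),
        neither = sum(av[ok2] == 0 & bv[ok2] == 0))
    }
    if (length(pairs)) overlap <- do.call(rbind, pairs)
  }
  list(rates = rates, siteRates = siteRates, latency = latency,
       overlap = overlap)
}

#' Hour-of-day profile of detected events
#'
#' Tallies detected events into 24 hour-of-day bins per method (and habitat,
#' when a sites table is supplied): the diel activity fingerprint each
#' sensor sees.
#'
#' @param events EventTable; only rows with \code{detected == TRUE} are
#'   counted.
#' @param sites optional site covariate table used to attach habitat.
#' @return data.frame with columns \code{method}, (\code{habitat}),
#'   \code{hour} (0-23, all present), \code{count}; counts sum to the number
#'   of detected events.
#' @export
hourlyProfile <- function(events, sites = NULL) {
  events <- .validateEvents(events, checkVisit = FALSE)
  ev <- events[events$detected, , drop = FALSE]
  hr <- as.integer(format(ev$timestamp, "%H", tz = "UTC"))
  strata <- if (!is.null(sites)) {
    hab <- sites$habitat[match(ev$site_id, sites$site_id)]
    data.frame(method = ev$method, habitat = hab, stringsAsFactors = FALSE)
  } else data.frame(method = ev$method, stringsAsFactors = FALSE)
  groups <- unique(strata)
  if (!nrow(groups)) {
    # empty input: one all-zero histogram per method present in the table
    groups <- data.frame(method = if (nrow(events)) unique(events$method)
                         else .METHODS, stringsAsFactors = FALSE)
    if (!is.null(sites)) groups$habitat <- NA_character_
  }
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    sel <- rep(TRUE, nrow(strata))
    for (cn in names(groups)) sel <- sel & strata[[cn]] == groups[[cn]][g]
    counts <- tabulate(hr[sel] + 1L, nbins = 24)
    cbind(groups[rep(g, 24), , drop = FALSE],
          data.frame(hour = 0:23, count = counts))
  }))
  rownames(out) <- NULL
  out
}

#' Write / read a detection history as CSV
#'
#' One row per site: the site covariates followed by \code{occ_1..occ_K}
#' cells coded 1/0/NA (empty).
#'
#' @param history a \code{\linkS4class{DetectionHistory}}.
#' @param path CSV path.
#' @return \code{writeHistory}: \code{path} invisibly; \code{readHistory}:
#'   the \code{\linkS4class{DetectionHistory}}.
#' @export
writeHistory <- function(history, path) {
  y <- detMatrix(history)
  colnames(y) <- paste0("occ_", seq_len(ncol(y)))
  write.csv(cbind(siteCovs(history), as.data.frame(y)), path,
            row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeHistory
#' @export
readHistory <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  occ <- grep("^occ_", names(d), value = TRUE)
  occ <- occ[order(as.integer(sub("^occ_", "", occ)))]
  if (!length(occ)) stop("no occ_* columns in history CSV", call. = FALSE)
  y <- as.matrix(d[occ])
  DetectionHistory(y, d[setdiff(names(d), occ)])
}
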