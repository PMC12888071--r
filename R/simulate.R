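## Synthetic multi-method survey campaigns with known ground truth.
##
## Detected events only are generated (the occupancy framework assumes no
## false positives; a false-positive hook exists but defaults to 0). Sensor
## streams are inhomogeneous Poisson in clock time with a 24-bin diel
## weight; point transects are scheduled Bernoulli visits.

#' Diel activity profiles per method
#'
#' Piecewise-constant 24-bin relative activity weights: the acoustic stream
#' peaks at dawn and dusk (loud-call bouts, 05-07 and 17-19 h), cameras
#' record from first light until early night (05-20 h), and point-transect
#' detections concentrate in the early morning (06-09 h). Weights are
#' relative; generators renormalize them so the occasion-level detection
#' target is preserved.
#'
#' @return Named list of numeric 24-vectors (hour bins 0-23) for PT, CT,
#'   PAM.
#' @export
dielProfiles <- function() {
  pam <- rep(0.1, 24)
  pam[(7:17) + 1] <- 1
  pam[c(5, 6, 17, 18) + 1] <- 4
  pam[19 + 1] <- 1
  ct <- rep(0, 24)
  ct[(5:19) + 1] <- 1
  pt <- rep(0, 24)
  pt[(6:8) + 1] <- 3
  pt[(9:17) + 1] <- 1
  list(PT = pt, CT = ct, PAM = pam)
}

#' Hourly event rate matching an occasion-level detection target
#'
#' Inverts the thinned-Poisson relation: with diel weights normalized to
#' mean 1 over the day, the base hourly rate \eqn{\lambda} satisfying
#' \eqn{1 - \exp(-\lambda W) = p} over one occasion, where W is the
#' profile-weighted hour total of the occasion (equal to the occasion's
#' length in hours when it spans whole days).
#'
#' @param pTarget per-occasion detection probability, in (0, 1).
#' @param occasionHours occasion length in hours (default 120 = 5 days).
#' @param dielProfile optional 24-vector of relative weights (flat when
#'   NULL).
#' @return Base hourly rate lambda.
#' @examples
#' rateFromOccasionP(0.5, 120)  # log(2)/120
#' @export
rateFromOccasionP <- function(pTarget, occasionHours = 120,
                              dielProfile = NULL) {
  if (pTarget <= 0 || pTarget >= 1)
    stop("pTarget must lie strictly in (0, 1)", call. = FALSE)
  if (is.null(dielProfile)) {
    W <- occasionHours
  } else {
    w <- 24 * dielProfile / sum(dielProfile)      # mean-1 normalization
    full <- floor(occasionHours / 24)
    rest <- occasionHours - 24 * full
    W <- full * 24 + sum(w[seq_len(floor(rest))]) +
      (rest %% 1) * if (rest %% 1 > 0) w[floor(rest) + 1] else 0
  }
  -log(1 - pTarget) / W
}

#' Default simulation scenario (the study's design constants)
#'
#' Ten 2-km2 sampling locations, each with a forest and an open survey
#' point; all sites occupied (psi = 1). Point transects: 20 sites, 3 visits
#' at least 5 days apart within 06:00-18:00. Camera traps: 19 sites (one
#' open site unequipped), continuous 40-day records, 8 five-day occasions.
#' PAM: 7 recorders (5 forest, 2 open), 3 deployed for 40 days and 4 for 15
#' days, with battery dropout truncating active spans to 24-40 and 5-11
#' days respectively. Per-occasion detection targets: 0.33 (PT), 0.65 (CT),
#' 0.79 (PAM).
#'
#' @return Scenario list consumed by \code{\link{simulateCampaign}}.
#' @export
scenarioDefaults <- function() {
  locs <- sprintf("L%02d", 1:10)
  pam <- data.frame(
    location_id = c("L01", "L02", "L03", "L04", "L06", "L01", "L02"),
    habitat = c(rep("forest", 5), "open", "open"),
    deploy_days = c(40, 40, 40, 15, 15, 15, 15),
    stringsAsFactors = FALSE)
  list(
    locations = locs,
    habitats = c("forest", "open"),
    psi = 1,
    pTargets = c(PT = 0.33, CT = 0.65, PAM = 0.79),
    dielProfiles = dielProfiles(),
    campaignDays = 40,
    occasionDays = 5,
    nOccasions = 8,
    ptVisits = 3,
    ptWindowHours = c(6, 18),
    minVisitGapDays = 5,
    ctMissing = data.frame(location_id = "L10", habitat = "open",
                           stringsAsFactors = FALSE),
    pamUnits = pam,
    dropoutRange = list(long = c(24, 40), short = c(5, 11)),
    falsePositiveRate = 0,
    startDate = as.POSIXct("2022-12-01 00:00:00", tz = "UTC"))
}

.poissonEvents <- function(lambda, weights24, startTime, activeHours) {
  ## hourly thinned sampling over the active span; minute resolution
  hrs <- seq_len(ceiling(activeHours)) - 1
  rate <- lambda * weights24[(hrs %% 24) + 1]
  n <- rpois(length(hrs), rate)
  if (!sum(n)) return(as.POSIXct(numeric(0), tz = "UTC",
                                 origin = "1970-01-01"))
  offs <- rep(hrs, n) + runif(sum(n))
  offs <- offs[offs <= activeHours]
  times <- startTime + round(offs * 3600 / 60) * 60
  sort(times)
}

#' Simulate a multi-method survey campaign
#'
#' Generates site layouts, detected-event streams and point-transect visit
#' records under a known scenario. Occupancy states z are drawn per
#' (location, habitat) sampling point and shared by all devices there, so
#' fused histories have a coherent truth. Occupied sensor sites emit
#' inhomogeneous-Poisson detected events at the rate implied by the
#' occasion-level detection target and the method's diel profile; ARU
#' dropout truncates the record tail. Point-transect visits are scheduled
#' uniformly among day triples at least 5 days apart, at profile-weighted
#' morning-biased hours, each a Bernoulli detection. Deterministic under
#' \code{seed}.
#'
#' @param scenario a scenario list (see \code{\link{scenarioDefaults}}).
#' @param seed RNG seed (required).
#' @return list with \code{events} (EventTable), \code{sites} (site
#'   covariate table), \code{coverage} (per sensor site active span),
#'   \code{truth} (per site: occupancy state z, hourly rate lambda, implied
#'   per-occasion p), \code{scenario}, \code{seed}.
#' @export
simulateCampaign <- function(scenario = scenarioDefaults(), seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  set.seed(seed)
  sc <- scenario
  t0 <- sc$startDate
  occH <- sc$occasionDays * 24

  pts <- expand.grid(location_id = sc$locations, habitat = sc$habitats,
                     stringsAsFactors = FALSE)
  pts <- pts[order(pts$location_id, pts$habitat), ]
  pts$z <- rbinom(nrow(pts), 1, sc$psi)
  zOf <- function(loc, hab)
    pts$z[pts$location_id == loc & pts$habitat == hab]

  sites <- list(); events <- list(); coverage <- list(); truth <- list()
  addSite <- function(loc, hab, method) {
    id <- paste(loc, hab, method, sep = "_")
    sites[[length(sites) + 1]] <<- data.frame(
      site_id = id, location_id = loc, habitat = hab, method = method,
      stringsAsFactors = FALSE)
    id
  }

  ## --- camera traps: continuous records over the whole campaign
  ct <- pts
  if (!is.null(sc$ctMissing) && nrow(sc$ctMissing))
    ct <- ct[!(paste(ct$location_id, ct$habitat) %in%
                 paste(sc$ctMissing$location_id, sc$ctMissing$habitat)), ]
  lamCT <- rateFromOccasionP(sc$pTargets[["CT"]], occH,
                             sc$dielProfiles$CT)
  wCT <- 24 * sc$dielProfiles$CT / sum(sc$dielProfiles$CT)
  for (i in seq_len(nrow(ct))) {
    id <- addSite(ct$location_id[i], ct$habitat[i], "CT")
    hours <- sc$campaignDays * 24
    coverage[[length(coverage) + 1]] <- data.frame(
      site_id = id, start = t0, end = t0 + hours * 3600)
    z <- ct$z[i]
    truth[[length(truth) + 1]] <- data.frame(
      site_id = id, method = "CT", z = z, lambda = lamCT,
      p_occasion = sc$pTargets[["CT"]])
    if (z == 1) {
      tt <- .poissonEvents(lamCT, wCT, t0, hours)
      if (length(tt))
        events[[length(events) + 1]] <- data.frame(
          site_id = id, method = "CT", timestamp = tt, detected = TRUE,
          visit_index = NA_integer_, stringsAsFactors = FALSE)
    }
  }

  ## --- PAM: staggered deployments with battery dropout at the tail
  lamPAM <- rateFromOccasionP(sc$pTargets[["PAM"]], occH,
                              sc$dielProfiles$PAM)
  wPAM <- 24 * sc$dielProfiles$PAM / sum(sc$dielProfiles$PAM)
  pu <- sc$pamUnits
  for (i in seq_len(nrow(pu))) {
    id <- addSite(pu$location_id[i], pu$habitat[i], "PAM")
    rng <- if (pu$deploy_days[i] >= 40) sc$dropoutRange$long
           else sc$dropoutRange$short
    activeDays <- rng[1] + sample.int(rng[2] - rng[1] + 1, 1) - 1
    depStart <- t0 + (sc$campaignDays - pu$deploy_days[i]) * 86400
    coverage[[length(coverage) + 1]] <- data.frame(
      site_id = id, start = depStart,
      end = depStart + activeDays * 86400)
    z <- zOf(pu$location_id[i], pu$habitat[i])
    truth[[length(truth) + 1]] <- data.frame(
      site_id = id, method = "PAM", z = z, lambda = lamPAM,
      p_occasion = sc$pTargets[["PAM"]])
    if (z == 1) {
      tt <- .poissonEvents(lamPAM, wPAM, depStart, activeDays * 24)
      if (length(tt))
        events[[length(events) + 1]] <- data.frame(
          site_id = id, method = "PAM", timestamp = tt, detected = TRUE,
          visit_index = NA_integer_, stringsAsFactors = FALSE)
    }
  }

  ## --- point transects: three visits >= minGap days apart, 06:00-18:00
  gap <- sc$minVisitGapDays
  lastFeasible <- sc$campaignDays - (sc$ptVisits - 1) * gap
  if (lastFeasible < 1)
    stop("campaign too short to schedule ", sc$ptVisits,
         " visits ", gap, " days apart", call. = FALSE)
  wPT <- sc$dielProfiles$PT
  hrsPT <- sc$ptWindowHours[1]:(sc$ptWindowHours[2] - 1)
  wVisit <- wPT[hrsPT + 1]
  if (sum(wVisit) <= 0) wVisit <- rep(1, length(hrsPT))
  for (i in seq_len(nrow(pts))) {
    id <- addSite(pts$location_id[i], pts$habitat[i], "PT")
    days <- sort(sample.int(lastFeasible, sc$ptVisits, replace = TRUE)) +
      gap * (seq_len(sc$ptVisits) - 1)
    hrs <- sample(hrsPT, sc$ptVisits, replace = TRUE,
                  prob = wVisit)
    mins <- sample.int(60, sc$ptVisits, replace = TRUE) - 1
    det <- rbinom(sc$ptVisits, 1, sc$pTargets[["PT"]] * pts$z[i]) == 1
    truth[[length(truth) + 1]] <- data.frame(
      site_id = id, method = "PT", z = pts$z[i], lambda = NA_real_,
      p_occasion = sc$pTargets[["PT"]])
    events[[length(events) + 1]] <- data.frame(
      site_id = id, method = "PT",
      timestamp = t0 + ((days - 1) * 24 + hrs) * 3600 + mins * 60,
      detected = det, visit_index = seq_len(sc$ptVisits),
      stringsAsFactors = FALSE)
  }

  ev <- do.call(rbind, events)
  ev <- ev[order(ev$site_id, ev$timestamp), ]
  rownames(ev) <- NULL
  list(events = .validateEvents(ev),
       sites = do.call(rbind, sites),
       coverage = do.call(rbind, coverage),
       truth = do.call(rbind, truth),
       scenario = sc, seed = seed)
}
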