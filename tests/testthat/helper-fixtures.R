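# Small fixture builders used across the suite.

# A DetectionHistory from an explicit matrix.
mkHistory <- function(y, method = "CT", habitat = NULL, location = NULL,
                      prefix = "s") {
  y <- rbind(y)
  n <- nrow(y)
  sc <- data.frame(site_id = paste0(prefix, seq_len(n)),
                   method = rep_len(method, n),
                   stringsAsFactors = FALSE)
  if (!is.null(habitat)) sc$habitat <- rep_len(habitat, n)
  if (!is.null(location)) sc$location_id <- rep_len(location, n)
  DetectionHistory(y, sc)
}

# A history whose pooled cells are exactly `ones` detections in `total`
# non-NA cells (single site stretched over `total` occasions).
mkCountHistory <- function(ones, total, method = "CT", habitat = "forest") {
  y <- matrix(c(rep(1L, ones), rep(0L, total - ones)), nrow = 1)
  mkHistory(y, method = method, habitat = habitat)
}

# Homogeneous-Poisson detected-event table: `nSites` independent records of
# `days` days at `lambda` events/hour, method CT. Deterministic under the
# caller's RNG state.
poissonEventTable <- function(nSites, days, lambda,
                              t0 = as.POSIXct("2022-12-01 00:00:00",
                                              tz = "UTC")) {
  rows <- lapply(seq_len(nSites), function(i) {
    n <- stats::rpois(1, lambda * days * 24)
    if (n == 0) return(NULL)
    data.frame(site_id = sprintf("p%03d", i), method = "CT",
               timestamp = t0 + sort(stats::runif(n, 0, days * 86400)),
               detected = TRUE, visit_index = NA_integer_)
  })
  ev <- do.call(rbind, rows)
  cov <- data.frame(site_id = sprintf("p%03d", seq_len(nSites)),
                    start = t0, end = t0 + days * 86400)
  list(events = ev, coverage = cov)
}

# A balanced-methods simulation scenario with nLoc locations (2 habitats
# each) per method, full-length PAM deployments, used by recovery studies.
bigScenario <- function(nLoc = 33, pamDropout = c(40, 40)) {
  sc <- scenarioDefaults()
  sc$locations <- sprintf("L%03d", seq_len(nLoc))
  grid <- expand.grid(location_id = sc$locations,
                      habitat = c("forest", "open"),
                      stringsAsFactors = FALSE)
  sc$ctMissing <- NULL
  sc$pamUnits <- data.frame(grid, deploy_days = 40)
  sc$dropoutRange <- list(long = pamDropout, short = pamDropout)
  sc
}

# Flat-diel variant so event streams are homogeneous Poisson in clock time.
flatDielScenario <- function(nLoc = 33) {
  sc <- bigScenario(nLoc, pamDropout = c(40, 40))
  sc$dielProfiles <- list(PT = rep(1, 24), CT = rep(1, 24),
                          PAM = rep(1, 24))
  sc
}
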