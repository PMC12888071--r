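t0 <- as.POSIXct("2022-12-01 00:00:00", tz = "UTC")

test_that("event CSV I/O round-trips and validates", {
  f <- tempfile(fileext = ".csv")
  ev <- data.frame(site_id = c("a", "a", "b"),
                   method = c("CT", "CT", "PT"),
                   timestamp = t0 + c(3600, 7200, 10 * 3600),
                   detected = c(TRUE, FALSE, TRUE),
                   visit_index = c(NA, NA, 1L))
  writeEvents(ev, f)
  back <- readEvents(f)
  expect_equal(nrow(back), 3)
  expect_equal(back$site_id, ev$site_id)
  expect_equal(back$timestamp, ev$timestamp)
  expect_equal(back$detected, ev$detected)
  expect_equal(back$visit_index, ev$visit_index)
  # a second write of the re-read data is byte-identical
  f2 <- tempfile(fileext = ".csv")
  writeEvents(back, f2)
  expect_identical(readLines(f), readLines(f2))

  bad <- tempfile(fileext = ".csv")
  writeLines(c("site_id,method,timestamp,detected",
               "a,CAM,2022-12-01 01:00:00,1"), bad)
  expect_error(readEvents(bad), "PT, CT, PAM")

  writeLines(c("site_id,method,timestamp,detected",
               "a,CT,not-a-time,1"), bad)
  expect_error(readEvents(bad), "unparseable")

  writeLines(c("site_id,timestamp,detected", "a,2022-12-01 01:00:00,1"),
             bad)
  expect_error(readEvents(bad), "method")
})

test_that("events outside the campaign window are rejected with a report", {
  f <- tempfile(fileext = ".csv")
  ev <- data.frame(site_id = "a", method = "CT",
                   timestamp = t0 + c(-86400, 3600),
                   detected = TRUE, visit_index = NA_integer_)
  writeEvents(ev, f)
  expect_warning(kept <- readEvents(f, campaignStart = t0), "dropped")
  expect_equal(nrow(kept), 1)
  expect_equal(nrow(attr(kept, "rejected")), 1)
})

test_that("sensor history windows events into 5-day occasions", {
  cov <- data.frame(site_id = "s1", start = t0, end = t0 + 40 * 86400)
  ev <- data.frame(site_id = "s1", method = "CT",
                   timestamp = t0 + 6.5 * 86400,   # day 7 of the record
                   detected = TRUE, visit_index = NA_integer_)
  h <- buildSensorHistory(ev, coverage = cov)
  expect_equal(unname(detMatrix(h)[1, ]), c(0, 1, 0, 0, 0, 0, 0, 0))

  # no events but full coverage: an all-zero row
  h0 <- buildSensorHistory(ev[0, ], coverage = cov)
  expect_equal(unname(detMatrix(h0)[1, ]), rep(0, 8))
})

test_that("partial-coverage occasions follow the 50% rule", {
  # ARU active days 1-11 only (battery dropout), one call on day 2
  cov <- data.frame(site_id = "s1", start = t0, end = t0 + 11 * 86400)
  ev <- data.frame(site_id = "s1", method = "PAM",
                   timestamp = t0 + 1.5 * 86400,
                   detected = TRUE, visit_index = NA_integer_)
  h <- buildSensorHistory(ev, coverage = cov)
  # occ 3 covers days 11-15: only 1/5 covered -> NA; occ 1 detected,
  # occ 2 active without detection
  expect_equal(unname(detMatrix(h)[1, ]),
               c(1, 0, NA, NA, NA, NA, NA, NA))
  # a laxer threshold scores occasion 3 from its covered day
  h2 <- buildSensorHistory(ev, coverage = cov, minCoverage = 0.2)
  expect_equal(unname(detMatrix(h2)[1, 3]), 0)
})

test_that("sensor history is invariant under time translation", {
  set.seed(42)
  ev <- data.frame(site_id = "s1", method = "CT",
                   timestamp = t0 + sort(runif(30, 0, 40 * 86400)),
                   detected = TRUE, visit_index = NA_integer_)
  cov <- data.frame(site_id = "s1", start = t0, end = t0 + 40 * 86400)
  h1 <- buildSensorHistory(ev, coverage = cov)
  shift <- 13 * 86400 + 7 * 3600
  ev2 <- ev; ev2$timestamp <- ev$timestamp + shift
  cov2 <- cov; cov2$start <- cov$start + shift; cov2$end <- cov$end + shift
  h2 <- buildSensorHistory(ev2, coverage = cov2, start = t0 + shift)
  expect_identical(detMatrix(h1), detMatrix(h2))
})

test_that("occasion windows partition the record", {
  # each event lands in exactly one half-open window
  set.seed(7)
  times <- sort(runif(200, 0, 40 * 86400))
  k <- floor(times / (5 * 86400)) + 1
  expect_true(all(k >= 1 & k <= 8))
  # boundary events belong to the later window
  kb <- floor((5 * 86400) / (5 * 86400)) + 1
  expect_equal(kb, 2)
  # per-occasion counts add up to the total
  ev <- data.frame(site_id = "s1", method = "CT", timestamp = t0 + times,
                   detected = TRUE, visit_index = NA_integer_)
  cov <- data.frame(site_id = "s1", start = t0, end = t0 + 40 * 86400)
  h <- buildSensorHistory(ev, coverage = cov)
  expect_true(all(!is.na(detMatrix(h))))
})

test_that("transect history codes visits and missing visits", {
  v <- data.frame(site_id = "tr1", method = "PT",
                  timestamp = t0 + c(1, 7, 14) * 86400 + 8 * 3600,
                  detected = c(TRUE, FALSE, TRUE), visit_index = 1:3)
  h <- buildTransectHistory(v)
  expect_equal(unname(detMatrix(h)[1, ]), c(1, 0, 1))

  h2 <- buildTransectHistory(v[1:2, ])
  expect_equal(unname(detMatrix(h2)[1, ]), c(1, 0, NA))

  vv <- v; vv$timestamp[2] <- vv$timestamp[1] + 2 * 86400
  expect_warning(buildTransectHistory(vv), "5 days apart")
})

test_that("the default campaign yields 20 point transects", {
  sim <- simulateCampaign(seed = 4)
  pt <- sim$events[sim$events$method == "PT", ]
  h <- suppressWarnings(buildTransectHistory(pt, sites = sim$sites))
  expect_equal(nSites(h), 20)
  expect_equal(nOccasions(h), 3)
})

test_that("fusion is OR with NA absorption", {
  a <- mkHistory(matrix(c(1, 0, NA), 1), method = "CT",
                 habitat = "forest", location = "L1")
  b <- mkHistory(matrix(c(0, 0, 1), 1), method = "PAM",
                 habitat = "forest", location = "L1")
  f <- fuseHistories(list(a, b))
  expect_equal(unname(detMatrix(f)[1, ]), c(1, 0, 1))
  expect_equal(siteCovs(f)$method, "CT+PAM")

  c1 <- mkHistory(matrix(c(NA, 0), 1), habitat = "forest", location = "L1")
  # an all-NA row is not a valid standalone history, so bypass validity to
  # probe the cell-wise NA rule
  c2 <- mkHistory(matrix(c(NA, 0), 1), method = "PAM", habitat = "forest",
                  location = "L1")
  c2@y[1, 2] <- NA_integer_
  f2 <- fuseHistories(list(c1, c2))
  expect_equal(unname(detMatrix(f2)[1, ]), c(NA, 0))

  expect_identical(fuseHistories(list(a)), a)

  d <- mkHistory(matrix(c(0, 1, 0), 1), method = "PAM",
                 habitat = "open", location = "L9")
  expect_error(fuseHistories(list(a, d)), "no overlapping")
})

test_that("fusion is commutative, associative, idempotent and dominates", {
  set.seed(11)
  rand <- function(method) {
    y <- matrix(sample(c(0L, 1L, NA), 40, replace = TRUE,
                       prob = c(0.4, 0.4, 0.2)), 10, 4)
    y[rowSums(!is.na(y)) == 0, 1] <- 0L
    DetectionHistory(y, data.frame(
      site_id = paste0(method, 1:10), method = method,
      habitat = rep(c("forest", "open"), 5),
      location_id = paste0("L", rep(1:5, each = 2))))
  }
  a <- rand("CT"); b <- rand("PAM"); c <- rand("PT")
  ab <- fuseHistories(list(a, b))
  ba <- fuseHistories(list(b, a))
  expect_identical(detMatrix(ab)[order(rownames(detMatrix(ab))), ],
                   detMatrix(ba)[order(rownames(detMatrix(ba))), ])
  abc1 <- fuseHistories(list(fuseHistories(list(a, b)), c),
                        label = "CT+PAM+PT")
  abc2 <- fuseHistories(list(a, fuseHistories(list(b, c))),
                        label = "CT+PAM+PT")
  expect_identical(detMatrix(abc1), detMatrix(abc2))
  aa <- fuseHistories(list(a, a), label = "CT")
  expect_identical(unname(detMatrix(aa)), unname(detMatrix(a)))
  # fused rows carry at least as many detections as any input row
  key <- paste(siteCovs(a)$location_id, siteCovs(a)$habitat)
  keyF <- paste(siteCovs(ab)$location_id, siteCovs(ab)$habitat)
  ones <- function(m) rowSums(m == 1L, na.rm = TRUE)
  expect_true(all(ones(detMatrix(ab)) >=
                    ones(detMatrix(a))[match(keyF, key)]))
})

test_that("naive summaries equal brute-force tallies", {
  set.seed(3)
  y <- matrix(sample(c(0L, 1L, NA), 60, replace = TRUE), 10, 6)
  y[rowSums(!is.na(y)) == 0, 1] <- 0L
  h <- mkHistory(y, method = "CT",
                 habitat = rep(c("forest", "open"), 5),
                 location = paste0("L", rep(1:5, each = 2)))
  ns <- naiveSummary(h)
  for (hab in c("forest", "open")) {
    sel <- siteCovs(h)$habitat == hab
    cells <- detMatrix(h)[sel, ]
    row <- ns$rates[ns$rates$habitat == hab, ]
    expect_equal(row$detected, sum(cells == 1L, na.rm = TRUE))
    expect_equal(row$total, sum(!is.na(cells)))
    expect_equal(row$rate, row$detected / row$total)
  }
  expect_equal(sum(ns$siteRates$detected_sites),
               sum(rowSums(y == 1L, na.rm = TRUE) > 0))
})

test_that("latency counts surveyed occasions to first detection", {
  h <- mkHistory(matrix(c(0, 0, 1), 1))
  expect_equal(naiveSummary(h)$latency$mean, 3)
  h2 <- mkHistory(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 0)))
  lat <- naiveSummary(h2)$latency
  expect_equal(lat$mean, 1.5)  # undetected site excluded
  expect_equal(c(lat$min, lat$max), c(1, 2))
})

test_that("pairwise overlap counts agree on shared site-occasions", {
  a <- mkHistory(rbind(c(1, 1, 0, 0)), method = "CT",
                 habitat = "forest", location = "L1")
  b <- mkHistory(rbind(c(1, 0, 1, NA)), method = "PAM",
                 habitat = "forest", location = "L1")
  ov <- naiveSummary(list(a, b))$overlap
  expect_equal(ov$both, 1)
  expect_equal(ov$only_a, 1)
  expect_equal(ov$only_b, 1)
  expect_equal(ov$neither, 0)
})

test_that("hourly profile bins detected events by hour of day", {
  ev <- data.frame(site_id = "s1", method = "PAM",
                   timestamp = t0 + c(5 * 3600 + 600, 5 * 3600 + 3000,
                                      17 * 3600 + 1800),
                   detected = TRUE, visit_index = NA_integer_)
  pr <- hourlyProfile(ev)
  expect_equal(sum(pr$count), 3)
  expect_equal(pr$count[pr$hour == 5], 2)
  expect_equal(pr$count[pr$hour == 17], 1)
  expect_equal(nrow(pr), 24)

  pr0 <- hourlyProfile(ev[0, ])
  expect_true(all(pr0$count == 0))
})

test_that("history CSV round-trips through the readers", {
  h <- mkHistory(rbind(c(1, 0, NA), c(0, 1, 1)), method = "CT",
                 habitat = c("forest", "open"), location = c("L1", "L2"))
  f <- tempfile(fileext = ".csv")
  writeHistory(h, f)
  back <- readHistory(f)
  expect_identical(detMatrix(back), detMatrix(h))
  expect_equal(siteCovs(back)$habitat, siteCovs(h)$habitat)
})

test_that("stacking warns about pseudo-replicated fused rows", {
  a <- mkHistory(rbind(c(1, 0)), method = "CT", habitat = "forest",
                 location = "L1", prefix = "ct")
  b <- mkHistory(rbind(c(0, 1)), method = "PAM", habitat = "forest",
                 location = "L1", prefix = "pam")
  f <- fuseHistories(list(a, b))
  expect_warning(st <- stackHistories(list(a, b, f)),
                 "pseudo-replicated")
  expect_equal(nSites(st), 3)
})
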