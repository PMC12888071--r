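test_that("negative log-likelihood matches closed forms", {
  h <- mkHistory(matrix(c(1L, 0L), 1))
  # psi = 1, p = 0.5: L = 0.25
  expect_equal(occuNegLogLik(h, occuModelSpec(~1), beta = 0), -log(0.25))

  # psi free: all-zero history of length 2, p = 0.5, psi = 0.4
  h0 <- mkHistory(matrix(c(0L, 0L), 1))
  expect_equal(occuNegLogLik(h0, occuModelSpec(~1, psi = "free"),
                             beta = 0, psi = 0.4),
               -log(0.4 * 0.25 + 0.6))

  # NA cells are skipped
  hNA <- mkHistory(matrix(c(1L, NA, 0L), 1))
  expect_equal(occuNegLogLik(hNA, occuModelSpec(~1), beta = 0),
               -log(0.25))
})

test_that("site probabilities enumerate to one over all histories", {
  # exhaustive oracle: for any p and psi the 2^3 single-site histories have
  # total probability 1
  combos <- expand.grid(h1 = 0:1, h2 = 0:1, h3 = 0:1)
  for (p in c(0.2, 0.6)) {
    for (psi in c(1, 0.7)) {
      spec <- if (psi == 1) occuModelSpec(~1)
              else occuModelSpec(~1, psi = "free")
      tot <- sum(apply(combos, 1, function(hv) {
        h <- mkHistory(matrix(as.integer(hv), 1))
        exp(-occuNegLogLik(h, spec, beta = qlogis(p), psi = psi))
      }))
      expect_equal(tot, 1, tolerance = 1e-12)
    }
  }
})

test_that("intercept-only MLE equals the binomial closed form", {
  # 19 detections in 60 surveyed cells across sites with missingness
  y <- rbind(matrix(c(rep(1L, 19), rep(0L, 35)), 9, 6),
             c(0L, 0L, 0L, NA, NA, NA),
             c(0L, 0L, 0L, NA, NA, NA))
  h <- mkHistory(y)
  stopifnot(sum(y == 1L, na.rm = TRUE) == 19, sum(!is.na(y)) == 60)
  fit <- fitOccu(h, occuModelSpec(~1))
  phat <- plogis(coef(fit)[[1]])
  expect_equal(phat, 19 / 60, tolerance = 1e-6)
  # fitted log-likelihood equals the binomial log-likelihood at p-hat
  expect_equal(fit@loglik, 19 * log(19 / 60) + 41 * log(41 / 60),
               tolerance = 1e-8)
  # delta-method SE matches the binomial SE sqrt(p(1-p)/n)
  pr <- predictP(fit, data.frame(method = "CT"))
  expect_equal(pr$p, 19 / 60, tolerance = 1e-6)
  expect_equal(pr$se, sqrt((19 / 60) * (41 / 60) / 60), tolerance = 1e-3)
})

test_that("method-model contrasts reproduce logit differences", {
  # disjoint site sets per method: level MLEs are the per-level cell means
  set.seed(21)
  mk <- function(m, p, n) {
    y <- matrix(rbinom(n * 6, 1, p), n, 6)
    if (all(y == 0)) y[1, 1] <- 1L
    DetectionHistory(y, data.frame(site_id = paste0(m, 1:n), method = m))
  }
  h <- stackHistories(list(mk("PT", 0.3, 12), mk("CT", 0.65, 12),
                           mk("PAM", 0.8, 12)))
  fit <- fitOccu(h, occuModelSpec(~method))
  y <- detMatrix(h); sc <- siteCovs(h)
  for (m in c("CT", "PAM")) {
    pm <- mean(y[sc$method == m, ], na.rm = TRUE)
    p0 <- mean(y[sc$method == "PT", ], na.rm = TRUE)
    expect_equal(unname(coef(fit)[paste0("method", m)]),
                 qlogis(pm) - qlogis(p0), tolerance = 1e-6)
  }
  # PT is the reference: the intercept is its own logit rate
  expect_equal(unname(plogis(coef(fit)["(Intercept)"])),
               mean(y[sc$method == "PT", ], na.rm = TRUE),
               tolerance = 1e-6)
})

test_that("design matrices use treatment coding with stated references", {
  sim <- simulateCampaign(seed = 2)
  hh <- suppressWarnings(
    buildStudyHistories(sim$events, sim$sites, sim$coverage))
  stopifnot(length(unique(siteCovs(hh$stacked)$method)) == 7)
  fits <- list(
    null = fitOccu(hh$stacked, occuModelSpec(~1)),
    method = suppressWarnings(fitOccu(hh$stacked, occuModelSpec(~method))),
    inter = suppressWarnings(
      fitOccu(hh$stacked, occuModelSpec(~method * habitat))))
  # 7 method levels: intercept + 6 dummies; +1 when psi is free
  expect_equal(fits$method@nParams, 7)
  free <- suppressWarnings(
    fitOccu(hh$stacked, occuModelSpec(~method, psi = "free")))
  expect_equal(free@nParams, 8)
  expect_equal(fits$null@nParams, 1)
  expect_equal(fits$inter@nParams, 14)
  interFree <- suppressWarnings(
    fitOccu(hh$stacked, occuModelSpec(~method * habitat, psi = "free")))
  expect_equal(interFree@nParams, 15)
  expect_false("methodPT" %in% names(coef(fits$method)))

  expect_error(predictP(fits$method, data.frame(method = "SONAR")),
               "not seen")
})

test_that("AICc follows the small-sample correction", {
  expect_equal(aicc(-5, 2, 10), 14 + 12 / 7)
  expect_equal(aicc(-5, 0, 10), 10)          # K = 0: AICc = AIC
  # approaches AIC monotonically from above as n grows
  vals <- sapply(c(20, 50, 200, 2000), function(n) aicc(-5, 3, n))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > -2 * -5 + 2 * 3))
  expect_error(aicc(-5, 9, 10), "undefined")
})

test_that("model ranking computes deltas and Akaike weights", {
  mkFit <- function(name, ll, K, n = 40) {
    new("OccupancyFit", name = name, beta = c("(Intercept)" = 0), psi = 1,
        vcov = matrix(0.1, 1, 1), loglik = ll, nParams = K, nSites = n,
        aic = -2 * ll + 2 * K, aicc = aicc(ll, K, n), converged = TRUE,
        spec = occuModelSpec(~1), xlevels = list(),
        sites = paste0("s", 1:n))
  }
  # equal K and n, log-likelihoods 1 apart: AICc differ by exactly 2
  f1 <- mkFit("a", -10, 1)
  f2 <- mkFit("b", -11, 1)
  tab <- rankModels(list(f1, f2))
  expect_equal(tab$delta, c(0, 2), tolerance = 1e-10)
  expect_equal(tab$weight, c(1, exp(-1)) / (1 + exp(-1)),
               tolerance = 1e-10)
  expect_equal(sum(tab$weight), 1)

  single <- rankModels(list(f1))
  expect_equal(single$delta, 0)
  expect_equal(single$weight, 1)

  f3 <- mkFit("c", -10, 1, n = 41)
  f3@sites <- paste0("x", 1:41)
  expect_error(rankModels(list(f1, f3)), "differing site sets")
})

test_that("only one parsimonious model emerges under a method effect", {
  sim <- simulateCampaign(seed = 9)
  hh <- suppressWarnings(
    buildStudyHistories(sim$events, sim$sites, sim$coverage))
  fits <- lapply(list(~1, ~method, ~habitat), function(f)
    suppressWarnings(fitOccu(hh$stacked, occuModelSpec(f))))
  tab <- rankModels(fits)
  expect_equal(tab$model[1], "p(method) psi(=1)")
  expect_equal(sum(tab$parsimonious), 1)
  expect_true(attr(tab, "null_delta") > 7)
})

test_that("back-transformed predictions apply the delta method", {
  fit <- new("OccupancyFit", name = "m", beta = c("(Intercept)" = 0),
             psi = 1, vcov = matrix(0.16, 1, 1,
                                    dimnames = list("(Intercept)",
                                                    "(Intercept)")),
             loglik = -1, nParams = 1, nSites = 10, aic = 4,
             aicc = aicc(-1, 1, 10), converged = TRUE,
             spec = occuModelSpec(~1), xlevels = list(),
             sites = paste0("s", 1:10))
  pr <- predictP(fit, data.frame(row = 1))
  expect_equal(pr$p, 0.5)
  expect_equal(pr$se, 0.5 * 0.5 * 0.4)   # p(1-p) * SE_eta = 0.1

  # towards the boundary both p and its SE vanish
  fit@beta <- c("(Intercept)" = -12)
  pr2 <- predictP(fit, data.frame(row = 1))
  expect_lt(pr2$p, 1e-5)
  expect_lt(pr2$se, 1e-5)
})

test_that("minimum-effort formula behaves across its domain", {
  expect_equal(round(nMin(0.648), 2), 2.87)
  expect_equal(round(nMin(0.793), 2), 1.90)
  expect_equal(nMin(0.95, alpha = 0.05), 1)   # log ratio of equal arguments
  expect_error(nMin(0), "strictly between")
  expect_error(nMin(1), "strictly between")
})

test_that("separated levels trigger a warning, not an error", {
  set.seed(8)
  h <- stackHistories(list(
    mkHistory(matrix(rep(1L, 12), 3, 4), method = "CT"),
    DetectionHistory(matrix(rbinom(12, 1, 0.5), 3, 4),
                     data.frame(site_id = paste0("q", 1:3),
                                method = "PT"))))
  w <- capture_warnings(fit <- fitOccu(h, occuModelSpec(~method)))
  expect_true(any(grepl("separated", w)))
  # a convergence warning may accompany it: the boundary MLE has no
  # interior stationary point
  expect_true(all(grepl("separated|converge", w)))
  expect_true(is.finite(fit@loglik))
})

test_that("parameters are recovered from simulated campaigns", {
  # moderately large single campaign: per-method estimates near truth
  sc <- bigScenario(nLoc = 33)
  sim <- simulateCampaign(sc, seed = 31)
  hh <- suppressWarnings(
    buildStudyHistories(sim$events, sim$sites, sim$coverage))
  h <- stackHistories(hh$single)
  fit <- fitOccu(h, occuModelSpec(~method))
  pr <- predictP(fit, data.frame(method = c("PT", "CT", "PAM")))
  expect_equal(pr$p[pr$method == "PT"], 0.33, tolerance = 0.03 / 0.33)
  expect_equal(pr$p[pr$method == "CT"], 0.65, tolerance = 0.03 / 0.65)
  expect_equal(pr$p[pr$method == "PAM"], 0.79, tolerance = 0.03 / 0.79)
})
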