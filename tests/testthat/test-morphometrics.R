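test_that("polygon areas match closed forms", {
  expect_equal(polygonArea(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))), 1)
  s <- 2.5
  hex <- cbind(s * cos((0:5) * pi / 3), s * sin((0:5) * pi / 3))
  expect_equal(polygonArea(hex), 3 * sqrt(3) / 2 * s^2, tolerance = 1e-12)
  expect_error(polygonArea(cbind(0:1, 0:1)), "3 vertices")
})

test_that("area conventions coincide on exact meshes", {
  hc <- sharedHoneycomb()
  pg <- polygons(hc)
  ids <- pg$id[pg$kind == "single"][1:8]
  a1 <- polygonArea(hc, ids, convention = "include_overlap")
  a2 <- polygonArea(hc, ids, convention = "plain")
  expect_equal(a1, a2, tolerance = 1e-9)
  expect_equal(unname(a1), pg$area[match(ids, pg$id)], tolerance = 1e-9)
})

test_that("polygon Z is the vertex average", {
  expect_equal(polygonZ(cbind(1:4, 1:4, rep(2, 4))), 2)
  expect_equal(polygonZ(cbind(1:4, 1:4, c(0, 0, 3, 3))), 1.5)
  # direct re-computation oracle on random polygons
  set.seed(7)
  for (k in 1:100) {
    n <- sample(3:12, 1)
    P <- matrix(rnorm(3 * n), n)
    expect_equal(polygonZ(P), sum(P[, 3]) / n)
  }
  hc <- sharedHoneycomb()
  z <- polygonZ(hc, polygons(hc)$id[1:5])
  ora <- vapply(rings(hc)[1:5], function(P) mean(P[, 3]), 0)
  expect_equal(unname(z), ora)
})

test_that("relative Z centres an octet and rejects other sizes", {
  expect_equal(relativeZ(rep(3.3, 8)), rep(0, 8))
  set.seed(3)
  for (k in 1:20) {
    z <- rnorm(8, sd = 4)
    expect_equal(sum(relativeZ(z)), 0, tolerance = 1e-12)
  }
  expect_error(relativeZ(1:7), "exactly 8")
})

test_that("octet relative-Z shows the exterior-above / interior-below pattern", {
  relz <- list()
  sim <- sharedSim()
  for (t in snapshotTimes(sim)[snapshotTimes(sim) > 48])
    relz[[length(relz) + 1L]] <- octetRelativeZ(extractHoneycomb(sim, t))
  Z <- do.call(rbind, relz)
  expect_gt(nrow(Z), 50)
  mEx <- mean(Z$rel_z[Z$kind == "exterior"])
  mSi <- mean(Z$rel_z[Z$kind == "single"])
  mIn <- mean(Z$rel_z[Z$kind == "interior"])
  expect_gt(mEx, 0)
  expect_lt(mIn, mSi)
  expect_lt(mSi, mEx)
  expect_lt(mIn, 0)
})

test_that("windows count by centroid and reduce to global counts at full cover", {
  hc <- sharedHoneycomb()
  pg <- polygons(hc)
  allxy <- do.call(rbind, lapply(rings(hc), function(P) P[, 1:2]))
  span <- max(apply(allxy, 2, function(v) diff(range(v)))) + 10
  w <- sampleWindows(hc, windowArea = span^2,
                     origins = matrix(apply(allxy, 2, min) - 5, 1),
                     wrap = FALSE)
  expect_identical(w$n_single, sum(pg$kind == "single"))
  expect_identical(w$n_double, nrow(doubleEdgedPairs(hc)))
  # equality with the engine-side transitioning fraction
  pct <- 100 * w$n_double / (w$n_double + w$n_single)
  st <- ftkd::snapshotAt(sharedSim(), max(snapshotTimes(sharedSim())))
  expect_equal(pct, 100 * sum(st$phase == 2L) / 81)
  expect_error(sampleWindows(hc, windowArea = 1e9), "larger than the domain")
})

test_that("window counts match the density oracle", {
  hc <- crystalHoneycomb(9, 9)
  set.seed(2)
  w <- sampleWindows(hc, nWindows = 200, windowArea = 15376)
  meanPoly <- enFaceArea(buildLattice(9, 9)) / 81
  expect_equal(mean(w$n_single + w$n_double), 15376 / meanPoly, tolerance = 0.1)
})

test_that("double-edged percentage pools windows within assays, SEM across assays", {
  expect_equal(doubleEdgedPercent(data.frame(n_single = 10, n_double = 0))$mean, 0)
  d <- data.frame(n_single = rep(9, 10), n_double = rep(1, 10),
                  assay = rep(1:5, each = 2))
  r <- doubleEdgedPercent(d)
  expect_equal(r$mean, 10)
  expect_equal(r$sem, 0)
  expect_identical(r$n_assays, 5L)
  # unequal assays: SEM is across the 2 assay percentages
  d2 <- data.frame(n_single = c(9, 8), n_double = c(1, 2), assay = 1:2)
  r2 <- doubleEdgedPercent(d2)
  expect_equal(unname(r2$percent), c(10, 20))
  expect_equal(r2$sem, stats::sd(c(10, 20)) / sqrt(2))
  expect_error(doubleEdgedPercent(data.frame(n_single = 1)), "n_double")
})

test_that("scale calibration hits the target mean single-edged area", {
  syn <- makeNoisyHoneycomb(synthConfig(plantRate = 9.8, seed = 5))
  pg <- polygons(syn$graph)
  m <- mean(pg$area[pg$kind == "single"])
  expect_equal(m, 905.8, tolerance = 1e-3 / 905.8)   # within 0.1%
  sc <- calibrateScale(syn$graph, 905.8)
  expect_equal(sc, syn$graph@scale, tolerance = 1e-9)
})

test_that("statistics are invariant under en face translation and 60-degree rotation", {
  hc <- crystalHoneycomb()
  rot <- function(g, ang, shift) {
    Rm <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    g@rings <- lapply(g@rings, function(P) {
      P[, 1:2] <- sweep(P[, 1:2, drop = FALSE] %*% t(Rm), 2, -shift)
      P
    })
    g@domain$latVec <- g@domain$latVec %*% t(Rm)
    ftkd:::.refreshGeometry(g)
  }
  g2 <- rot(hc, pi / 3, c(13.7, -4.2))
  expect_equal(polygons(g2)$area, polygons(hc)$area, tolerance = 1e-9)
  expect_equal(polygons(g2)$z, polygons(hc)$z, tolerance = 1e-9)
  set.seed(8); w1 <- sampleWindows(hc, nWindows = 50)
  set.seed(8); w2 <- sampleWindows(g2, nWindows = 50)
  expect_equal(mean(w1$n_single + w1$n_double), mean(w2$n_single + w2$n_double),
               tolerance = 0.05)
})

test_that("summaryStats reports every metric with its n", {
  st <- summaryStats(sharedSim(), nWindows = 10)
  expect_true(all(c("double_edged_percent", "residence", "area", "relative_z")
                  %in% st$metric))
  expect_true(all(st$n > 0))
  expect_true(all(st$units %in% c("%", "hr", "um^2", "um")))
  a <- st[st$metric == "area", ]
  expect_gt(a$mean[a$class == "exterior"], a$mean[a$class == "single"])
  expect_gt(a$mean[a$class == "single"], a$mean[a$class == "interior"])
})
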