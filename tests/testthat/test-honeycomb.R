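test_that("the all-steady crystal honeycomb is a pure bicellular tiling", {
  hc <- crystalHoneycomb()
  pg <- polygons(hc)
  expect_identical(nrow(pg), 36L)                 # one polygon per column
  expect_true(all(pg$kind == "single"))
  expect_identical(sum(seams(hc)$class == "tTJ"), 0L)
  expect_true(all(seams(hc)$n_share == 2L))       # every seam bicellular
  # tricellular contact points at the vertices are recorded, not displayed
  expect_true(all(pg$n_ttj_vertices > 0))
  # polygons tile the domain exactly
  expect_equal(sum(pg$area), enFaceArea(buildLattice(6, 6)), tolerance = 1e-9)
  bc <- barrierContinuity(hc)
  expect_true(bc$ok)
  expect_equal(bc$coverage, 1)
})

test_that("snapshot honeycombs pair exteriors and interiors per transitioning column", {
  sim <- sharedSim()
  for (t in utils::tail(snapshotTimes(sim), 3)) {
    hc <- extractHoneycomb(sim, t)
    st <- ftkd::snapshotAt(sim, t)
    pg <- polygons(hc)
    nT <- sum(st$phase == 2L)
    expect_identical(sum(pg$kind == "exterior"), nT)
    expect_identical(sum(pg$kind == "interior"), nT)
    expect_identical(nrow(doubleEdgedPairs(hc)), nT)
    # cross-module consistency: fraction counted on polygons (a pair = one)
    expect_equal(nT / (nT + sum(pg$kind == "single")), nT / 81)
    # interior polygons are all-tricellular; every tTJ seam is shared by 3 cells
    sm <- seams(hc)
    iid <- pg$id[pg$kind == "interior"]
    expect_true(all(sm$n_share[sm$polygon_id %in% iid] == 3L))
    expect_true(all(sm$n_share[sm$class == "tTJ"] == 3L))
    expect_true(all(sm$n_share[sm$class == "bTJ"] == 2L))
    # exact tiling: singles + exteriors sum to the domain area
    expect_equal(sum(pg$area[pg$kind != "interior"]), enFaceArea(sim@lattice),
                 tolerance = 1e-6)
  }
})

test_that("nested-pair classification recovers the construction and its geometry", {
  hc <- sharedHoneycomb()
  cd <- classifyDoubleEdged(hc)
  tp <- doubleEdgedPairs(hc)
  expect_identical(sort(cd$exterior), sort(tp$exterior))
  expect_identical(sort(cd$interior), sort(tp$interior))
  expect_true(all(cd$area_int < cd$area_ext))
  expect_true(all(cd$z_int < cd$z_ext))
  # all-steady snapshot: no pairs
  expect_identical(nrow(classifyDoubleEdged(crystalHoneycomb())), 0L)
})

test_that("barrier continuity holds on simulated snapshots and detects damage", {
  hc <- sharedHoneycomb()
  bc <- barrierContinuity(hc)
  expect_true(bc$ok)
  expect_equal(bc$coverage, 1)
  broken <- barrierContinuity(dropSeam(hc, polygons(hc)$id[5]))
  expect_false(broken$ok)
  expect_true(5L %in% broken$open_polygons)
})

test_that("the hexagonal-prism comparison model tears its barrier when a column slides", {
  hx <- makeFixture("hexprism_strawman")
  expect_true(barrierContinuity(hx$aligned)$ok)
  bad <- barrierContinuity(hx$graph)
  expect_false(bad$ok)
  expect_true(hx$column %in% bad$unsealed_columns)
})

test_that("polygon adjacency is symmetric and matches the lattice degree", {
  hc <- crystalHoneycomb()
  ids <- polygons(hc)$id
  nb <- lapply(ids, function(id) polygonNeighbors(hc, id))
  names(nb) <- ids
  for (id in ids) {
    expect_length(nb[[as.character(id)]], 6L)   # triangular lattice degree
    for (q in nb[[as.character(id)]])
      expect_true(id %in% nb[[as.character(q)]])
  }
  expect_error(polygonNeighbors(hc, 999L), "unknown polygon")
})

test_that("a double-edged pair in the regular lattice has six single-edged neighbours", {
  cp <- makeFixture("column_pair")
  pr <- doubleEdgedPairs(cp$graph)
  expect_identical(nrow(pr), 1L)
  nb <- polygonNeighbors(cp$graph, c(pr$exterior, pr$interior))
  expect_length(nb, 6L)
  expect_true(all(polygons(cp$graph)$kind[match(nb, polygons(cp$graph)$id)] == "single"))
  # the interior is adjacent to its exterior (nesting adjacency)
  expect_true(pr$exterior %in% polygonNeighbors(cp$graph, pr$interior))
})

test_that("TJ replacement is edge-by-edge: polygons grow stepwise between own transitions", {
  sim <- runTurnover(simConfig(nx = 6, ny = 6, duration = 84, burnIn = 24,
                               seed = 21, snapshotEvery = 1.2))
  ev <- events(sim)
  ts <- snapshotTimes(sim)
  # pick a column with two completed turnovers inside the stored window
  ends <- ev[ev$event == "transition_end", ]
  cand <- as.integer(names(which(table(ends$column_id[ends$time_hr > 30]) >= 2)))
  c0 <- cand[1]
  own <- sort(ends$time_hr[ends$column_id == c0])
  lo <- own[own > 30][1]; hi <- own[own > 30][2]
  win <- ts[ts > lo & ts < hi]
  areas <- numeric(0); seamsPrev <- NULL; maxswap <- 0L
  for (t in win) {
    hc <- extractHoneycomb(sim, t)
    pg <- polygons(hc)
    row <- which(pg$column_id == c0 & pg$kind != "interior")[1]
    areas <- c(areas, pg$area[row])
    keys <- seams(hc)$key[seams(hc)$polygon_id == pg$id[row]]
    if (!is.null(seamsPrev))
      maxswap <- max(maxswap, length(setdiff(seamsPrev, keys)))
    seamsPrev <- keys
  }
  expect_true(all(diff(areas) >= -1e-9))          # non-decreasing
  expect_gt(areas[length(areas)], areas[1])       # it actually grows
  expect_lte(maxswap, 4L)                         # a few seams per step, not all
})

test_that("age order always matches geometric height order during a run", {
  sim <- sharedSim()
  for (t in snapshotTimes(sim))
    expect_true(auditHeights(ftkd::snapshotAt(sim, t), sim@lattice))
  # iid snapshots are rejected as geometrically unrealizable
  simBad <- runTurnover(simConfig(nx = 6, ny = 6, duration = 12, burnIn = 6,
                                  seed = 1, init = "iid"))
  expect_error(extractHoneycomb(simBad), "age order|height")
})

test_that("honeycomb extraction requires a 3-divisible periodic lattice", {
  sim <- runTurnover(simConfig(nx = 4, ny = 6, duration = 12, burnIn = 6))
  expect_error(extractHoneycomb(sim), "divisible by 3")
})
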