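# Polarity vectors, angle-to-flow statistics, scalar products, regressions.

test_that("nucleus-Golgi pairing follows greedy nearest matching", {
  ct <- pair_points(rbind(c(0, 0)), rbind(c(3, 4)))
  expect_equal(ct$px, 3)
  expect_equal(ct$py, 4)
  expect_equal(ct$pmag, 5)
  # coincident Golgi: |p| = 0
  ct0 <- pair_points(rbind(c(1, 1)), rbind(c(1, 1)))
  expect_equal(ct0$pmag, 0)
  # crossing 2x2 arrangement: greedy result equals the exhaustive
  # minimum-successive-distance assignment
  nuc <- rbind(c(0, 0), c(10, 0))
  gol <- rbind(c(4, 0), c(6, 0))
  ct2 <- pair_points(nuc, gol, max_pair_dist = 10)
  # brute force: greedy picks globally closest pair first
  d <- as.matrix(dist(rbind(nuc, gol)))[1:2, 3:4]
  first <- which(d == min(d), arr.ind = TRUE)[1, ]
  expect_equal(ct2$golgi_x[first[1]], gol[first[2], 1])
  expect_true(all(ct2$paired))
  # out-of-range nuclei stay unpaired
  ct3 <- pair_points(rbind(c(0, 0), c(100, 100)), rbind(c(1, 0)), max_pair_dist = 5)
  expect_identical(ct3$paired, c(TRUE, FALSE))
  expect_identical(nrow(pair_points(matrix(numeric(0), 0, 2),
                                    matrix(numeric(0), 0, 2))), 0L)
})

test_that("segment assignment matches exhaustive nearest-polyline search", {
  w <- small_world()
  set.seed(42)
  n <- 100
  th <- runif(n, 0, 2 * pi); rr <- sqrt(runif(n)) * 280
  cells <- data.frame(cell_id = 1:n, nucleus_x = rr * cos(th),
                      nucleus_y = rr * sin(th),
                      golgi_x = rr * cos(th) + 3, golgi_y = rr * sin(th))
  got <- assign_to_segments(cells, w$net, max_assign_dist = 1e9)
  # brute force over every polyline edge of every segment
  for (i in seq_len(n)) {
    dmin <- Inf; best <- NA
    for (k in seq_len(nrow(w$net$segments))) {
      g <- w$net$geometry[[k]]
      d <- min(polarflow:::point_seg_dist(cells$nucleus_x[i], cells$nucleus_y[i],
                                          g[-nrow(g), 1], g[-nrow(g), 2],
                                          g[-1, 1], g[-1, 2]))
      if (d < dmin - 1e-9) { dmin <- d; best <- w$net$segments$id[k] }
    }
    # nearest-vertex assignment can differ from nearest-polyline only when
    # two segments are nearly equidistant; allow that slack
    d_got <- got$distance_to_segment[i]
    expect_lt(abs(d_got - dmin), 1.5)
  }
  # nucleus exactly on a centerline vertex: distance 0 to that segment
  g7 <- w$net$geometry[[7]]
  on_vtx <- data.frame(cell_id = 1L, nucleus_x = g7[3, 1], nucleus_y = g7[3, 2],
                       golgi_x = g7[3, 1] + 2, golgi_y = g7[3, 2])
  got2 <- assign_to_segments(on_vtx, w$net)
  expect_lt(got2$distance_to_segment, 1e-9)
  # far-away cells are left unassigned
  far <- data.frame(cell_id = 1L, nucleus_x = 5000, nucleus_y = 5000,
                    golgi_x = 5001, golgi_y = 5000)
  expect_true(is.na(assign_to_segments(far, w$net)$segment_id))
})

test_that("angle and scalar product follow the sign convention", {
  # straight tube flowing +x; cells with hand-computed angles
  net <- tube_network(r = 4, L = 100)
  flow <- wall_shear(net, solve_flow(net, boundary_conditions(1L, 2L, 10, 0)))
  mk <- function(px, py) {
    data.frame(cell_id = 1L, nucleus_x = 50, nucleus_y = 0,
               golgi_x = 50 + px, golgi_y = py)
  }
  run <- function(px, py) {
    cells <- assign_to_segments(mk(px, py), net)
    angle_and_scalar(cells, net, flow)
  }
  # antiparallel: theta = 180, s = -|p|
  r1 <- run(-6, 0)
  expect_equal(r1$theta_deg, 180)
  expect_equal(r1$scalar_product, -6)
  expect_true(r1$against_flow)
  # perpendicular: theta = 90, s = 0
  r2 <- run(0, 3)
  expect_equal(r2$theta_deg, 90)
  expect_equal(r2$scalar_product, 0, tolerance = 1e-12)
  # p = (1, 0) against flow at 45 degrees: rotate flow via the polarity
  r3 <- run(sqrt(2) / 2, sqrt(2) / 2)
  expect_equal(r3$theta_deg, 45)
  expect_equal(r3$scalar_product, cos(pi / 4), tolerance = 1e-9)
  # |p| = 0: angle undefined by convention
  r4 <- run(0, 0)
  expect_true(is.na(r4$theta_deg))
})

test_that("the scalar product is bounded by the polarity magnitude", {
  w <- small_world()
  cells <- angle_and_scalar(assign_to_segments(w$cells, w$net), w$net, w$flow)
  ok <- !is.na(cells$scalar_product)
  expect_true(all(cells$scalar_product[ok] <= cells$pmag[ok] + 1e-9))
  expect_true(all(cells$scalar_product[ok] >= -cells$pmag[ok] - 1e-9))
  at180 <- ok & abs(cells$theta_deg - 180) < 1e-9
  expect_equal(cells$scalar_product[at180], -cells$pmag[at180], tolerance = 1e-9)
})

test_that("region statistics count the closed against-flow window", {
  cells <- data.frame(cell_id = 1:2, region = "capillary",
                      theta_deg = c(170, 10), pmag = c(5, 5),
                      px = c(1, 1), py = 0,
                      scalar_product = c(-4.9, 4.9))
  st <- region_stats(cells)
  expect_equal(st$by_region$frac_against[st$by_region$region == "all"], 0.5)
  # all cells at exactly 180: fraction 1, resultant length 1
  cells2 <- data.frame(cell_id = 1:5, region = "artery", theta_deg = 180,
                       pmag = 5, px = -1, py = 0, scalar_product = -5)
  st2 <- region_stats(cells2)
  expect_equal(st2$by_region$frac_against[1], 1)
  expect_equal(st2$by_region$resultant[1], 1)
  # boundary cell at exactly 135 counts as against (closed interval)
  cells3 <- data.frame(cell_id = 1L, region = "vein", theta_deg = 135,
                       pmag = 2, px = 1, py = 0, scalar_product = -1)
  expect_equal(region_stats(cells3)$by_region$frac_against[1], 1)
  # histogram counts sum to the angle-defined n
  w <- small_world()
  cc <- angle_and_scalar(assign_to_segments(w$cells, w$net), w$net, w$flow)
  st4 <- region_stats(cc)
  expect_identical(sum(st4$histograms$all),
                   st4$by_region$n[st4$by_region$region == "all"])
})

test_that("uniform polarity yields a quarter against flow", {
  w <- small_world(seed = 4, n_cells = 5000, kappa = 0)
  cells <- angle_and_scalar(assign_to_segments(w$cells, w$net), w$net, w$flow)
  st <- region_stats(cells)
  frac <- st$by_region$frac_against[st$by_region$region == "all"]
  expect_lt(abs(frac - 0.25), 0.02)
})

test_that("kappa sweep recovers the von Mises window mass monotonically", {
  # independent oracle: numerical integration of the von Mises density
  mass <- function(kappa) {
    if (kappa == 0) return(0.25)
    f <- function(t) exp(kappa * cos(t))
    integrate(f, -pi / 4, pi / 4)$value / integrate(f, -pi, pi)$value
  }
  fracs <- c(); masses <- c()
  for (kappa in c(0, 1, 4, 16)) {
    w <- small_world(seed = 5, n_cells = 4000, kappa = kappa)
    cells <- angle_and_scalar(assign_to_segments(w$cells, w$net), w$net, w$flow)
    th <- cells$theta_deg[!is.na(cells$theta_deg)]
    frac <- mean(th >= 135)
    m <- mass(kappa)
    se <- sqrt(m * (1 - m) / length(th))
    expect_lt(abs(frac - m), 2.5 * se + 0.005)
    fracs <- c(fracs, frac); masses <- c(masses, m)
  }
  expect_true(all(diff(fracs) > 0))
  expect_true(all(diff(masses) > 0))
})

test_that("sign-stratified shear regressions recover planted lines", {
  w <- small_world()
  cells <- angle_and_scalar(assign_to_segments(w$cells, w$net), w$net, w$flow)
  tau <- w$flow$segments$tau[match(cells$segment_id, w$flow$segments$segment_id)]
  ok <- !is.na(cells$theta_deg) & !is.na(tau)
  cells <- cells[ok, ]; tau <- tau[ok]
  # noiseless: s = -0.5 tau on half the cells, s = +0.2 tau + 1 on the rest
  half <- seq_len(nrow(cells)) %% 2 == 0
  cells$scalar_product[half] <- -0.5 * tau[half] - 1e-6
  cells$scalar_product[!half] <- 0.2 * tau[!half] + 1
  fits <- shear_regressions(cells, w$flow)
  neg <- fits[fits$region == "all" & fits$stratum == "negative", ]
  pos <- fits[fits$region == "all" & fits$stratum == "positive", ]
  expect_equal(neg$gradient, -0.5, tolerance = 1e-6)
  expect_equal(neg$R, -1, tolerance = 1e-6)
  expect_equal(pos$gradient, 0.2, tolerance = 1e-6)
  expect_equal(pos$R, 1, tolerance = 1e-6)
  # constant tau: stratum skipped with a warning
  cells2 <- cells
  flow2 <- w$flow
  flow2$segments$tau[] <- 1
  wrn <- capture_warnings(shear_regressions(cells2, flow2))
  expect_true(any(grepl("zero shear variance", wrn)))
  # noisy planted gradient recovered within sampling error
  set.seed(9)
  n <- 500
  taus <- runif(n, 0, 2)
  noisy <- data.frame(cell_id = 1:n, region = "capillary",
                      segment_id = NA_integer_,
                      scalar_product = -0.4 * taus + rnorm(n, 0, 0.1))
  flow3 <- list(segments = data.frame(segment_id = NA_integer_, tau = NA_real_))
  # bypass the segment join by supplying tau directly through a fake flow
  noisy$segment_id <- 1:n
  flow3$segments <- data.frame(segment_id = 1:n, tau = taus)
  fit3 <- shear_regressions(noisy, flow3)
  g3 <- fit3$gradient[fit3$region == "all" & fit3$stratum == "pooled"]
  expect_lt(abs(g3 - (-0.4)), 0.03)
})

test_that("axis projection separates dorsal and ventral polarity", {
  cells <- data.frame(cell_id = 1:2, px = c(0, 3), py = c(-5, 0))
  pr <- axis_projection(cells, c(0, -1))
  expect_equal(pr$projection, c(5, 0))
  expect_equal(pr$frac_dorsal, 0.5)
  expect_equal(pr$frac_zero, 0.5)
  expect_warning(axis_projection(cells, c(0, -2)), "normalizing")
  # planted 70/30 dorsal mixture recovered at binomial accuracy
  set.seed(11)
  n <- 400
  up <- runif(n) < 0.7
  cells2 <- data.frame(cell_id = 1:n,
                       px = rnorm(n), py = ifelse(up, -abs(rnorm(n)) - 0.1,
                                                  abs(rnorm(n)) + 0.1))
  pr2 <- axis_projection(cells2, c(0, -1))
  expect_lt(abs(pr2$frac_dorsal - 0.7), 3 * sqrt(0.7 * 0.3 / n))
})

test_that("rotating the whole frame leaves polarity statistics unchanged", {
  w <- small_world()
  cells1 <- angle_and_scalar(assign_to_segments(w$cells, w$net), w$net, w$flow)
  rot <- rotate_world(w$net, w$cells, 0.7)
  flow2 <- solve_haemodynamics(rot$net, boundary_conditions(
    w$net$meta$inlets, w$net$meta$outlets, 60, 0, 3.5e-3))
  cells2 <- angle_and_scalar(assign_to_segments(rot$cells, rot$net), rot$net, flow2)
  ok <- !is.na(cells1$theta_deg) & !is.na(cells2$theta_deg)
  expect_gt(mean(ok), 0.9)
  expect_equal(cells2$theta_deg[ok], cells1$theta_deg[ok], tolerance = 1e-9)
  expect_equal(cells2$scalar_product[ok], cells1$scalar_product[ok],
               tolerance = 1e-9)
  s1 <- region_stats(cells1)$by_region
  s2 <- region_stats(cells2)$by_region
  expect_equal(s2$frac_against, s1$frac_against, tolerance = 1e-9)
})

test_that("misalignment comparisons detect planted low-shear depolarization", {
  w <- small_world()
  cells <- angle_and_scalar(assign_to_segments(w$cells, w$net), w$net, w$flow)
  cls <- classify_flow(w$net, w$flow)
  lab <- cls$label[match(cells$segment_id, cls$segment_id)]
  # plant smaller polarity vectors on low-shear segments
  cells$pmag[lab %in% "low"] <- cells$pmag[lab %in% "low"] * 0.4
  profiles <- detect_profiles(w$net)
  res <- misalignment_near_regression(cells, w$net, w$flow, profiles,
                                      n_perm = 499, seed = 3)
  expect_identical(res$shear$magnitude$direction, "group1 < group0")
  expect_lt(res$shear$magnitude$p_value, 0.01)
  # single group only: skipped with a warning
  cells_high <- cells[lab %in% "high", ]
  wrn <- capture_warnings(
    misalignment_near_regression(cells_high, w$net, w$flow,
                                 profiles[0, ], n_perm = 99, seed = 1))
  expect_true(any(grepl("skipped", wrn)))
})
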