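test_that("normalized density reproduces hand arithmetic", {
  atl <- toy_atlas(c(A = 2000, B = 4000, C = 4000))
  pts <- rbind(make_points(rep("A", 10)), make_points(rep("B", 30)),
               make_points(rep("C", 60)))
  pts$y_um <- (match(pts$lobule, c("A", "B", "C")) - 1) * 1000 + 50
  prof <- normalized_density(pts, atl)
  s <- prof$summary[match(c("A", "B", "C"), prof$summary$zone), ]
  expect_equal(s$mean_fraction, c(0.1, 0.3, 0.6))
  expect_equal(s$mean_density, c(5.0e-5, 7.5e-5, 1.5e-4))
})

test_that("single-lobule and zero-count edge cases behave", {
  atl <- toy_atlas(c(A = 2500, B = 1000))
  pts <- make_points(rep("A", 12))
  prof <- normalized_density(pts, atl)
  sA <- prof$summary[prof$summary$zone == "A", ]
  sB <- prof$summary[prof$summary$zone == "B", ]
  expect_equal(sA$mean_fraction, 1)
  expect_equal(sA$mean_density, 1 / 2500)
  expect_equal(sB$mean_density, 0)
  expect_error(normalized_density(make_points("nope"), atl), "not in the atlas")
})

test_that("per-mouse fractions sum to one over included lobules", {
  cfg <- gen_config(seed = 21)
  an <- gen_anatomy(cfg, n_mice = 5)
  for (cloud in list(an$inputs, an$outputs)) {
    prof <- normalized_density(cloud, cfg$atlas)
    sums <- tapply(prof$per_mouse$fraction, prof$per_mouse$mouse_id, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
  }
})

test_that("sub-lobule split follows the mediolateral thresholds", {
  atl <- cb_atlas()
  pts <- data.frame(
    x_um = c(3500, 2000, 2500, -3300),
    y_um = c(1300, 100, 100, 1300), z_um = 100,
    hemisphere = c("R", "R", "R", "L"),
    lobule = c("Crus 1", "SIM", "SIM", "Crus 1"),
    mouse_id = "m1", stringsAsFactors = FALSE)
  sp <- split_sublobules(pts, atl)
  expect_equal(sp$zone[1], "lat-Crus 1")   # 3.5 mm vs 3.2 mm threshold
  expect_equal(sp$zone[2], "med-SIM")      # 2.0 mm vs 2.5 mm threshold
  expect_equal(sp$zone[3], "lat-SIM")      # exactly at threshold -> lateral
  expect_equal(sp$zone[4], "lat-Crus 1")   # left hemisphere, |x| used
})

test_that("sub-lobule split partitions each splittable lobule", {
  cfg <- gen_config(seed = 13)
  an <- gen_anatomy(cfg, n_mice = 3)
  sp <- split_sublobules(an$inputs, cfg$atlas)
  for (lb in names(cfg$atlas$splits)) {
    n_all <- sum(sp$lobule == lb)
    n_med <- sum(sp$zone == paste0("med-", lb))
    n_lat <- sum(sp$zone == paste0("lat-", lb))
    expect_equal(n_med + n_lat, n_all)
  }
})

test_that("region classification applies the conjunctive threshold", {
  mk <- function(dens) list(summary = data.frame(
    zone = names(dens), mean_density = as.numeric(dens),
    stringsAsFactors = FALSE))
  cl <- classify_regions(mk(c(a = 5e-11, b = 5e-11, c = 0, d = 0)),
                         mk(c(a = 3e-11, b = 0, c = 3e-11, d = 0)),
                         theta = 1e-11)
  expect_equal(as.character(cl$region), c("conjunction", "input-dominant",
                                          "output-dominant", "excluded"))
  # mismatched zone sets are an error
  expect_error(classify_regions(mk(c(a = 1)), mk(c(b = 1))), "different zone")
})

test_that("region classification is monotone in input density", {
  # raising a zone's input density can only move it toward (never away
  # from) the input-carrying classes
  rank_in <- c(excluded = 0, `output-dominant` = 0,
               `input-dominant` = 1, conjunction = 1)
  mk <- function(dens) list(summary = data.frame(
    zone = names(dens), mean_density = as.numeric(dens),
    stringsAsFactors = FALSE))
  set.seed(4)
  for (rep in 1:50) {
    d_in <- 10^runif(4, -13, -9); d_out <- 10^runif(4, -13, -9)
    names(d_in) <- names(d_out) <- letters[1:4]
    before <- classify_regions(mk(d_in), mk(d_out))
    d_in[2] <- d_in[2] * 100
    after <- classify_regions(mk(d_in), mk(d_out))
    expect_gte(rank_in[as.character(after$region[2])],
               rank_in[as.character(before$region[2])])
    # the other zones are untouched
    expect_equal(as.character(after$region[-2]),
                 as.character(before$region[-2]))
  }
})

test_that("defaults reproduce the fastigial-pathway region memberships", {
  cfg <- gen_config(seed = 11)
  an <- gen_anatomy(cfg, n_mice = 4)
  cl <- classify_regions(
    normalized_density(an$inputs, cfg$atlas, hemisphere = "combine"),
    normalized_density(an$outputs, cfg$atlas, hemisphere = "R"))
  region_of <- setNames(as.character(cl$region), cl$zone)
  expect_setequal(names(region_of)[region_of == "conjunction"],
                  c("med-SIM", "med-Crus 1", "med-Crus 2", "Lob VII"))
  expect_setequal(names(region_of)[region_of == "input-dominant"],
                  c("lat-SIM", "lat-Crus 1", "lat-Crus 2", "PRM"))
  expect_setequal(names(region_of)[region_of == "excluded"],
                  c("Lob I", "PFL", "FL"))
})

test_that("KDE equals the brute-force kernel sum", {
  set.seed(8)
  pts <- data.frame(x_um = runif(50, 0, 200), y_um = runif(50, 0, 200),
                    z_um = runif(50, 0, 200),
                    mouse_id = sample(c("m1", "m2", "m3"), 50, replace = TRUE))
  got <- kde_map(pts, c(20, 20, 20))
  want <- kde_bruteforce(pts, c(20, 20, 20))
  expect_lt(max(abs(got - want) / want), 1e-10)
})

test_that("KDE has its mode at a lone datum and respects symmetry", {
  one <- data.frame(x_um = c(0, 30, 60), y_um = 0, z_um = 0, mouse_id = "m1")
  d <- kde_map(one)
  expect_equal(which.max(d), 2L)  # middle point closest to the others
  pair <- data.frame(x_um = c(-40, 40), y_um = 0, z_um = 0, mouse_id = "m1")
  dp <- kde_map(pair)
  expect_equal(dp[1], dp[2])
  expect_error(kde_map(pair, c(0, 20, 20)))
})

test_that("voxelization bins by floor(coordinate/edge) and conserves counts", {
  p1 <- data.frame(x_um = 50, y_um = 50, z_um = 50)
  g <- voxelize(p1, p1[0, ], edge_um = 100)
  expect_equal(g[, c("ix", "iy", "iz")], data.frame(ix = 0L, iy = 0L, iz = 0L))
  expect_equal(voxelize(p1[0, ], p1[0, ])$input_n, numeric(0))

  set.seed(5)
  pts <- data.frame(x_um = runif(1000, -500, 500), y_um = runif(1000, 0, 900),
                    z_um = runif(1000, 0, 300))
  g <- voxelize(pts, pts[0, ], edge_um = 100)
  expect_equal(sum(g$input_n), 1000)
  expect_equal(sum(g$input_strength), 1)
  # brute-force per-point loop
  key <- paste(floor(pts$x_um / 100), floor(pts$y_um / 100),
               floor(pts$z_um / 100))
  want <- table(key)
  got <- setNames(g$input_n, paste(g$ix, g$iy, g$iz))
  expect_equal(sort(got[names(want)]), sort(as.numeric(want)[order(names(want))]),
               ignore_attr = TRUE)
  expect_equal(unname(got[names(want)]), as.numeric(want))
})

test_that("connectivity-activity model identifies the generative predictor", {
  set.seed(6)
  n <- 500
  grid <- data.frame(ix = 1:n, iy = 0L, iz = 0L)
  grid$input_strength <- runif(n); grid$output_strength <- runif(n)
  grid$n_units <- 5L
  noise <- rnorm(n, sd = 0.02)
  # multiplicative structure
  g1 <- grid
  g1$frac_selective <- 2 * g1$input_strength * g1$output_strength + noise
  g1$mean_amp <- g1$frac_selective
  m1 <- connectivity_activity_model(g1)
  expect_equal(m1$predictor[m1$winner & m1$activity == "frac_selective"],
               "product")
  # input-only structure
  g2 <- grid
  g2$frac_selective <- g2$input_strength + noise
  g2$mean_amp <- g2$frac_selective
  m2 <- connectivity_activity_model(g2)
  r2 <- setNames(m2$cv_r2[m2$activity == "frac_selective"],
                 m2$predictor[m2$activity == "frac_selective"])
  expect_gt(r2["input"], r2["output"])
  # activity independent of connectivity
  g3 <- grid
  g3$frac_selective <- rnorm(n)
  g3$mean_amp <- g3$frac_selective
  m3 <- connectivity_activity_model(g3)
  expect_true(all(abs(m3$cv_r2) <= 0.05))
  # degenerate predictor flagged as undefined
  g4 <- g2; g4$output_strength <- 0.5
  m4 <- connectivity_activity_model(g4)
  expect_true(all(is.na(m4$cv_r2[m4$predictor == "output"])))
})
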