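# segmentation, bone labeling, location grid, thickness/density maps

shell_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- generate_skull_phantom(
        small_shell_spec(suture_gaps = default_suture_bands()),
        n_locations = 642L)
      mask <- segment_calvaria(ph$volume)
      mask <- label_bones(mask)
      grid <- build_location_grid(mask, n_locations = 642L)
      cache <<- list(ph = ph, mask = mask, grid = grid)
    }
    cache
  }
})

test_that("an all-air volume yields a 'no bone found' error", {
  vol <- new_volume(array(-1000, c(8, 8, 8)), c(1, 1, 1))
  expect_error(segment_calvaria(vol), "no bone found")
})

test_that("segmentation of a clean shell matches the brute-force count", {
  ph <- generate_skull_phantom(small_shell_spec(), n_locations = 12L)
  mask <- segment_calvaria(ph$volume, close_mm = 0)
  brute <- sum(ph$volume$values >= 150)
  expect_lt(abs(sum(mask$mask) - brute) / brute, 0.02)
})

test_that("only the largest of two disjoint components is retained", {
  vals <- array(-1000, c(30, 10, 10))
  vals[2:11, 2:9, 2:9] <- 1000          # 10 x 8 x 8 = 640 voxels
  vals[20:21, 2:5, 2:9] <- 1000         # 2 x 4 x 8 = 64 voxels
  vol <- new_volume(vals, c(1, 1, 1))
  mask <- segment_calvaria(vol, close_mm = 0)
  expect_equal(sum(mask$mask), 640)
  expect_false(any(mask$mask[20:21, , ]))
})

test_that("bone labels form the five-bone partition plus sutures", {
  fx <- shell_fixture()
  lab <- fx$mask$levels[fx$mask$bone_labels[fx$mask$mask]]
  expect_setequal(unique(lab),
                  c("frontal_L", "frontal_R", "parietal_L", "parietal_R",
                    "occipital", "suture"))
  counts <- table(lab)
  # mirror symmetry of the construction
  expect_lt(abs(counts[["frontal_L"]] - counts[["frontal_R"]]) /
              counts[["frontal_R"]], 0.01)
  expect_lt(abs(counts[["parietal_L"]] - counts[["parietal_R"]]) /
              counts[["parietal_R"]], 0.01)
})

test_that("suture voxels are excluded from bone summaries", {
  fx <- shell_fixture()
  maps <- compute_calvaria_maps(fx$ph$volume, fx$mask, fx$grid)
  expect_true(any(maps$bone == "suture"))
  s <- summarize_bones(maps)
  n_bone <- sum(maps$valid & maps$bone %in%
                  c("frontal_L", "frontal_R", "parietal_L", "parietal_R",
                    "occipital"))
  expect_equal(s$n_locations[s$region == "global"], n_bone)
})

test_that("labeling requires orientation metadata", {
  fx <- shell_fixture()
  broken <- fx$mask
  broken$orientation <- NULL
  expect_error(label_bones(broken), "orientation")
})

test_that("the location grid is deterministic with the configured size", {
  fx <- shell_fixture()
  again <- build_location_grid(fx$mask, n_locations = 642L)
  expect_identical(fx$grid$bone, again$bone)
  expect_identical(fx$grid$directions, again$directions)
  big <- build_location_grid(fx$mask, n_locations = 2562L)
  expect_equal(big$n, 2562L)
  expect_equal(nrow(big$directions), 2562L)
})

test_that("grid labels and maps are equivariant under a 90-degree rotation", {
  fx <- shell_fixture()
  vals <- fx$ph$volume$values
  nd <- dim(vals)
  expect_equal(nd[1], nd[2])  # square in-plane by construction
  # rotate the array by 90 degrees about z and declare the rotation in the
  # orientation metadata; canonical-frame results must be unchanged
  rot_vals <- aperm(vals[nd[1]:1, , , drop = FALSE], c(2, 1, 3))
  R <- matrix(c(0, -1, 0,
                1, 0, 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  rot_vol <- new_volume(rot_vals, spacing = fx$ph$volume$spacing,
                        origin = fx$ph$volume$origin, orientation = R)
  rq <- quantify_volume(rot_vol, n_locations = 642L)
  oq <- quantify_volume(fx$ph$volume, n_locations = 642L)
  expect_gt(mean(rq$grid$bone == oq$grid$bone), 0.99)
  both <- rq$maps$valid & oq$maps$valid
  expect_gt(mean(both), 0.99)
  expect_lt(mean(abs(rq$maps$thickness_mm[both] -
                       oq$maps$thickness_mm[both])), 0.2)
  expect_lt(mean(abs(rq$maps$density_hu[both] -
                       oq$maps$density_hu[both])), 5)
})

test_that("shell thickness is recovered and scales linearly", {
  fx <- shell_fixture()
  th <- compute_local_thickness(fx$mask, fx$grid)
  expect_true(all(th$thickness_mm[th$valid] >= 0))
  expect_lt(abs(mean(th$thickness_mm[th$valid]) - 3), 0.6)
  ph2 <- generate_skull_phantom(small_shell_spec(thickness = 6),
                                n_locations = 162L)
  q2 <- quantify_volume(ph2$volume, n_locations = 162L)
  m1 <- mean(th$thickness_mm[th$valid])
  m2 <- mean(q2$maps$thickness_mm[q2$maps$valid])
  expect_lt(abs(m2 / m1 - 2), 0.15)
})

test_that("rays that miss the mask are flagged invalid", {
  # upper-hemisphere-only shell: downward rays have nothing to hit
  spec <- small_shell_spec(
    thickness = function(az, el) ifelse(el > 10, 3, 0))
  ph <- generate_skull_phantom(spec, n_locations = 162L)
  mask <- label_bones(segment_calvaria(ph$volume))
  grid <- build_location_grid(mask, n_locations = 162L)
  th <- compute_local_thickness(mask, grid)
  down <- grid$elevation < -30
  expect_true(any(down))
  expect_true(all(!th$valid[down]))
  expect_true(any(th$valid[grid$elevation > 30]))
})

test_that("a constant-density shell reads back exactly", {
  ph <- generate_skull_phantom(small_shell_spec(density = 800),
                               n_locations = 162L)
  q <- quantify_volume(ph$volume, n_locations = 162L)
  ok <- q$maps$valid
  expect_true(all(abs(q$maps$density_hu[ok] - 800) <= 1))
})

test_that("a half-and-half density shell resolves both sides", {
  spec <- small_shell_spec(
    density = function(az, el) ifelse(az > 0, 500, 900))
  ph <- generate_skull_phantom(spec, n_locations = 162L)
  mask <- label_bones(segment_calvaria(ph$volume))
  grid <- build_location_grid(mask, n_locations = 162L)
  de <- compute_local_density(ph$volume, mask, grid, n_subrays = 1L)
  left <- de$valid & grid$azimuth > 10
  right <- de$valid & grid$azimuth < -10
  expect_lt(abs(mean(de$density_hu[left]) - 500), 5)
  expect_lt(abs(mean(de$density_hu[right]) - 900), 5)
})

test_that("maps are deterministic given identical inputs", {
  fx <- shell_fixture()
  a <- compute_calvaria_maps(fx$ph$volume, fx$mask, fx$grid)
  b <- compute_calvaria_maps(fx$ph$volume, fx$mask, fx$grid)
  expect_identical(a, b)
})

test_that("metric accuracy under default degradation stays within bounds", {
  for (sp in list(c(0.5, 0.5, 1.5), c(1, 1, 1))) {
    spec <- phantom_spec(outer_radii = c(38, 38, 38), thickness_field = 3,
                         density_field = 800, spacing = sp, rng_seed = 7L)
    ph <- generate_skull_phantom(spec, n_locations = 162L)
    q <- quantify_volume(ph$volume, n_locations = 162L)
    tr <- ph$truth
    sel <- q$maps$valid & tr$bone != "suture" & q$maps$bone != "suture"
    th_mae <- mean(abs(q$maps$thickness_mm[sel] - tr$thickness_mm[sel]))
    de_mae <- mean(abs(q$maps$density_hu[sel] - tr$density_hu[sel]))
    expect_lt(th_mae, max(0.6, 0.15 * 3))
    expect_lt(de_mae, 10)
  }
})

test_that("uniform maps give per-bone means equal to the global mean", {
  fx <- shell_fixture()
  maps <- compute_calvaria_maps(fx$ph$volume, fx$mask, fx$grid)
  maps$thickness_mm[maps$valid] <- 3.21
  maps$density_hu[maps$valid] <- 777
  s <- summarize_bones(maps)
  expect_true(all(abs(s$thickness_mm - 3.21) < 1e-12))
  expect_true(all(abs(s$density_hu - 777) < 1e-12))
})

test_that("the global mean is the location-weighted mean of bone regions", {
  fx <- shell_fixture()
  maps <- compute_calvaria_maps(fx$ph$volume, fx$mask, fx$grid)
  s <- summarize_bones(maps)
  regions <- c("frontal", "parietal", "occipital")
  w <- s$n_locations[match(regions, s$region)]
  m <- s$density_hu[match(regions, s$region)]
  expect_equal(sum(w * m) / sum(w),
               s$density_hu[s$region == "global"])
  expect_equal(sum(w), s$n_locations[s$region == "global"])
})

test_that("side-resolved summaries appear when a fused side is given", {
  fx <- shell_fixture()
  maps <- compute_calvaria_maps(fx$ph$volume, fx$mask, fx$grid)
  s <- summarize_bones(maps, ucc_fused_side = "left")
  expect_true(all(c("frontal_fused_side", "frontal_open_side",
                    "parietal_fused_side", "parietal_open_side")
                  %in% s$region))
  fused <- s[s$region == "frontal_fused_side", ]
  open <- s[s$region == "frontal_open_side", ]
  joint <- s[s$region == "frontal", ]
  expect_equal(fused$n_locations + open$n_locations, joint$n_locations)
})

test_that("a region with no valid locations propagates missing values", {
  maps <- data.frame(location = 1:4, azimuth = 0, elevation = 0,
                     bone = c("frontal_L", "frontal_R", "suture", "none"),
                     thickness_mm = 3, density_hu = 800,
                     valid = c(TRUE, TRUE, TRUE, FALSE))
  s <- summarize_bones(maps)
  expect_true(is.na(s$thickness_mm[s$region == "occipital"]))
  expect_equal(s$n_locations[s$region == "occipital"], 0)
})
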