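test_that("slice decomposition matches a flood-fill oracle", {
  m <- array(FALSE, c(12, 12, 3))
  expect_length(slice_components(m), 0)
  m[2:4, 2:4, 2] <- TRUE
  m[8:10, 8:10, 2] <- TRUE
  comps <- slice_components(m)
  expect_length(comps, 2)
  expect_equal(max(brute_flood_labels(m[, , 2])), 2L)
  # a tube crossing 10 slices: one component per slice
  sp <- phantom_spec(shape = c(16, 16, 12), seed = 1)
  cl <- make_centerlines(straight_curve(c(7, 7, 0), c(7, 7, 11), r = 2))
  tube <- rasterize_vessels(cl, sp)
  comps <- slice_components(tube)
  expect_equal(length(comps), 12)
  expect_equal(sort(unique(vapply(comps, function(c) c$z, 1L))), 1:12)
})

test_that("adaptive windows follow the margin formula, clip, and grow with size", {
  cfg <- refine_config(min_margin = 5)
  comp <- list(id = 1L, z = 10L, voxels = cbind(x = 20, y = 20, z = 10),
               bbox = c(xmin = 20, xmax = 20, ymin = 20, ymax = 20))
  w <- adaptive_window(comp, cfg, c(64, 64, 64))
  b <- w$bounds
  expect_equal(unname(b[c("xmax", "ymax")] - b[c("xmin", "ymin")] + 1),
               c(11, 11))
  expect_equal(unname(b["zmax"] - b["zmin"] + 1), 3)
  # corner component: clipped but still contains the component
  corner <- list(id = 1L, z = 1L, voxels = cbind(x = 1, y = 1, z = 1),
                 bbox = c(xmin = 1, xmax = 1, ymin = 1, ymax = 1))
  wc <- adaptive_window(corner, cfg, c(64, 64, 64))
  expect_equal(unname(wc$bounds[c("xmin", "ymin", "zmin")]), c(1, 1, 1))
  # monotone growth of the window with component size
  set.seed(1)
  sides <- sort(sample(1:30, 6))
  areas <- vapply(sides, function(s) {
    cm <- list(id = 1L, z = 32L, voxels = NULL,
               bbox = c(xmin = 30, xmax = 30 + s - 1, ymin = 30,
                        ymax = 30 + s - 1))
    bb <- adaptive_window(cm, cfg, c(128, 128, 64))$bounds
    (bb[["xmax"]] - bb[["xmin"]] + 1) * (bb[["ymax"]] - bb[["ymin"]] + 1)
  }, 1)
  expect_true(all(diff(areas) > 0))
})

test_that("local threshold is the exact class-mean midpoint", {
  vol <- volume3d(array(100, c(10, 10, 3)))
  lab <- array(FALSE, c(10, 10, 3))
  vol$data[4:6, 4:6, 2] <- 200
  lab[4:6, 4:6, 2] <- TRUE
  win <- structure(list(component = NULL,
                        bounds = c(xmin = 1, xmax = 10, ymin = 1, ymax = 10,
                                   zmin = 1, zmax = 3)),
                   class = "component_window")
  thr <- local_threshold(vol, win, lab)
  expect_equal(thr$T, 150)
  expect_true(thr$usable)
  # degenerate equal means: flagged unusable
  vol2 <- volume3d(array(100, c(10, 10, 3)))
  thr2 <- local_threshold(vol2, win, lab)
  expect_equal(thr2$T, 100)
  expect_false(thr2$usable)
  # empty class: NULL
  expect_null(local_threshold(vol, win, array(FALSE, c(10, 10, 3))))
})

test_that("local thresholds on phantom windows lie strictly between class means", {
  ph <- generate_phantom(phantom_spec(shape = c(32, 32, 32), seed = 21))
  vol <- ph$volume
  comps <- slice_components(ph$truth)
  cfg <- refine_config()
  n_checked <- 0
  for (cm in comps[seq(1, length(comps), by = 3)]) {
    win <- adaptive_window(cm, cfg, dim(vol$data))
    thr <- local_threshold(vol, win, ph$truth$mask)
    if (is.null(thr) || !thr$usable) next
    expect_gt(thr$T, thr$mu_o)
    expect_lt(thr$T, thr$mu_b)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 5)
})

test_that("seed generation respects the threshold and finds missed thin vessels", {
  # thick vessel (caught) next to a thin one (missed)
  sp <- phantom_spec(shape = c(24, 24, 24), noise_sd = 0,
                     class_sds = c(background = 2, tissue = 3, vessel = 3,
                                   shell = 3),
                     bias_coefs = c(x = 0), skull_shell = FALSE, seed = 2)
  thick <- straight_curve(c(10, 10, 2), c(10, 10, 21), r = 2.5, label = 1L)
  thin <- straight_curve(c(15, 10, 2), c(15, 10, 21), r = 1, label = 2L)
  truth <- rasterize_vessels(make_centerlines(thick, thin), sp)
  vol <- synthesize_volume(truth, sp)$volume
  initial <- rasterize_vessels(make_centerlines(thick), sp)$mask
  comps <- slice_components(initial)
  cfg <- refine_config()
  found_in_thin <- FALSE
  thin_mask <- rasterize_vessels(make_centerlines(thin), sp)$mask
  for (cm in comps) {
    win <- adaptive_window(cm, cfg, dim(vol$data))
    thr <- local_threshold(vol, win, initial)
    if (is.null(thr) || !thr$usable) next
    seeds <- generate_seeds(vol, win, thr, initial, cfg)
    expect_true(all(vol$data[seeds] >= thr$T)) # seeds within supra-T set
    if (any(thin_mask[seeds])) found_in_thin <- TRUE
  }
  expect_true(found_in_thin)
  # window where all supra-threshold voxels are already labeled: no seeds
  win1 <- adaptive_window(comps[[5]], cfg, dim(vol$data))
  thr1 <- local_threshold(vol, win1, truth$mask)
  seeds1 <- generate_seeds(vol, win1, thr1, truth$mask, cfg)
  expect_true(all(!truth$mask[seeds1]))
})

test_that("region growing equals thresholded flood fill from the seed", {
  sp <- phantom_spec(shape = c(20, 20, 20), noise_sd = 0,
                     class_sds = c(background = 0, tissue = 0, vessel = 0,
                                   shell = 0),
                     bias_coefs = c(x = 0), skull_shell = FALSE, seed = 1)
  tube <- rasterize_vessels(
    make_centerlines(straight_curve(c(9, 9, 2), c(9, 9, 17), r = 2)), sp)
  vol <- synthesize_volume(tube, sp)$volume
  seed_idx <- which(tube$mask)[1]
  tmap <- array(150, c(20, 20, 20))
  init <- array(FALSE, c(20, 20, 20))
  grown <- region_grow(vol, seed_idx, tmap, init)
  # oracle: connected component of {q >= 150} containing the seed
  supra <- vol$data >= 150
  lab <- brute_flood_labels(supra)
  expect_identical(grown$mask, lab == lab[seed_idx])
  # no seeds: identity
  expect_identical(region_grow(vol, integer(0), tmap, tube$mask)$mask,
                   tube$mask)
  # refinement only adds
  expect_true(all(grown$mask[init]))
})

test_that("refinement improves the segmentation and terminates", {
  sp <- phantom_spec(shape = c(48, 48, 48), radius_range = c(0.75, 3),
                     seed = 31)
  ph <- generate_phantom(sp)
  bc <- correct_bias(ph$volume)
  sm <- ggmrf_smooth(bc$volume)
  brain <- strip_skull(sm)
  mod <- fit_lcdg(empirical_density(sm, mask = brain))
  init <- classify_initial(sm, mod, mask = brain)
  lut <- lcdg_decision(mod)
  gt <- min(which(lut)) - 1
  fin <- refine_segmentation(sm, init, global_threshold = gt, mask = brain)
  e0 <- evaluate_segmentation(init, ph$truth)
  e1 <- evaluate_segmentation(fin, ph$truth)
  expect_gt(e1$dsc, e0$dsc)
  expect_gte(e1$dsc, 90)
  # monotone growth invariant
  expect_true(all(fin$mask[init$mask]))
  # small-vessel sensitivity improves
  dmap_truth <- distance_transform(ph$truth)
  small <- ph$truth$mask & dmap_truth <= 1.5
  expect_gt(sum(fin$mask[small]) / sum(small),
            sum(init$mask[small]) / sum(small))
  # idempotence: re-running adds nothing
  fin2 <- refine_segmentation(sm, fin, global_threshold = gt, mask = brain)
  expect_identical(fin2$mask, fin$mask)
})

test_that("empty initial mask on a vessel-free volume stays empty", {
  vol <- volume3d(array(30, c(16, 16, 16)))
  init <- vessel_mask(array(FALSE, c(16, 16, 16)))
  fin <- refine_segmentation(vol, init)
  expect_false(any(fin$mask))
})
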