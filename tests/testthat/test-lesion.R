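test_that("connected components follow 26-connectivity", {
  arr <- array(0L, c(12, 12, 12))
  arr[2:3, 2:3, 2:3] <- 1L          # cube of 8
  arr[8:10, 8:10, 8:10] <- 1L       # cube of 27
  vent <- array(0L, c(12, 12, 12)); vent[6, , ] <- 1L
  sc <- lesion_scene(voxel_grid(arr), voxel_grid(vent))
  lb <- label_components(sc)
  expect_equal(nrow(lb$lesions), 2)
  expect_equal(lb$lesions$voxels, c(27L, 8L))   # sorted by descending volume

  diag_arr <- array(0L, c(6, 6, 6))
  diag_arr[2, 2, 2] <- 1L
  diag_arr[3, 3, 3] <- 1L           # corner contact only
  sc2 <- lesion_scene(voxel_grid(diag_arr), voxel_grid(vent[1:6, 1:6, 1:6]))
  expect_equal(nrow(label_components(sc2)$lesions), 1)

  empty <- lesion_scene(voxel_grid(array(0L, c(6, 6, 6))),
                        voxel_grid(array(c(1L, rep(0L, 215)), c(6, 6, 6))))
  expect_equal(nrow(label_components(empty)$lesions), 0)
})

test_that("the distance transform agrees with brute force on random masks", {
  set.seed(21)
  for (rep in 1:5) {
    spacing <- sample(list(c(1, 1, 1), c(0.7, 1, 1.4), c(2, 1, 1)), 1)[[1]]
    mask <- array(as.integer(runif(14 * 12 * 10) < 0.05), c(14, 12, 10))
    if (!any(mask == 1)) mask[3, 3, 3] <- 1L
    dt <- distance_transform(voxel_grid(mask, spacing))
    probe <- array(0L, dim(mask))
    probe[mask == 0] <- 1L
    expected <- brute_min_distance(probe, mask, spacing)
    expect_equal(dt[probe == 1], expected, tolerance = 1e-9)
    expect_true(all(dt[mask == 1] == 0))
  }
})

test_that("morphometry reproduces unit-step and containment distances", {
  arr <- array(0L, c(10, 10, 10)); vent <- array(0L, c(10, 10, 10))
  vent[5, , ] <- 1L
  arr[6, 4, 4] <- 1L                  # adjacent to the ventricle plane
  sc <- lesion_scene(voxel_grid(arr), voxel_grid(vent))
  mo <- morphometry(label_components(sc), sc)
  expect_equal(mo$min_distance, 1)

  arr2 <- array(0L, c(10, 10, 10)); arr2[5, 4, 4] <- 1L   # inside ventricle
  sc2 <- lesion_scene(voxel_grid(arr2), voxel_grid(vent))
  expect_equal(morphometry(label_components(sc2), sc2)$min_distance, 0)

  sc3 <- lesion_scene(voxel_grid(arr), voxel_grid(array(0L, c(10, 10, 10))))
  expect_error(morphometry(label_components(sc3), sc3), "ventricle")
})

test_that("principal axes recover planted ellipsoid dimensions", {
  specs <- data.frame(cx = 16, cy = 16, cz = 16, ax = 6, ay = 3, az = 2)
  sc <- gen_lesion_scene(specs, shape = c(32L, 32L, 32L),
                         ventricle_halfwidth = 2)
  mo <- morphometry(label_components(sc), sc)
  expect_equal(mo$axis1, 12, tolerance = 1 / 12)   # within one 1-mm voxel
  expect_equal(mo$axis2, 6, tolerance = 1 / 6)
  expect_equal(mo$axis3, 4, tolerance = 1 / 4)
  expect_equal(c(mo$centroid_x, mo$centroid_y, mo$centroid_z),
               c(16, 16, 16), tolerance = 0.05)
})

test_that("classification respects the inclusive 8-mm rule and conserves volume", {
  lesions <- data.frame(label = 1:4, voxels = c(10L, 10L, 10L, 10L),
                        volume = c(10, 20, 30, 40),
                        min_distance = c(0, 7.9, 8.0, 8.1))
  cl <- classify_lesions(lesions)
  expect_equal(as.character(cl$lesions$class),
               c("periventricular", "periventricular", "periventricular",
                 "deep"))
  expect_equal(unname(cl$volumes["pwmh"]), 60)
  expect_equal(unname(cl$volumes["dwmh"]), 40)
  expect_equal(unname(cl$volumes["total"]),
               unname(cl$volumes["pwmh"] + cl$volumes["dwmh"]))
  # raising the threshold never decreases periventricular volume
  v8 <- classify_lesions(lesions, 8)$volumes["pwmh"]
  v10 <- classify_lesions(lesions, 10)$volumes["pwmh"]
  expect_gte(v10, v8)
})

test_that("distances scale with voxel spacing", {
  arr <- array(0L, c(10, 10, 10)); vent <- array(0L, c(10, 10, 10))
  vent[2, , ] <- 1L; arr[8, 5, 5] <- 1L
  d1 <- morphometry(label_components(lesion_scene(voxel_grid(arr), voxel_grid(vent))),
                    lesion_scene(voxel_grid(arr), voxel_grid(vent)))$min_distance
  sc2 <- lesion_scene(voxel_grid(arr, spacing = c(2, 2, 2)),
                      voxel_grid(vent, spacing = c(2, 2, 2)))
  d2 <- morphometry(label_components(sc2), sc2)$min_distance
  expect_equal(d2, 2 * d1)
})

test_that("generated scenes classify to their intended classes", {
  set.seed(33)
  total_ok <- 0L; total <- 0L
  for (rep in 1:3) {
    specs <- random_lesion_specs()
    sc <- gen_lesion_scene(specs)
    tr <- attr(sc, "truth")
    # keep lesions with at least one voxel (1 mm) of margin from the rule
    keep <- abs(tr$analytic_gap - 8) > 1
    mo <- morphometry(label_components(sc), sc)
    cl <- classify_lesions(mo)
    # match lesions to specs by centroid proximity
    for (r in which(keep)) {
      i <- which.min((cl$lesions$centroid_x - tr$cx[r])^2 +
                     (cl$lesions$centroid_y - tr$cy[r])^2 +
                     (cl$lesions$centroid_z - tr$cz[r])^2)
      total <- total + 1L
      if (as.character(cl$lesions$class[i]) ==
          as.character(tr$intended_class[r])) total_ok <- total_ok + 1L
    }
    expect_equal(unname(cl$volumes["pwmh"] + cl$volumes["dwmh"]),
                 unname(cl$volumes["total"]))
  }
  expect_equal(total_ok, total)
})

test_that("Fazekas grouping follows the 0 / 1-3 / 4-6 partition", {
  expect_equal(as.character(fazekas_group(0, 0)), "HC")
  expect_equal(as.character(fazekas_group(1, 2)), "mild")
  expect_equal(as.character(fazekas_group(3, 3)), "severe")
  expect_equal(as.character(fazekas_group(2, 2)), "severe")
  expect_error(fazekas_group(4, 0), "0-3")
  expect_error(fazekas_group(total = 7), "0-6")
})
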