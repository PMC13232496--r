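pixel_image <- function(rgb_list, mask = NULL) {
  n <- length(rgb_list)
  px <- array(0, c(1, n, 3))
  for (j in seq_len(n)) px[1, j, ] <- rgb_list[[j]]
  rgb_image(px, mask = if (is.null(mask)) matrix(TRUE, 1, n) else mask)
}

test_that("image loading normalizes 8-bit channels to [0, 1]", {
  d <- withr::local_tempdir()
  px <- array(0, c(2, 2, 3))
  px[1, 1, ] <- 1          # white pixel
  px[2, 2, ] <- 128 / 255
  png::writePNG(px, file.path(d, "t.png"))
  img <- load_image(file.path(d, "t.png"))
  expect_equal(img$pixels[1, 1, ], c(1, 1, 1))
  expect_equal(img$pixels[2, 1, ], c(0, 0, 0))
  expect_equal(img$pixels[2, 2, ], rep(128 / 255, 3))
  # mask of the wrong shape is rejected
  png::writePNG(matrix(1, 3, 3), file.path(d, "m.png"))
  expect_error(load_image(file.path(d, "t.png"), file.path(d, "m.png")),
               "shape")
  expect_error(load_image(file.path(d, "missing.png")), "not found")
})

test_that("DTR rules classify reference pixels as printed", {
  img <- pixel_image(list(
    c(0.20, 0.60, 0.30),              # green: R < 0.9G, B < 0.9G
    c(150, 150, 100) / 255,           # fails green (R >= 0.9G), yellow box
    c(0.40, 0.40, 0.05)))             # fails green and yellow, necrotic box
  labs <- classify_pixels_dtr(img)$labels
  expect_equal(as.vector(labs), c("green", "yellow", "necrotic"))
})

test_that("classification needs a mask and respects it", {
  img <- pixel_image(list(c(0.2, 0.6, 0.3), c(0.2, 0.6, 0.3)))
  img$mask <- NULL
  expect_error(classify_pixels_dtr(img), "mask")
  img$mask <- matrix(c(TRUE, FALSE), 1, 2)
  cl <- classify_pixels_dtr(img)
  expect_equal(cl$counts$green, 1)
  expect_true(is.na(cl$labels[1, 2]))
})

test_that("label counts always partition the masked pixels", {
  for (s in 1:5) {
    gen <- generate_plant_image(image_truth(random_proportions(s), 700,
                                            seed = s), 40, 40)
    cl <- classify_pixels_dtr(gen$image)
    total <- cl$counts$green + cl$counts$yellow + cl$counts$necrotic +
      cl$counts$unclassified
    expect_equal(total, sum(gen$image$mask))
    q <- median_cut_quantize(gen$image)
    expect_equal(sum(q$sizes), sum(gen$image$mask))
  }
})

test_that("background masking recovers the planted mask and is monotone", {
  gen <- generate_plant_image(image_truth(c(0.6, 0.3, 0.1), 500, seed = 8),
                              30, 30)
  img <- gen$image
  img$mask <- NULL
  rec <- mask_background(img, gen$truth$background_color, tol = 0)
  expect_identical(rec$mask, gen$truth$mask)
  expect_error(mask_background(img, gen$truth$background_color, tol = 1),
               "every pixel")
  # background pixel count shrinks monotonically as tol decreases
  n_bg <- vapply(c(0.5, 0.2, 0.1, 0.02, 0),
                 function(tl) sum(!mask_background(img,
                   gen$truth$background_color, tol = tl)$mask), numeric(1))
  expect_true(all(diff(n_bg) <= 0))
})

test_that("damage statistic follows the printed formula", {
  expect_equal(damage_score(tissue_counts(850, 100, 50)), 0.15)
  expect_equal(damage_score(tissue_counts(500, 0, 0)), 0)
  expect_equal(damage_score(tissue_counts(0, 30, 20)), 1)
  # ratio is invariant to uniform scaling of the counts
  expect_equal(damage_score(tissue_counts(850 * 7, 100 * 7, 50 * 7)), 0.15)
  # unclassified pixels are excluded from the denominator
  expect_equal(damage_score(tissue_counts(850, 100, 50, unclassified = 999)),
               0.15)
  expect_error(damage_score(tissue_counts(0, 0, 0, 10)), "undefined")
})

test_that("median cut separates distinct colors exactly", {
  cols <- list(c(0.1, 0.7, 0.1), c(0.6, 0.45, 0.35), c(0.5, 0.3, 0.02))
  counts <- c(60, 25, 15)
  px <- array(0, c(10, 10, 3))
  cls <- rep(1:3, counts)
  for (ch in 1:3) {
    plane <- matrix(0, 10, 10)
    plane[seq_len(100)] <- vapply(cls, function(k) cols[[k]][ch], numeric(1))
    px[, , ch] <- plane
  }
  img <- rgb_image(px, mask = matrix(TRUE, 10, 10))
  q <- median_cut_quantize(img, 3)
  expect_equal(nrow(q$centroids), 3L)
  got <- q$centroids[order(q$sizes, decreasing = TRUE), ]
  expect_equal(unname(got), do.call(rbind, cols), tolerance = 1e-12)
  expect_equal(sort(q$sizes, decreasing = TRUE), c(60, 25, 15))
})

test_that("median cut degenerates gracefully on a single color", {
  px <- array(0.5, c(5, 5, 3))
  img <- rgb_image(px, mask = matrix(TRUE, 5, 5))
  q <- median_cut_quantize(img, 3)
  expect_equal(nrow(q$centroids), 1L)
  expect_equal(q$sizes, 25L)
})

test_that("median cut is deterministic", {
  gen <- generate_plant_image(image_truth(c(0.5, 0.3, 0.2), 600, seed = 21),
                              40, 40)
  q1 <- median_cut_quantize(gen$image)
  q2 <- median_cut_quantize(gen$image)
  expect_identical(q1, q2)
})

test_that("cluster-to-class mapping recovers fixture classes and ties break
           by class order", {
  gen <- generate_plant_image(image_truth(c(0.6, 0.25, 0.15), 500, seed = 2),
                              30, 30, jitter = FALSE)
  q <- median_cut_quantize(gen$image)
  counts <- assign_clusters_to_classes(q)
  expect_equal(c(counts$green, counts$yellow, counts$necrotic),
               as.numeric(gen$truth$counts))
  expect_equal(counts$unclassified, 0)
  # centroid matching no rule and equidistant from two prototypes picks the
  # earlier class in green < yellow < necrotic order
  proto <- rbind(green = c(0.2, 0.2, 0.2), yellow = c(0.4, 0.2, 0.2),
                 necrotic = c(0.9, 0.9, 0.9))
  q_fake <- structure(list(centroids = matrix(c(0.3, 0.2, 0.2), 1,
                                              dimnames = list(NULL, c("R", "G", "B"))),
                           labels = rep(1L, 10), sizes = 10L,
                           pixel_index = 1:10),
                      class = "quantization_result")
  tc <- assign_clusters_to_classes(q_fake, prototypes = proto)
  expect_equal(tc$green, 10)
})

test_that("DQU equals DTR on separable-color fixtures", {
  for (s in 1:8) {
    gen <- generate_plant_image(image_truth(random_proportions(300 + s), 600,
                                            seed = s), 40, 40, jitter = FALSE)
    dtr <- damage_score(classify_pixels_dtr(gen$image)$counts)
    dqu <- damage_score(assign_clusters_to_classes(
      median_cut_quantize(gen$image)))
    expect_identical(dqu, dtr)
  }
})

test_that("batch quantification processes a directory and skips corrupt files", {
  d <- withr::local_tempdir()
  truths <- numeric(10)
  for (i in 1:10) {
    gen <- generate_plant_image(image_truth(random_proportions(i), 400,
                                            seed = i), 30, 30)
    write_image_fixture(gen, file.path(d, sprintf("img%02d", i)))
    truths[i] <- sum(gen$truth$counts[c("yellow", "necrotic")]) /
      sum(gen$truth$counts)
  }
  writeLines("not a png", file.path(d, "corrupt.png"))
  out_csv <- file.path(d, "damage.csv")
  suppressMessages(
    tab <- batch_quantify(d, method = "both", mask_dir = d, out = out_csv))
  expect_equal(attr(tab, "n_skipped"), 1L)
  dtr <- tab[tab$method == "dtr", ]
  dqu <- tab[tab$method == "dqu", ]
  expect_equal(nrow(dtr), 10L)
  expect_equal(dtr$damage[order(dtr$image_id)], truths)
  # both methods agree on these fixtures, per-image
  expect_equal(dqu$damage[order(dqu$image_id)],
               dtr$damage[order(dtr$image_id)])
  expect_true(file.exists(out_csv))
  expect_error(batch_quantify(withr::local_tempdir()), "no decodable")
})
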