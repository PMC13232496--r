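# Synthetic plant images with exact tissue ground truth.
#
# Class-conditional colors are drawn from fixed closed RGB boxes lying
# strictly inside the corresponding DTR acceptance region (and, for yellow
# and necrotic, outside the regions of the classes that precede them), with
# a margin of at least 5/255 on every face. Values sit on the 8-bit grid,
# so lossless PNG encoding preserves class membership and the planted
# tissue counts are exact, not approximate.

# 8-bit sampling boxes (inclusive integer bounds) per tissue class.
# green:    satisfies the green rule everywhere in the box.
# yellow:   fails green (R >= 0.9 G guaranteed), inside the yellow box.
# necrotic: fails green and yellow (B <= 13 < 18), inside the necrotic box.
# The green channel carries the class signal (one constant level per
# class, necrotic < yellow < green) while within-class jitter lives in the
# red and blue channels. With this geometry the widest channel of any
# pixel box spanning several classes either separates whole classes or
# splits only within the two damage classes, so three-subgroup median-cut
# quantization recovers the planted damage exactly even under jitter.
.class_color_boxes <- list(
  green    = list(R = c(130L, 140L), G = c(185L, 185L), B = c(95L, 105L)),
  yellow   = list(R = c(125L, 135L), G = c(120L, 120L), B = c(95L, 105L)),
  necrotic = list(R = c(125L, 135L), G = c(80L, 80L),   B = c(6L, 13L))
)

#' Ground truth for one synthetic plant image
#'
#' @param proportions length-3 numeric: fractions of plant pixels that are
#'   green, yellow (chlorotic) and necrotic; each in \[0, 1\], summing to 1
#'   (within 1e-12).
#' @param n_plant_pixels number of plant pixels.
#' @param background_color RGB triple in \[0, 1\]; snapped to the 8-bit grid.
#' @param seed integer seed controlling color sampling and pixel placement.
#' @return An object of class `image_truth`.
#' @export
image_truth <- function(proportions, n_plant_pixels,
                        background_color = c(210, 230, 250) / 255,
                        seed = 1L) {
  proportions <- as.numeric(proportions)
  if (length(proportions) != 3L || any(proportions < 0) ||
      any(proportions > 1) || abs(sum(proportions) - 1) > 1e-12) {
    stop("`proportions` must be 3 fractions in [0,1] summing to 1",
         call. = FALSE)
  }
  if (n_plant_pixels < 1L) stop("n_plant_pixels must be >= 1", call. = FALSE)
  structure(
    list(proportions = setNames(proportions, c("green", "yellow", "necrotic")),
         n_plant_pixels = as.integer(n_plant_pixels),
         background_color = round(background_color * 255) / 255,
         mask = NULL, seed = as.integer(seed)),
    class = "image_truth"
  )
}

# Integer class counts from proportions by largest remainder (ties broken
# by class order green, yellow, necrotic), so counts sum exactly to n.
class_counts_from_proportions <- function(proportions, n) {
  raw <- proportions * n
  counts <- floor(raw)
  rem <- as.integer(round(n - sum(counts)))
  if (rem > 0) {
    ord <- order(-(raw - counts), seq_along(raw))
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

#' Generate a synthetic plant image with exact tissue ground truth
#'
#' The image consists of `truth$n_plant_pixels` plant pixels placed at
#' random positions (or at `truth$mask` if supplied) over a uniform
#' background. Plant pixels are colored per class so that classifying the
#' image with [classify_pixels_dtr] recovers the planted counts exactly.
#' Deterministic given `truth$seed`.
#'
#' @param truth an [image_truth].
#' @param height,width image dimensions; `height * width` must exceed
#'   `n_plant_pixels`.
#' @param jitter if `TRUE` (default) colors are drawn uniformly from the
#'   class sampling boxes (within-class color variation); if `FALSE` each
#'   class is a single flat color (the box midpoint), giving a
#'   three-color separable image on which the unsupervised method agrees
#'   with DTR exactly.
#' @return A list with `image` (an [rgb_image] carrying the plant mask),
#'   `truth` (with `mask` and planted `counts` filled in).
#' @export
generate_plant_image <- function(truth, height = 60L, width = 60L,
                                 jitter = TRUE) {
  stopifnot(inherits(truth, "image_truth"))
  n_px <- height * width
  if (n_px <= truth$n_plant_pixels) {
    stop("image too small for n_plant_pixels", call. = FALSE)
  }
  counts <- class_counts_from_proportions(truth$proportions,
                                          truth$n_plant_pixels)
  with_seed(truth$seed, {
    if (is.null(truth$mask)) {
      plant_idx <- sample.int(n_px, truth$n_plant_pixels)
    } else {
      if (sum(truth$mask) != truth$n_plant_pixels) {
        stop("mask pixel count does not equal n_plant_pixels", call. = FALSE)
      }
      plant_idx <- which(truth$mask)
    }
    # shuffle class assignment over plant positions
    cls <- sample(rep.int(1:3, counts))
    px <- array(0, dim = c(height, width, 3L))
    for (ch in 1:3) px[, , ch] <- truth$background_color[ch]
    for (k in 1:3) {
      box <- .class_color_boxes[[k]]
      pos <- plant_idx[cls == k]
      if (length(pos) == 0L) next
      for (ch in 1:3) {
        rng <- box[[ch]]
        vals <- if (jitter) {
          rng[1] + sample.int(rng[2] - rng[1] + 1L, length(pos),
                              replace = TRUE) - 1L
        } else {
          rep.int(round(mean(rng)), length(pos))
        }
        plane <- px[, , ch]
        plane[pos] <- vals / 255
        px[, , ch] <- plane
      }
    }
    mask <- matrix(FALSE, height, width)
    mask[plant_idx] <- TRUE
    truth$mask <- mask
    truth$counts <- setNames(counts, c("green", "yellow", "necrotic"))
    list(image = rgb_image(px, mask = mask), truth = truth)
  })
}

#' Write a synthetic image fixture to disk
#'
#' Writes `<prefix>.png` (lossless 8-bit), `<prefix>_mask.png` (0/255) and
#' `<prefix>.json` (planted proportions and counts).
#'
#' @param generated a list from [generate_plant_image].
#' @param prefix output path prefix.
#' @return Invisibly, the three paths written.
#' @export
write_image_fixture <- function(generated, prefix) {
  img <- generated$image; truth <- generated$truth
  p_img <- paste0(prefix, ".png")
  p_mask <- paste0(prefix, "_mask.png")
  p_json <- paste0(prefix, ".json")
  png::writePNG(img$pixels, p_img)
  png::writePNG(matrix(as.numeric(img$mask), nrow(img$mask)), p_mask)
  jsonlite::write_json(
    list(proportions = as.list(truth$proportions),
         counts = as.list(truth$counts),
         n_plant_pixels = truth$n_plant_pixels,
         background_color = truth$background_color,
         seed = truth$seed),
    p_json, auto_unbox = TRUE, digits = NA
  )
  invisible(c(image = p_img, mask = p_mask, truth = p_json))
}
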