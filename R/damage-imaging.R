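# Supervised (DTR) and unsupervised (DQU) quantification of plant damage
# from lightbox images.
#
# DTR classifies each plant pixel with fixed RGB threshold rules for green,
# chlorotic (yellow) and necrotic tissue; DQU quantizes the masked pixels
# into three color subgroups by median-cut and maps each subgroup to a
# tissue class. Both reduce to the damage statistic
#   damage = (yellow + necrotic) / (yellow + necrotic + green).

# RGB threshold rules, on channels normalized to [0, 1]. All inequalities
# are strict. The yellow and necrotic boxes overlap; classification applies
# the rules in the order green -> yellow -> necrotic and the first match
# wins (the order in which the rules are stated).
.dtr_rules <- list(
  green = function(R, G, B) {
    R < 0.9 * G & B < 0.9 * G & 2 * G > (20 / 255) * (B + R)
  },
  yellow = function(R, G, B) {
    R > 90 / 255 & R < 241 / 255 &
      G > 97 / 255 & G < 216 / 255 &
      B > 18 / 255 & B < 165 / 255
  },
  necrotic = function(R, G, B) {
    R > 27 / 255 & R < 225 / 255 &
      G > 56 / 255 & G < 213 / 255 &
      B > 0 & B < 53 / 255
  }
)

#' Construct an RGB image object
#'
#' Container for an H x W x 3 pixel array on the \[0, 1\] scale with an
#' optional logical plant mask (`TRUE` = plant pixel).
#'
#' @param pixels numeric H x W x 3 array with values in \[0, 1\].
#' @param mask optional logical H x W matrix marking plant pixels.
#' @param source_path optional path the image was read from.
#' @param bit_depth integer bit depth of the original encoding (8 or 16).
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(pixels, mask = NULL, source_path = NA_character_,
                      bit_depth = 8L) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  }
  if (any(pixels < 0 | pixels > 1, na.rm = TRUE)) {
    stop("pixel values must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(mask)) {
    if (!is.logical(mask)) mask <- mask > 0.5
    if (!identical(dim(mask), dim(pixels)[1:2])) {
      stop("mask shape does not match image shape", call. = FALSE)
    }
  }
  structure(
    list(pixels = pixels, mask = mask,
         source_path = source_path, bit_depth = as.integer(bit_depth)),
    class = "rgb_image"
  )
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image> %d x %d px, %s mask%s\n", d[1], d[2],
              if (is.null(x$mask)) "no" else
                sprintf("%d-px", sum(x$mask)),
              if (is.na(x$source_path)) "" else
                sprintf(" [%s]", basename(x$source_path))))
  invisible(x)
}

#' Load a PNG or JPEG image (and optional mask) from disk
#'
#' Pixels are returned normalized to \[0, 1\] (integer channel values divided
#' by `2^bit_depth - 1`). JPEG input is supported for reading only; masks and
#' generated fixtures are PNG because lossy compression perturbs
#' threshold-adjacent pixels.
#'
#' @param path path to a PNG or JPEG image.
#' @param mask_path optional path to a PNG mask (nonzero = plant pixel).
#' @return An [rgb_image].
#' @export
load_image <- function(path, mask_path = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)  # already scaled by 2^depth - 1
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("reading JPEG requires the EBImage package", call. = FALSE)
    }
    im <- EBImage::readImage(path)
    px <- aperm(EBImage::imageData(im), c(2, 1, 3))
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  if (length(dim(px)) == 2L) {  # grayscale -> replicate channels
    px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  }
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- png::readPNG(mask_path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    if (!identical(dim(m), dim(px)[1:2])) {
      stop("mask shape does not match image shape", call. = FALSE)
    }
    mask <- m > 0.5
  }
  rgb_image(px, mask = mask, source_path = path)
}

#' Mask a uniform lightbox background
#'
#' Marks as background every pixel whose channels are all within `tol` of
#' `background_color`; the remaining pixels form the plant mask.
#'
#' @param img an [rgb_image].
#' @param background_color RGB triple in \[0, 1\].
#' @param tol per-channel absolute tolerance (>= 0).
#' @return The image with its `mask` field set.
#' @export
mask_background <- function(img, background_color, tol = 2 / 255) {
  stopifnot(inherits(img, "rgb_image"), tol >= 0,
            length(background_color) == 3L)
  d <- abs(sweep(img$pixels, 3L, background_color))
  is_bg <- apply(d <= tol, c(1, 2), all)
  mask <- !is_bg
  if (!any(mask)) {
    stop("background masking removed every pixel; check background_color/tol",
         call. = FALSE)
  }
  img$mask <- mask
  img
}

#' Construct a tissue-count record
#'
#' @param green,yellow,necrotic,unclassified non-negative pixel counts.
#' @return An object of class `tissue_counts`.
#' @export
tissue_counts <- function(green, yellow, necrotic, unclassified = 0) {
  counts <- c(green = green, yellow = yellow, necrotic = necrotic,
              unclassified = unclassified)
  if (any(counts < 0)) stop("tissue counts must be >= 0", call. = FALSE)
  structure(as.list(counts), class = "tissue_counts")
}

#' Classify plant pixels with the supervised RGB threshold rules (DTR)
#'
#' Each masked pixel receives exactly one label by applying the green,
#' yellow (chlorotic) and necrotic rules in that order; pixels matching no
#' rule are `unclassified` and are excluded from the damage denominator.
#'
#' @param img an [rgb_image] with a plant mask (set explicitly or via
#'   [mask_background]).
#' @return A list with `counts` (a [tissue_counts]) and `labels`, a
#'   character H x W matrix (`NA` outside the mask).
#' @export
classify_pixels_dtr <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  if (is.null(img$mask)) {
    stop("DTR classification needs a plant mask; call mask_background() ",
         "or supply one", call. = FALSE)
  }
  hw <- dim(img$pixels)[1:2]
  R <- array(img$pixels[, , 1], dim = hw)
  G <- array(img$pixels[, , 2], dim = hw)
  B <- array(img$pixels[, , 3], dim = hw)
  lab <- matrix(NA_character_, hw[1], hw[2])
  m <- img$mask
  is_g <- .dtr_rules$green(R, G, B)
  is_y <- .dtr_rules$yellow(R, G, B)
  is_n <- .dtr_rules$necrotic(R, G, B)
  lab[m] <- "unclassified"
  lab[m & is_n] <- "necrotic"
  lab[m & is_y] <- "yellow"    # yellow overrides necrotic
  lab[m & is_g] <- "green"     # green overrides both
  counts <- tissue_counts(
    green = sum(lab == "green", na.rm = TRUE),
    yellow = sum(lab == "yellow", na.rm = TRUE),
    necrotic = sum(lab == "necrotic", na.rm = TRUE),
    unclassified = sum(lab == "unclassified", na.rm = TRUE)
  )
  list(counts = counts, labels = lab)
}

#' Damage statistic from tissue counts
#'
#' `damage = (yellow + necrotic) / (yellow + necrotic + green)`. Unclassified
#' pixels are excluded from the denominator.
#'
#' @param counts a [tissue_counts].
#' @return Damage fraction in \[0, 1\].
#' @export
damage_score <- function(counts) {
  stopifnot(inherits(counts, "tissue_counts"))
  denom <- counts$green + counts$yellow + counts$necrotic
  if (denom <= 0) {
    stop("damage undefined: no classified (green/yellow/necrotic) pixels",
         call. = FALSE)
  }
  (counts$yellow + counts$necrotic) / denom
}

#' Quantify damage for a directory of images
#'
#' Runs the supervised (`"dtr"`) and/or unsupervised (`"dqu"`) method on
#' every PNG/JPEG in `image_dir`. Masks are taken from `mask_dir`
#' (`<image>_mask.png`) when given, otherwise derived with
#' [mask_background]. Images that fail to load or classify are logged and
#' skipped, not fatal.
#'
#' @param image_dir directory containing >= 1 decodable image.
#' @param method `"dtr"`, `"dqu"` or `"both"`.
#' @param mask_dir optional directory of PNG masks named `<image>_mask.png`.
#' @param background_color,tol background rule used when no mask file exists.
#' @param out optional CSV path to write the table to.
#' @return A data frame with one row per image x method: `image_id`,
#'   `method`, tissue counts and `damage`.
#' @export
batch_quantify <- function(image_dir, method = c("both", "dtr", "dqu"),
                           mask_dir = NULL, background_color = NULL,
                           tol = 2 / 255, out = NULL) {
  method <- match.arg(method)
  files <- list.files(image_dir, pattern = "\\.(png|jpe?g)$",
                      ignore.case = TRUE, full.names = TRUE)
  files <- files[!grepl("_mask\\.png$", files, ignore.case = TRUE)]
  if (length(files) == 0L) {
    stop("no decodable images found in ", image_dir, call. = FALSE)
  }
  methods <- if (method == "both") c("dtr", "dqu") else method
  rows <- list()
  n_skipped <- 0L
  for (f in files) {
    id <- tools::file_path_sans_ext(basename(f))
    res <- tryCatch({
      mask_path <- NULL
      if (!is.null(mask_dir)) {
        cand <- file.path(mask_dir, paste0(id, "_mask.png"))
        if (file.exists(cand)) mask_path <- cand
      }
      img <- load_image(f, mask_path)
      if (is.null(img$mask)) {
        if (is.null(background_color)) {
          stop("no mask available and no background rule configured")
        }
        img <- mask_background(img, background_color, tol)
      }
      out_rows <- list()
      for (m in methods) {
        counts <- if (m == "dtr") {
          classify_pixels_dtr(img)$counts
        } else {
          assign_clusters_to_classes(median_cut_quantize(img))
        }
        out_rows[[m]] <- data.frame(
          image_id = id, method = m,
          n_green = counts$green, n_yellow = counts$yellow,
          n_necrotic = counts$necrotic, n_unclassified = counts$unclassified,
          damage = damage_score(counts),
          stringsAsFactors = FALSE
        )
      }
      do.call(rbind, out_rows)
    }, error = function(e) {
      message("skipping ", basename(f), ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) n_skipped <- n_skipped + 1L else rows[[f]] <- res
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(tab, "n_skipped") <- n_skipped
  if (!is.null(out)) write.csv(tab, out, row.names = FALSE)
  tab
}
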