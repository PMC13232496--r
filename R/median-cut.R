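# Unsupervised color quantization (DQU): iterative median cut into up to
# three color subgroups, then a rule-based mapping of subgroups to tissue
# classes.

#' Median-cut color quantization of masked plant pixels
#'
#' Maintains a set of pixel boxes, repeatedly splitting the box whose widest
#' channel range is largest at the median of that channel, until
#' `n_clusters` boxes exist or no box is splittable. The centroid of a box
#' is the mean color of its pixels. Fully deterministic: box selection ties
#' break by larger pixel count then lower box index, and pixels whose
#' channel value equals the median go to the lower box (unless that empties
#' the upper box, in which case the median itself moves up).
#'
#' @param img an [rgb_image] with a plant mask.
#' @param n_clusters maximum number of color subgroups (default 3).
#' @return An object of class `quantization_result`: `centroids` (k x 3
#'   matrix), `labels` (integer vector over masked pixels, row-major over
#'   the mask), `sizes`, and `pixel_index` (which masked pixels).
#' @export
median_cut_quantize <- function(img, n_clusters = 3L) {
  stopifnot(inherits(img, "rgb_image"), n_clusters >= 1L)
  if (is.null(img$mask)) {
    stop("median-cut quantization needs a plant mask", call. = FALSE)
  }
  idx <- which(img$mask)
  if (length(idx) < 1L) stop("empty plant mask", call. = FALSE)
  P <- cbind(img$pixels[, , 1][idx],
             img$pixels[, , 2][idx],
             img$pixels[, , 3][idx])

  boxes <- list(seq_len(nrow(P)))
  box_range <- function(b) {
    if (length(b) < 2L) return(c(0, 0, 0))
    apply(P[b, , drop = FALSE], 2L, function(v) max(v) - min(v))
  }
  while (length(boxes) < n_clusters) {
    ranges <- vapply(boxes, function(b) max(box_range(b)), numeric(1))
    splittable <- ranges > 0
    if (!any(splittable)) break
    # widest box wins; ties by pixel count, then by lower index
    sizes <- lengths(boxes)
    ord <- order(-ranges, -sizes, seq_along(boxes))
    pick <- ord[match(TRUE, splittable[ord])]
    b <- boxes[[pick]]
    ch <- which.max(box_range(b))
    v <- P[b, ch]
    med <- stats::median(v)
    lower <- b[v <= med]
    upper <- b[v > med]
    if (length(upper) == 0L) {  # median equals the max; split strictly below
      lower <- b[v < med]
      upper <- b[v >= med]
    }
    boxes[[pick]] <- lower
    boxes[[length(boxes) + 1L]] <- upper
  }

  labels <- integer(nrow(P))
  for (k in seq_along(boxes)) labels[boxes[[k]]] <- k
  centroids <- t(vapply(boxes, function(b) colMeans(P[b, , drop = FALSE]),
                        numeric(3)))
  colnames(centroids) <- c("R", "G", "B")
  structure(
    list(centroids = centroids, labels = labels,
         sizes = lengths(boxes), pixel_index = idx),
    class = "quantization_result"
  )
}

# Default class prototypes: midpoints of the synthetic sampling boxes (on
# the [0,1] scale), used only when a centroid satisfies no DTR rule.
.default_prototypes <- rbind(
  green    = c(135, 185, 100) / 255,
  yellow   = c(130, 120, 100) / 255,
  necrotic = c(130, 80, 9.5) / 255
)

#' Map median-cut color subgroups to tissue classes
#'
#' Each cluster centroid is first classified by the DTR threshold rules
#' (green -> yellow -> necrotic precedence). A centroid matching no rule is
#' assigned to the nearest class prototype by Euclidean RGB distance, with
#' ties broken by the fixed class order green < yellow < necrotic. Cluster
#' sizes are then aggregated per class, so `unclassified` is 0 by
#' construction.
#'
#' @param q a `quantization_result` from [median_cut_quantize].
#' @param prototypes 3 x 3 matrix of class prototype colors (rows green,
#'   yellow, necrotic) used for the nearest-prototype fallback.
#' @return A [tissue_counts].
#' @export
assign_clusters_to_classes <- function(q, prototypes = .default_prototypes) {
  stopifnot(inherits(q, "quantization_result"))
  classes <- c("green", "yellow", "necrotic")
  cls <- character(nrow(q$centroids))
  for (k in seq_len(nrow(q$centroids))) {
    cen <- q$centroids[k, ]
    hit <- vapply(classes,
                  function(cl) .dtr_rules[[cl]](cen[1], cen[2], cen[3]),
                  logical(1))
    if (any(hit)) {
      cls[k] <- classes[match(TRUE, hit)]
    } else {
      d <- sqrt(rowSums(sweep(prototypes, 2L, cen)^2))
      cls[k] <- classes[which.min(d)]  # which.min: first minimum = tie-break
    }
  }
  counts <- vapply(classes, function(cl) sum(q$sizes[cls == cl]), numeric(1))
  tissue_counts(green = counts[["green"]], yellow = counts[["yellow"]],
                necrotic = counts[["necrotic"]], unclassified = 0)
}
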