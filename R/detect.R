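# Frames are numeric matrices indexed [x, z]: first index runs along the
# horizontal (azimuth) axis, second index increases upward (elevation), so
# geometry below matches the nose-up-positive pitch convention directly.

#' Detector thresholds
#'
#' Bundles the per-run detection parameters: the per-pixel background
#' raster, the intensity noise threshold applied to the background
#' difference, blob area bounds (in pixels) that an animal must satisfy,
#' and the size/intensity criteria used to resolve the two animal parts
#' (body and head).
#'
#' @param background Background raster (matrix), same dimensions as the
#'   frames to be processed.
#' @param noise_threshold Intensity difference below which pixels are
#'   treated as background noise. Default 25.
#' @param area_min,area_max Connected-component area bounds (pixels^2).
#' @param elongation_min Minimum blob elongation (sqrt of the principal
#'   moment ratio) for part splitting to be attempted; round blobs cannot
#'   be resolved into body and head. Default 1.25.
#' @param intensity_ratio_min Minimum ratio of mean part intensities for
#'   the brighter part to be labelled the head; below it the smaller part
#'   is used instead (area criterion). Default 1.02.
#' @return A list of class `bk_thresholds`.
#' @export
detector_thresholds <- function(background,
                                noise_threshold = 25,
                                area_min = 80,
                                area_max = 8000,
                                elongation_min = 1.25,
                                intensity_ratio_min = 1.02) {
  stopifnot(is.matrix(background), area_min < area_max,
            noise_threshold > 0, elongation_min >= 1)
  out <- list(background = background,
              noise_threshold = noise_threshold,
              area_min = area_min,
              area_max = area_max,
              elongation_min = elongation_min,
              intensity_ratio_min = intensity_ratio_min)
  class(out) <- "bk_thresholds"
  out
}

#' Background model from a frame sample
#'
#' Per-pixel temporal median over a sample of frames; robust to the
#' transient presence of the animal.
#'
#' @param frames List of frames (matrices of identical dimensions).
#' @return A background raster (matrix).
#' @export
background_model <- function(frames) {
  stopifnot(length(frames) >= 1)
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1)))) {
    stop("all frames must share dimensions")
  }
  arr <- array(unlist(frames, use.names = FALSE), dim = c(d, length(frames)))
  apply(arr, c(1, 2), median)
}

#' Background subtraction
#'
#' @param frame Frame raster (matrix).
#' @param background Background raster of identical dimensions.
#' @return The non-negative absolute-difference raster.
#' @export
subtract_background <- function(frame, background) {
  if (!identical(dim(frame), dim(background))) {
    stop("frame and background dimensions differ")
  }
  abs(frame - background)
}

# 8-connected labelling: EBImage::bwlabel plus a union-find merge of
# diagonally adjacent labels
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]   # down-right diagonal pairs
  c_ <- lab[-nr, -1]; d <- lab[-1, -nc]  # up-right diagonal pairs
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c_), as.vector(d)))
  pairs <- unique(pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                          pairs[, 1] != pairs[, 2], , drop = FALSE])
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  lab[lab > 0] <- relab[lab[lab > 0]]
  lab
}

# second-moment summary of a pixel set: centroid, principal axis angle
# (radians, in (-pi/2, pi/2]), eigenvalues, major-axis length
blob_moments <- function(px, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(px))
  w <- weights / sum(weights)
  cx <- sum(w * px[, 1]); cz <- sum(w * px[, 2])
  dx <- px[, 1] - cx; dz <- px[, 2] - cz
  mxx <- sum(w * dx^2) + 1 / 12  # pixel footprint keeps moments nonzero
  mzz <- sum(w * dz^2) + 1 / 12
  mxz <- sum(w * dx * dz)
  theta <- 0.5 * atan2(2 * mxz, mxx - mzz)
  tr <- mxx + mzz
  det_ <- mxx * mzz - mxz^2
  disc <- sqrt(max(0, tr^2 / 4 - det_))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 1e-12)
  list(centroid = c(x = cx, z = cz), theta = theta,
       lambda = c(l1, l2),
       elongation = sqrt(l1 / l2),
       major_length = 4 * sqrt(l1))
}

#' Split a blob into body and head parts
#'
#' Pixels are projected onto the blob's principal axis and partitioned by a
#' 1-D intensity-weighted two-means split. The head is the part with the
#' higher mean intensity; if the parts are nearly iso-intense, the smaller
#' part is taken as the head (size criterion). Round blobs, for which no
#' axis is defined, are reported as unresolved.
#'
#' @param px Two-column matrix of blob pixel coordinates (x, z).
#' @param intensities Intensity of each pixel (same length as rows of
#'   `px`), typically from the background difference raster.
#' @param thresholds A `bk_thresholds`.
#' @return A list with elements `body` and `head` (row-index vectors into
#'   `px`) and `reason` (`NULL` on success, `"parts_unresolved"` on
#'   failure).
#' @export
split_parts <- function(px, intensities, thresholds) {
  mom <- blob_moments(px)
  if (mom$elongation < thresholds$elongation_min || nrow(px) < 4) {
    return(list(body = NULL, head = NULL, reason = "parts_unresolved"))
  }
  u <- c(cos(mom$theta), sin(mom$theta))
  proj <- (px[, 1] - mom$centroid[1]) * u[1] + (px[, 2] - mom$centroid[2]) * u[2]
  w <- pmax(intensities, 0)
  if (sum(w) <= 0) w <- rep(1, length(proj))
  # 1-D weighted 2-means on the axial projection
  thr <- sum(w * proj) / sum(w)
  for (it in 1:50) {
    lo <- proj <= thr
    if (all(lo) || !any(lo)) {
      thr <- median(proj)
      lo <- proj <= thr
      break
    }
    m1 <- sum(w[lo] * proj[lo]) / sum(w[lo])
    m2 <- sum(w[!lo] * proj[!lo]) / sum(w[!lo])
    new_thr <- (m1 + m2) / 2
    if (abs(new_thr - thr) < 1e-9) break
    thr <- new_thr
  }
  g1 <- which(lo); g2 <- which(!lo)
  if (length(g1) == 0 || length(g2) == 0) {
    return(list(body = NULL, head = NULL, reason = "parts_unresolved"))
  }
  i1 <- mean(intensities[g1]); i2 <- mean(intensities[g2])
  ratio <- max(i1, i2) / max(min(i1, i2), 1e-12)
  if (ratio >= thresholds$intensity_ratio_min) {
    head <- if (i2 > i1) g2 else g1
  } else {
    # iso-intense parts: the head is the smaller part
    head <- if (length(g2) < length(g1)) g2 else g1
  }
  body <- setdiff(seq_len(nrow(px)), head)
  list(body = body, head = head, reason = NULL)
}

#' Pitch from body and head centroids
#'
#' The pitch angle is the inclination of the head-minus-body vector above
#' the horizontal, nose-up positive, independent of whether the animal
#' faces left or right.
#'
#' @param body,head Numeric length-2 centroids `c(x, z)`.
#' @return Pitch in degrees, in \[-90, 90\].
#' @export
orientation_from_parts <- function(body, head) {
  dx <- head[1] - body[1]
  dz <- head[2] - body[2]
  if (dx == 0 && dz == 0) stop("coincident body and head centroids")
  atan2(dz, abs(dx)) * 180 / pi
}

#' Detect a single animal in a frame
#'
#' Implements the real-time detection chain: background subtraction, noise
#' thresholding, connected-component analysis (8-connectivity), rejection
#' of frames with zero or multiple in-bounds animals, size/intensity part
#' splitting, and extraction of location and body orientation relative to
#' the horizon. Rejection is a result, not an error.
#'
#' @param frame Frame raster (matrix).
#' @param thresholds A `bk_thresholds`.
#' @return A list of class `bk_detection` with fields `accepted`,
#'   `body` and `head` part centroids and the intensity-weighted full-blob
#'   `centroid` (x, z in pixels), `pitch` (deg),
#'   `animal_length` (pixels) and `rejection_reason` (`NA` when accepted;
#'   otherwise one of `"no_animal"`, `"multiple_animals"`,
#'   `"size_out_of_bounds"`, `"parts_unresolved"`).
#' @export
detect_animal <- function(frame, thresholds) {
  stopifnot(inherits(thresholds, "bk_thresholds"))
  diffr <- subtract_background(frame, thresholds$background)
  mask <- diffr > thresholds$noise_threshold
  reject <- function(reason) {
    structure(list(accepted = FALSE, body = c(x = NA_real_, z = NA_real_),
                   head = c(x = NA_real_, z = NA_real_),
                   centroid = c(x = NA_real_, z = NA_real_), pitch = NA_real_,
                   animal_length = NA_real_, rejection_reason = reason),
              class = "bk_detection")
  }
  if (!any(mask)) return(reject("no_animal"))
  lab <- label_components(mask)
  areas <- tabulate(lab[lab > 0])
  in_bounds <- which(areas >= thresholds$area_min & areas <= thresholds$area_max)
  if (length(in_bounds) == 0) {
    # only sub/super-sized components: distinguish specks from oversize blobs
    if (all(areas < thresholds$area_min)) return(reject("no_animal"))
    return(reject("size_out_of_bounds"))
  }
  if (length(in_bounds) > 1) return(reject("multiple_animals"))
  idx <- which(lab == in_bounds)
  px <- cbind(x = (idx - 1) %% nrow(lab) + 1,
              z = (idx - 1) %/% nrow(lab) + 1)
  ints <- diffr[idx]
  parts <- split_parts(px, ints, thresholds)
  if (!is.null(parts$reason)) return(reject(parts$reason))
  mom <- blob_moments(px, weights = ints)
  bc <- blob_moments(px[parts$body, , drop = FALSE],
                     weights = ints[parts$body])$centroid
  hc <- blob_moments(px[parts$head, , drop = FALSE],
                     weights = ints[parts$head])$centroid
  # principal axis gives the body line; the head part fixes its direction
  u <- c(cos(mom$theta), sin(mom$theta))
  s <- sign(sum((hc - bc) * u))
  if (s == 0) return(reject("parts_unresolved"))
  dirv <- s * u
  pitch <- atan2(dirv[2], abs(dirv[1])) * 180 / pi
  structure(list(accepted = TRUE,
                 body = c(x = unname(bc[1]), z = unname(bc[2])),
                 head = c(x = unname(hc[1]), z = unname(hc[2])),
                 centroid = c(x = unname(mom$centroid[1]),
                              z = unname(mom$centroid[2])),
                 pitch = pitch,
                 animal_length = mom$major_length,
                 rejection_reason = NA_character_),
            class = "bk_detection")
}

#' @export
print.bk_detection <- function(x, ...) {
  if (x$accepted) {
    cat(sprintf("<detection> accepted: body (%.1f, %.1f), pitch %.2f deg, length %.1f px\n",
                x$body[1], x$body[2], x$pitch, x$animal_length))
  } else {
    cat(sprintf("<detection> rejected: %s\n", x$rejection_reason))
  }
  invisible(x)
}

#' Render a synthetic animal frame
#'
#' Draws a two-part animal -- an elongated trunk ellipse plus a brighter
#' head disc centred on the body axis -- at a given pose over a background
#' raster, with optional Gaussian pixel noise. Used to validate the
#' detector against known ground truth.
#'
#' @param pose List with `x`, `z` (body centre, pixels), `pitch` (deg,
#'   nose-up positive), `heading` (+1 rightward, -1 leftward) and `length`
#'   (total animal length, pixels).
#' @param background Background raster (matrix).
#' @param noise_sd Gaussian pixel noise SD (intensity units). Default 0.
#' @param trunk_gain,head_gain Intensity added over background by trunk
#'   and head. Defaults 80 and 240: a strongly brighter head disc, as seen
#'   in IR backlit imaging where the head/swim-bladder region dominates.
#' @return The frame (matrix) with attribute `truth`: a list with the
#'   rendered body centre, head centre, pitch, heading, length, and the
#'   noiseless intensity-weighted centroid (`centroid`).
#' @export
render_frame <- function(pose, background, noise_sd = 0,
                         trunk_gain = 80, head_gain = 240) {
  stopifnot(is.matrix(background))
  nx <- nrow(background); nz <- ncol(background)
  L <- pose$length
  pr <- pose$pitch * pi / 180
  u <- c(pose$heading * cos(pr), sin(pr))
  body <- c(pose$x, pose$z)
  headc <- body + 0.42 * L * u
  a <- 0.38 * L; b <- 0.11 * L; hr <- 0.14 * L
  ext <- 0.6 * L
  if (pose$x - ext < 1 || pose$x + ext > nx ||
      pose$z - ext < 1 || pose$z + ext > nz) {
    stop("pose out of frame bounds")
  }
  gx <- matrix(seq_len(nx), nx, nz)
  gz <- matrix(rep(seq_len(nz), each = nx), nx, nz)
  dx <- gx - body[1]; dz <- gz - body[2]
  ax <- dx * u[1] + dz * u[2]         # along-axis coordinate
  pz <- -dx * u[2] + dz * u[1]        # across-axis coordinate
  e <- sqrt((ax / a)^2 + (pz / b)^2)  # normalised elliptical radius
  ew <- 0.12
  trunk_cov <- pmin(1, pmax(0, (1 - e) / ew + 0.5))
  dh <- sqrt((gx - headc[1])^2 + (gz - headc[2])^2)
  head_cov <- pmin(1, pmax(0, (hr - dh) / (ew * hr * 4) + 0.5))
  fg <- pmax(trunk_cov * trunk_gain, head_cov * head_gain)
  img <- background + fg
  truth_centroid <- c(
    x = sum(fg * gx) / sum(fg),
    z = sum(fg * gz) / sum(fg)
  )
  if (noise_sd > 0) {
    img <- img + matrix(rnorm(nx * nz, sd = noise_sd), nx, nz)
  }
  attr(img, "truth") <- list(body = body, head = headc, pitch = pose$pitch,
                             heading = pose$heading, length = L,
                             centroid = truth_centroid)
  img
}

#' Run the detector over a frame sequence
#'
#' Applies [detect_animal()] to each frame and assembles the accepted
#' detections into a raw trace. Contiguous runs of accepted frames become
#' epochs, mirroring the acquisition-time definition of an epoch as an
#' uninterrupted interval of valid single-animal detection.
#'
#' @param frames List of frames (matrices).
#' @param thresholds A `bk_thresholds`.
#' @param frame_rate Hz; supplies the per-frame time stamps.
#' @return A list with `trace` (a `bk_trace`), `accepted` (logical per
#'   frame) and `rejections` (named counts by reason).
#' @export
track_frames <- function(frames, thresholds, frame_rate = 166) {
  dets <- lapply(frames, detect_animal, thresholds = thresholds)
  acc <- vapply(dets, `[[`, logical(1), "accepted")
  reasons <- vapply(dets, `[[`, character(1), "rejection_reason")
  t <- (seq_along(frames) - 1) / frame_rate
  # epoch id increments at every break in the accepted-frame sequence
  epoch <- integer(length(frames))
  if (any(acc)) {
    breaks <- c(TRUE, diff(which(acc)) > 1)
    epoch[acc] <- cumsum(breaks) - 1L
  }
  rows <- which(acc)
  df <- data.frame(
    time_stamp = t[rows],
    body_x = vapply(dets[rows], function(d) d$body[["x"]], 0),
    body_z = vapply(dets[rows], function(d) d$body[["z"]], 0),
    head_x = vapply(dets[rows], function(d) d$head[["x"]], 0),
    head_z = vapply(dets[rows], function(d) d$head[["z"]], 0),
    pitch = vapply(dets[rows], `[[`, 0, "pitch"),
    epoch_id = epoch[rows],
    animal_length = vapply(dets[rows], `[[`, 0, "animal_length")
  )
  list(trace = as_trace(df),
       accepted = acc,
       rejections = table(factor(reasons[!acc],
                                 levels = c("no_animal", "multiple_animals",
                                            "size_out_of_bounds",
                                            "parts_unresolved"))))
}
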