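#' Otsu threshold of an intensity sample
#'
#' Exhaustively maximizes the between-class variance over every cut point
#' between consecutive distinct intensity values (the classes are
#' \code{<= cut} and \code{> cut}).  The returned threshold is the midpoint
#' between the best cut value and the next distinct value, so foreground is
#' \code{value > threshold}.  On ties the lowest maximizing cut is taken.
#'
#' @param values numeric vector of intensities (e.g. pixels within one
#'   nucleus)
#' @return numeric threshold.
#' @examples
#' otsuThreshold(c(rep(10, 50), rep(200, 50)))  # 105
#' @export
otsuThreshold <- function(values) {
  values <- values[is.finite(values)]
  v <- sort(unique(values))
  if (length(v) < 2L)
    stop("no threshold: need at least 2 distinct intensity values")
  cnt <- as.numeric(table(factor(values, levels = v)))
  n <- sum(cnt)
  cw <- cumsum(cnt)                 # class-0 weight at cut i (<= v[i])
  cs <- cumsum(cnt * v)
  tot <- cs[length(cs)]
  i <- seq_len(length(v) - 1L)      # cuts between v[i] and v[i+1]
  w0 <- cw[i] / n
  w1 <- 1 - w0
  mu0 <- cs[i] / cw[i]
  mu1 <- (tot - cs[i]) / (n - cw[i])
  sigmaB <- w0 * w1 * (mu0 - mu1)^2
  best <- which.max(sigmaB)         # lowest index on ties
  (v[best] + v[best + 1L]) / 2
}

#' Segment nuclei from a DAPI image
#'
#' Global Otsu foreground detection, hole filling, distance-transform
#' watershed to split touching nuclei, and a minimum-area filter.  Labels
#' are renumbered contiguously from 1.
#'
#' @param img numeric intensity matrix (any scale)
#' @param minArea minimum object area in pixels (default 100)
#' @param smoothSigma Gaussian pre-smoothing sigma in pixels (0 disables;
#'   default 2)
#' @param tolerance watershed merging tolerance in distance-map units
#'   (default 1)
#' @return integer label matrix (0 = background), same shape as \code{img}.
#' @export
segmentNuclei <- function(img, minArea = 100, smoothSigma = 2,
                          tolerance = 1) {
  if (length(unique(as.vector(img))) < 2L) {
    warning("blank image: no nuclei found")
    return(matrix(0L, nrow(img), ncol(img)))
  }
  work <- img
  if (smoothSigma > 0)
    work <- as.matrix(EBImage::gblur(EBImage::Image(img / max(img)),
                                     sigma = smoothSigma)) * max(img)
  thr <- otsuThreshold(as.vector(work))
  mask <- work > thr
  mask <- EBImage::fillHull(mask)
  dm <- EBImage::distmap(mask)
  labels <- EBImage::watershed(dm, tolerance = tolerance, ext = 1)
  labels <- as.matrix(EBImage::imageData(labels))
  sizes <- table(labels[labels > 0])
  keep <- as.integer(names(sizes)[sizes >= minArea])
  out <- matrix(0L, nrow(img), ncol(img))
  for (k in seq_along(keep)) out[labels == keep[k]] <- k
  if (!any(out > 0)) warning("no object above the minimum area")
  out
}

.nucleusPixels <- function(img, mask, nucleusId = NULL) {
  sel <- if (is.logical(mask)) mask else mask == nucleusId
  img[sel]
}

#' Chromatin-compaction ratio i80/i20
#'
#' Ratio of the 80th to the 20th percentile of the DAPI intensity
#' distribution within one nucleus — a proxy for the relative abundance of
#' (bright) heterochromatin to (dim) euchromatin.  Percentiles use the
#' linear-interpolation convention (R \code{quantile} type 7), the fixed
#' convention for every percentile in this package.  The ratio is
#' scale-invariant and always \eqn{\ge 1}.
#'
#' @param img numeric intensity matrix
#' @param mask logical mask, or an integer label matrix with
#'   \code{nucleusId}
#' @param nucleusId label of the nucleus when \code{mask} is a label matrix
#' @param minPixels minimum pixel count (default 10)
#' @return numeric ratio, or \code{NA} when the 20th percentile is zero
#'   after flooring negative intensities at zero.
#' @examples
#' m <- matrix(c(10, 20, 30, 40, 50), 1)
#' i80i20(m, m > 0)  # 42/18
#' @export
i80i20 <- function(img, mask, nucleusId = NULL, minPixels = 10) {
  px <- .nucleusPixels(img, mask, nucleusId)
  if (length(px) < minPixels)
    stop("nucleus has fewer than ", minPixels, " pixels")
  px <- pmax(px, 0)
  q <- stats::quantile(px, c(0.2, 0.8), type = 7, names = FALSE)
  if (q[1L] <= 0) {
    message("i80i20: 20th percentile is zero; metric reported as missing")
    return(NA_real_)
  }
  q[2L] / q[1L]
}

#' Detect heterochromatin foci in one nucleus
#'
#' Pixels above the per-nucleus Otsu threshold form candidate foci;
#' connected components smaller than \code{minFocusArea} are discarded.
#'
#' @inheritParams i80i20
#' @param minFocusArea minimum focus area in pixels (default 5)
#' @return list with \code{focusMask} (integer label matrix, full image
#'   size), \code{focus_count} and \code{total_focus_area}.
#' @export
heterochromatinFoci <- function(img, mask, nucleusId = NULL,
                                minFocusArea = 5) {
  sel <- if (is.logical(mask)) mask else mask == nucleusId
  empty <- list(focusMask = matrix(0L, nrow(img), ncol(img)),
                focus_count = 0L, total_focus_area = 0L)
  px <- img[sel]
  if (length(unique(px)) < 2L) return(empty)
  thr <- otsuThreshold(px)
  fmask <- matrix(FALSE, nrow(img), ncol(img))
  fmask[sel] <- img[sel] > thr
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(fmask)))
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[sizes >= minFocusArea])
  out <- matrix(0L, nrow(img), ncol(img))
  for (k in seq_along(keep)) out[lab == keep[k]] <- k
  list(focusMask = out, focus_count = length(keep),
       total_focus_area = as.integer(sum(out > 0)))
}

#' Fraction of heterochromatin foci at the nuclear periphery
#'
#' The peripheral shell is the set of nucleus pixels within
#' \code{shellWidth} of the nuclear boundary (by the Euclidean distance
#' transform); the core is its complement inside the nucleus, so the
#' peripheral and core fractions of focus pixels always sum to one.
#'
#' @param focusMask integer or logical matrix of focus pixels
#' @param nucleusMask logical mask of the nucleus
#' @param shellWidth shell width in pixels (default 3)
#' @return fraction of focus pixels in the shell (in [0, 1]); \code{NA}
#'   when the nucleus has no focus pixels.
#' @export
peripheralFraction <- function(focusMask, nucleusMask, shellWidth = 3) {
  stopifnot(shellWidth >= 1)
  d <- as.matrix(EBImage::imageData(EBImage::distmap(nucleusMask)))
  shell <- nucleusMask & d <= shellWidth
  core <- nucleusMask & d > shellWidth
  if (!any(core)) {
    warning("shell wider than the nucleus radius; peripheral fraction is 1")
    shell <- nucleusMask
  }
  foci <- (focusMask > 0) & nucleusMask
  if (!any(foci)) return(NA_real_)
  sum(foci & shell) / sum(foci)
}

#' Per-nucleus chromatin metrics table
#'
#' Runs [segmentNuclei()] (unless a label mask is supplied) and computes
#' [i80i20()], [heterochromatinFoci()] and [peripheralFraction()] for every
#' nucleus.
#'
#' @param img DAPI intensity matrix
#' @param mask optional precomputed label matrix
#' @param minArea minimum nucleus area (pixels)
#' @param minFocusArea minimum focus area (pixels)
#' @param shellWidth peripheral shell width (pixels)
#' @return data.frame with one row per nucleus: \code{nucleus_id},
#'   \code{nucleus_area}, \code{i80_i20}, \code{focus_count},
#'   \code{total_focus_area}, \code{peripheral_fraction}.
#' @export
nucleiMetrics <- function(img, mask = NULL, minArea = 100,
                          minFocusArea = 5, shellWidth = 3) {
  if (is.null(mask)) mask <- segmentNuclei(img, minArea = minArea)
  ids <- sort(setdiff(unique(as.vector(mask)), 0L))
  rows <- lapply(ids, function(id) {
    nmask <- mask == id
    foci <- heterochromatinFoci(img, nmask, minFocusArea = minFocusArea)
    data.frame(
      nucleus_id = id,
      nucleus_area = sum(nmask),
      i80_i20 = tryCatch(i80i20(img, nmask), error = function(e) NA_real_),
      focus_count = foci$focus_count,
      total_focus_area = foci$total_focus_area,
      peripheral_fraction =
        peripheralFraction(foci$focusMask, nmask, shellWidth = shellWidth))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(nucleus_id = integer(), nucleus_area = integer(),
                      i80_i20 = numeric(), focus_count = integer(),
                      total_focus_area = integer(),
                      peripheral_fraction = numeric())
  rownames(out) <- NULL
  out
}

#' Spheroid spread area
#'
#' Foreground is detected by a global Otsu threshold, consolidated by
#' morphological closing and hole filling; the spread area is the area of
#' the resulting union of the spheroid body and its outward-migrating
#' cells.  The core area is the largest connected component of the
#' brighter (denser) foreground class (second Otsu pass within the
#' foreground); for images without an intensity gradient the core equals
#' the spread mask.
#'
#' @param img intensity matrix (DAPI, actin, or their pixelwise maximum)
#' @param closingRadius radius in pixels of the closing structuring element
#'   (default 5)
#' @return data.frame with \code{spread_area}, \code{core_area} (pixels)
#'   and \code{n_objects} (foreground components before closing).
#' @export
spheroidSpreadArea <- function(img, closingRadius = 5) {
  if (length(unique(as.vector(img))) < 2L)
    stop("no foreground: image has a single intensity value")
  thr <- otsuThreshold(as.vector(img))
  fg <- img > thr
  if (!any(fg)) stop("no foreground above the Otsu threshold")
  nObj <- max(EBImage::bwlabel(fg))
  brush <- EBImage::makeBrush(2L * closingRadius + 1L, shape = "disc")
  closed <- EBImage::closing(fg, brush)
  filled <- EBImage::fillHull(closed)
  spread <- as.matrix(EBImage::imageData(filled)) > 0
  fgPix <- img[fg]
  if (length(unique(fgPix)) < 2L) {
    core <- spread
  } else {
    thr2 <- otsuThreshold(fgPix)
    dense <- img > thr2 & spread
    dense <- EBImage::closing(dense, brush)
    lab <- EBImage::bwlabel(dense)
    sizes <- table(as.vector(lab)[as.vector(lab) > 0])
    core <- if (length(sizes))
      as.matrix(EBImage::imageData(lab)) ==
        as.integer(names(sizes)[which.max(sizes)])
    else spread
  }
  data.frame(spread_area = sum(spread),
             core_area = min(sum(core), sum(spread)),
             n_objects = nObj)
}

#' Cytoskeleton area ratio
#'
#' Ratio of actin-positive area outside the initial spheroid core to the
#' core area.  Actin positivity is called by a global Otsu threshold, so
#' the ratio is invariant to uniform intensity rescaling.
#'
#' @param actin actin-channel intensity matrix
#' @param coreMask logical mask of the initial spheroid core
#' @return non-negative numeric ratio.
#' @export
cytoskeletonAreaRatio <- function(actin, coreMask) {
  if (!any(coreMask)) stop("zero core area")
  thr <- otsuThreshold(as.vector(actin))
  pos <- actin > thr
  sum(pos & !coreMask) / sum(coreMask)
}
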