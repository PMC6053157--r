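## Bright-field RBC aggregate detection and sizing.  Aggregates appear as
## dark (light-absorbing) objects on a bright background under white-light
## transmission.  The chain is: illumination correction (flat-fielding by a
## large-scale smooth background estimate) -> global intensity threshold
## (Otsu by default) -> hole filling -> small-object removal -> connected
## component labeling -> pixel-count areas converted to um^2.  No
## distinction is made between rouleaux and three-dimensional clusters, and
## no inter-frame tracking is attempted: objects are re-detected each frame
## and sizes averaged per frame, then per recording.

#' Correct non-uniform illumination in a bright-field frame
#'
#' Divides the frame by a smooth background estimate (Gaussian blur at a
#' scale much larger than a cell) and renormalizes so the corrected frame
#' keeps the original median intensity.  Uneven illumination otherwise
#' splits dark objects at a global threshold (incomplete detection on the
#' dim side of the image).  Flat frames pass through unchanged to within
#' 1e-6 relative.
#'
#' @param frame intensity matrix (rows y, columns x), values > 0 expected
#'   for the background.
#' @param sigma Gaussian blur scale in pixels (default 50, i.e. roughly the
#'   size of the largest aggregates at 0.2 um/px).
#' @return corrected intensity matrix of the same shape.
#' @export
correctIllumination <- function(frame, sigma = 50) {
  if (length(frame) == 0)
    .rheoflowError("rheoflowDomainError", "empty frame")
  bg <- .smoothBackground(frame, sigma)
  if (any(bg <= 0))
    .rheoflowError("rheoflowCorrectionError",
                   "background estimate contains non-positive values")
  corrected <- frame / bg
  corrected * stats::median(frame) / stats::median(corrected)
}

## Large-scale background: Gaussian blur on an odd-reflection padded frame
## (no wrap-around artefacts from EBImage's FFT filtering), cropped back.
.smoothBackground <- function(frame, sigma) {
  ## pad by 3 sigma so the blur kernel fits and almost no Gaussian mass
  ## wraps around the padded image; the scale is capped only when the
  ## frame itself is too small to support it
  sigma <- min(sigma, (min(dim(frame)) - 2) / 3)
  pad <- min(c(dim(frame) - 1, ceiling(3 * sigma)))
  nr <- nrow(frame); nc <- ncol(frame)
  ## odd (anti-mirror) reflection about the edge value: smooth linear
  ## illumination trends continue through the border, so the blurred
  ## background reproduces a ramp exactly instead of flattening its ends
  top <- 2 * matrix(frame[1, ], pad, nc, byrow = TRUE) -
    frame[(pad + 1):2, , drop = FALSE]
  bot <- 2 * matrix(frame[nr, ], pad, nc, byrow = TRUE) -
    frame[(nr - 1):(nr - pad), , drop = FALSE]
  big <- rbind(top, frame, bot)
  left <- 2 * matrix(big[, 1], nrow(big), pad) -
    big[, (pad + 1):2, drop = FALSE]
  right <- 2 * matrix(big[, nc], nrow(big), pad) -
    big[, (nc - 1):(nc - pad), drop = FALSE]
  big <- cbind(left, big, right)
  sm <- EBImage::gblur(EBImage::Image(big), sigma = sigma)
  as.matrix(EBImage::imageData(sm))[pad + seq_len(nr), pad + seq_len(nc)]
}

#' Segment dark aggregates in an illumination-corrected frame
#'
#' Thresholds the frame (objects are the low-intensity regions), fills
#' holes, removes components smaller than `minAreaUm2` and labels the
#' remaining 8-connected components.
#'
#' @param frame illumination-corrected intensity matrix.
#' @param method `"otsu"` (default; Otsu's threshold on the frame histogram)
#'   or `"fixed"`.
#' @param fixedThreshold intensity threshold when `method = "fixed"`.
#' @param minAreaUm2 minimum object area kept, in um^2 (default 20,
#'   approximately one projected red blood cell).
#' @param pixelScale micrometres per pixel (default 0.2).
#' @param excludeBorder drop objects touching the frame border
#'   (default FALSE).
#' @return an [AggregateMask-class]; a blank frame yields zero labels.
#' @export
segmentAggregates <- function(frame, method = c("otsu", "fixed"),
                              fixedThreshold = NULL, minAreaUm2 = 20,
                              pixelScale = 0.2, excludeBorder = FALSE) {
  method <- match.arg(method)
  rng <- range(frame)
  if (diff(rng) == 0)
    return(new("AggregateMask",
               labels = matrix(0L, nrow(frame), ncol(frame))))
  scaled <- (frame - rng[1]) / diff(rng)
  thr <- if (method == "otsu") {
    ## Otsu always splits the histogram somewhere, even on an object-free
    ## frame of pure noise; capping the threshold a few noise widths below
    ## the background median keeps blank frames blank
    floorThr <- stats::median(scaled) - 5 * stats::mad(scaled)
    min(as.numeric(EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))),
        floorThr)
  } else {
    if (is.null(fixedThreshold))
      .rheoflowError("rheoflowConfigError",
                     "fixedThreshold required for method = 'fixed'")
    (fixedThreshold - rng[1]) / diff(rng)
  }
  mask <- scaled < thr                       # aggregates are dark
  filled <- EBImage::fillHull(EBImage::Image(mask * 1))
  lab <- EBImage::bwlabel(filled)
  labm <- as.matrix(EBImage::imageData(lab))
  if (excludeBorder && max(labm) > 0) {
    border <- unique(c(labm[1, ], labm[nrow(labm), ],
                       labm[, 1], labm[, ncol(labm)]))
    labm[labm %in% setdiff(border, 0)] <- 0L
  }
  if (max(labm) > 0) {
    minPx <- minAreaUm2 / pixelScale^2
    cnt <- tabulate(labm[labm > 0])
    drop <- which(cnt < minPx)
    if (length(drop)) labm[labm %in% drop] <- 0L
    ## relabel contiguously
    keep <- sort(unique(labm[labm > 0]))
    labm <- matrix(match(labm, keep, nomatch = 0L) * 1L,
                   nrow(labm), ncol(labm))
  }
  new("AggregateMask", labels = labm)
}

#' Measure aggregate areas in um^2
#'
#' Converts per-label pixel counts with the exactly quadratic rule
#' `area = pixels * pixelScale^2`.
#'
#' @param mask an [AggregateMask-class].
#' @param pixelScale micrometres per pixel.
#' @return numeric vector of areas ordered by label; empty for an empty
#'   mask.
#' @examples
#' m <- new("AggregateMask", labels = matrix(rep(c(0L, 1L), c(50, 50)), 10))
#' measureAggregateAreas(m, 0.2)  # 50 px * 0.04 = 2 um^2
#' @export
measureAggregateAreas <- function(mask, pixelScale) {
  stopifnot(is(mask, "AggregateMask"))
  lab <- mask@labels
  if (max(lab) == 0) return(numeric(0))
  tabulate(lab[lab > 0]) * pixelScale^2
}

#' Summarize a recording of per-frame aggregate areas
#'
#' Computes the mean aggregate area of each frame, then the recording-level
#' mean and standard error over the per-frame means.  Frames without any
#' detected aggregate are excluded from the mean-of-means and counted in
#' `nEmptyFrames`; a recording with only empty frames yields `NA` summary
#' statistics rather than an error.
#'
#' @param perFrameAreas list of numeric vectors of areas (um^2), one per
#'   frame.
#' @param binEdges strictly increasing size-class edges (um^2) used for the
#'   pooled size histogram; the default follows the aggregate-size ranges
#'   seen at low hematocrit (single cells to ~3500 um^2 clusters).
#' @return an [AggregateRecord-class].
#' @examples
#' rec <- summarizeRecording(list(c(100, 300), 200))
#' recordingMean(rec)  # 200
#' @export
summarizeRecording <- function(perFrameAreas,
                               binEdges = c(0, 100, 500, 1500, 3500, Inf)) {
  if (!is.list(perFrameAreas)) perFrameAreas <- list(perFrameAreas)
  pfm <- vapply(perFrameAreas,
                function(a) if (length(a)) mean(a) else NA_real_, numeric(1))
  nonEmpty <- pfm[is.finite(pfm)]
  recMean <- if (length(nonEmpty)) mean(nonEmpty) else NA_real_
  recSE <- if (length(nonEmpty) > 1)
    stats::sd(nonEmpty) / sqrt(length(nonEmpty)) else
      if (length(nonEmpty) == 1) 0 else NA_real_
  pooled <- unlist(perFrameAreas)
  counts <- classifySizeBins(pooled, binEdges)
  new("AggregateRecord", perFrameAreas = perFrameAreas, perFrameMean = pfm,
      recordingMean = recMean, recordingStderr = recSE,
      sizeClassCounts = counts, binEdges = binEdges,
      nEmptyFrames = sum(!is.finite(pfm)))
}

#' Histogram areas into size classes
#'
#' Counts areas into half-open bins `[e_k, e_{k+1})`; counts always sum to
#' the number of areas.
#'
#' @param areas numeric vector of areas (um^2).
#' @param binEdges strictly increasing edges; use `Inf` as the last edge for
#'   an unbounded top class.
#' @return named integer vector of counts, one per bin.
#' @examples
#' classifySizeBins(c(90, 150, 2000), c(0, 100, 500, 1500, 3500, Inf))
#' @export
classifySizeBins <- function(areas, binEdges = c(0, 100, 500, 1500, 3500, Inf)) {
  if (is.unsorted(binEdges, strictly = TRUE))
    .rheoflowError("rheoflowConfigError",
                   "binEdges must be strictly increasing")
  nb <- length(binEdges) - 1
  labels <- paste0("[", binEdges[-length(binEdges)], ",",
                   binEdges[-1], ")")
  if (!length(areas))
    return(stats::setNames(integer(nb), labels))
  idx <- findInterval(areas, binEdges, rightmost.closed = FALSE)
  idx <- idx[idx >= 1 & idx <= nb]
  stats::setNames(tabulate(idx, nbins = nb), labels)
}

#' Run the aggregate detection chain over a whole recording
#'
#' Applies [correctIllumination()], [segmentAggregates()] and
#' [measureAggregateAreas()] to every frame of a stack and summarizes the
#' recording with [summarizeRecording()].
#'
#' @param stack a [FrameStack-class].
#' @param method,fixedThreshold,minAreaUm2,excludeBorder passed to
#'   [segmentAggregates()].
#' @param illuminationSigma blur scale for [correctIllumination()].
#' @param binEdges size-class edges for [summarizeRecording()].
#' @return an [AggregateRecord-class].
#' @export
analyzeAggregateStack <- function(stack, method = "otsu",
                                  fixedThreshold = NULL, minAreaUm2 = 20,
                                  excludeBorder = FALSE,
                                  illuminationSigma = 50,
                                  binEdges = c(0, 100, 500, 1500, 3500, Inf)) {
  stopifnot(is(stack, "FrameStack"))
  areas <- lapply(stack@frames, function(fr) {
    corr <- correctIllumination(fr, sigma = illuminationSigma)
    m <- segmentAggregates(corr, method = method,
                           fixedThreshold = fixedThreshold,
                           minAreaUm2 = minAreaUm2,
                           pixelScale = stack@pixelScale,
                           excludeBorder = excludeBorder)
    measureAggregateAreas(m, stack@pixelScale)
  })
  summarizeRecording(areas, binEdges = binEdges)
}
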