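## Fluorescence image quantification: background subtraction, Otsu masks,
## Manders co-localization, line profiles, membrane/cytosol ratios,
## marker-defined region intensities.
##
## Images are plain numeric matrices img[row, col] (or 3-D arrays for
## stacks); point coordinates are (x, y) = (column, row), 1-based,
## continuous.

#' Read a single- or multi-page TIFF channel
#'
#' @param path TIFF file.
#' @return Numeric matrix (single page) or 3-D array (stack).
#' @export
readImageChannel <- function(path) {
    img <- EBImage::readImage(path)
    a <- EBImage::imageData(img)
    ## EBImage stores x (col) first; transpose into row-major convention
    if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
}

#' Rolling-ball style background subtraction
#'
#' Estimates the background as the grayscale morphological opening with a
#' disc structuring element of the given radius (the flat-kernel
#' realisation of rolling-ball subtraction) and subtracts it, clipping at
#' 0. Features narrower than the disc survive; smooth background (constant
#' or slowly varying) maps to 0. Stacks are processed per slice.
#'
#' @param channel Numeric matrix or 3-D array, intensities >= 0.
#' @param radius Structuring-element radius in pixels (default 50;
#'   must fit inside the image).
#' @return Background-subtracted image, same shape.
#' @export
subtractBackground <- function(channel, radius = 50) {
    stopifnot(radius >= 1)
    d <- dim(channel)
    if (2 * radius + 1 > min(d[1L], d[2L]))
        stop("radius ", radius, " exceeds the image size")
    brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
    one <- function(m) {
        rng <- range(m)
        if (rng[2L] == rng[1L]) return(m * 0)
        ## grayscale morphology operates on [0,1]; rescale around it
        scaled <- (m - rng[1L]) / (rng[2L] - rng[1L])
        bg <- EBImage::imageData(EBImage::opening(scaled, brush)) *
            (rng[2L] - rng[1L]) + rng[1L]
        pmax(m - bg, 0)
    }
    if (length(d) == 2L) return(one(channel))
    out <- channel
    for (k in seq_len(d[3L])) out[, , k] <- one(channel[, , k])
    out
}

#' Otsu threshold and foreground mask
#'
#' The threshold maximizes the between-class variance over a 256-bin
#' histogram scaled to the image's min-max range; the mask is the pixels
#' strictly above the threshold. For 3-D stacks the threshold is computed
#' over the whole volume. Ties in the variance criterion resolve to the
#' lowest threshold.
#'
#' @param channel Numeric matrix or array with at least 2 distinct values.
#' @return List with \code{threshold} (intensity units) and \code{mask}
#'   (logical, same shape).
#' @export
otsuThreshold <- function(channel) {
    v <- as.numeric(channel)
    lo <- min(v); hi <- max(v)
    if (hi == lo)
        stop("constant image: no Otsu threshold exists")
    nb <- 256L
    bin <- pmin(floor((v - lo) / (hi - lo) * nb), nb - 1L)  # 0..255
    h <- tabulate(bin + 1L, nbins = nb)
    w <- h / length(v)
    mu <- (seq_len(nb) - 1L) * w
    omega0 <- cumsum(w)[-nb]
    mu0 <- cumsum(mu)[-nb]
    muT <- sum(mu)
    omega1 <- 1 - omega0
    crit <- ifelse(omega0 > 0 & omega1 > 0,
                   (muT * omega0 - mu0)^2 / (omega0 * omega1), -Inf)
    k <- which.max(crit) - 1L                # classes: bins <= k vs > k
    thr <- lo + (k + 1) * (hi - lo) / nb
    mask <- channel > thr
    dim(mask) <- dim(channel)
    list(threshold = thr, mask = mask)
}

#' Manders co-localization coefficients
#'
#' Thresholded (JaCoP-style) definition, the default: M1 is the fraction
#' of channel A's masked intensity that lies where channel B's mask is
#' also on, \code{M1 = sum(A[maskA & maskB]) / sum(A[maskA])}; M2 is
#' symmetric with the roles swapped. Both are in [0, 1] and invariant
#' under positive scaling of a channel. The \code{"plain"} variant uses
#' all of A as the denominator and B's mask alone in the numerator. An
#' empty own-mask makes the corresponding coefficient \code{NA}.
#'
#' @param channelA,channelB Numeric images, same shape.
#' @param maskA,maskB Logical masks (e.g. from \code{\link{otsuThreshold}}).
#' @param variant \code{"thresholded"} (default) or \code{"plain"}.
#' @return List with \code{M1} and \code{M2}, plus the mask pixel counts
#'   \code{nMaskA}, \code{nMaskB}.
#' @export
manders <- function(channelA, maskA, channelB, maskB,
                    variant = c("thresholded", "plain")) {
    variant <- match.arg(variant)
    stopifnot(all(dim(channelA) == dim(maskA)),
              all(dim(channelB) == dim(maskB)),
              all(dim(channelA) == dim(channelB)))
    if (variant == "thresholded") {
        denA <- sum(channelA[maskA]); denB <- sum(channelB[maskB])
        m1 <- if (any(maskA)) sum(channelA[maskA & maskB]) / denA else NA_real_
        m2 <- if (any(maskB)) sum(channelB[maskA & maskB]) / denB else NA_real_
    } else {
        m1 <- if (any(maskA)) sum(channelA[maskB]) / sum(channelA) else NA_real_
        m2 <- if (any(maskB)) sum(channelB[maskA]) / sum(channelB) else NA_real_
    }
    list(M1 = m1, M2 = m2, nMaskA = sum(maskA), nMaskB = sum(maskB))
}

## bilinear interpolation at continuous (x=col, y=row) positions
.bilinear <- function(img, x, y) {
    nr <- nrow(img); nc <- ncol(img)
    x <- pmin(pmax(x, 1), nc); y <- pmin(pmax(y, 1), nr)
    x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
    fx <- x - x0; fy <- y - y0
    img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
        img[cbind(y0, x0 + 1)] * fx * (1 - fy) +
        img[cbind(y0 + 1, x0)] * (1 - fx) * fy +
        img[cbind(y0 + 1, x0 + 1)] * fx * fy
}

## uniform arc-length samples along a polyline (n x 2 matrix of x, y)
.samplePolyline <- function(polyline, step) {
    polyline <- as.matrix(polyline)
    if (nrow(polyline) < 2L)
        stop("polyline needs at least 2 points")
    seg <- diff(polyline)
    len <- sqrt(rowSums(seg^2))
    if (any(len == 0)) {                  # drop duplicated vertices
        keep <- c(TRUE, len > 0)
        polyline <- polyline[keep, , drop = FALSE]
        if (nrow(polyline) < 2L) stop("zero-length polyline")
        seg <- diff(polyline)
        len <- sqrt(rowSums(seg^2))
    }
    total <- sum(len)
    if (total == 0)
        stop("zero-length polyline")
    s <- seq(0, total, by = step)
    cum <- c(0, cumsum(len))
    i <- pmin(findInterval(s, cum, rightmost.closed = TRUE), length(len))
    f <- (s - cum[i]) / len[i]
    cbind(x = polyline[i, 1L] + f * seg[i, 1L],
          y = polyline[i, 2L] + f * seg[i, 2L],
          position = s)
}

#' Normalized intensity profile along a polyline
#'
#' Samples each channel by bilinear interpolation at uniform arc-length
#' steps along the polyline, then min-max normalizes each channel's trace
#' to [0, 1] (a constant trace degenerates to all zeros).
#'
#' @param channels Named list of numeric matrices (one per channel).
#' @param polyline \code{n x 2} matrix of (x, y) points, in image bounds.
#' @param step Sampling step in pixels (default 1).
#' @param pixelSize Physical pixel size; positions are multiplied by it
#'   (default 1, i.e. positions in pixels).
#' @return \code{data.frame}: \code{position} plus one normalized-intensity
#'   column per channel.
#' @export
lineProfile <- function(channels, polyline, step = 1, pixelSize = 1) {
    if (!is.list(channels)) channels <- list(intensity = channels)
    pts <- .samplePolyline(polyline, step)
    out <- data.frame(position = pts[, "position"] * pixelSize)
    for (nm in names(channels)) {
        v <- .bilinear(channels[[nm]], pts[, "x"], pts[, "y"])
        rng <- range(v)
        out[[nm]] <- if (rng[2L] > rng[1L]) (v - rng[1L]) / diff(rng)
                     else rep(0, length(v))
    }
    out
}

#' Vacuole-membrane to cytosol intensity ratio
#'
#' Ratio of the mean intensity sampled along a membrane polyline to the
#' average of the mean intensities of three circular cytosolic regions.
#'
#' @param channel Numeric matrix.
#' @param membrane \code{n x 2} polyline (x, y) tracing the membrane.
#' @param cytosolDisks List of exactly 3 disks, each \code{c(x, y, r)}.
#' @param step Polyline sampling step in pixels.
#' @return The ratio (scalar). Scale-invariant: multiplying the image by a
#'   positive constant leaves it unchanged.
#' @export
membraneCytosolRatio <- function(channel, membrane, cytosolDisks, step = 1) {
    if (length(cytosolDisks) != 3L)
        stop("exactly 3 cytosol disks are required")
    pts <- .samplePolyline(membrane, step)
    if (any(pts[, "x"] < 1 | pts[, "x"] > ncol(channel) |
            pts[, "y"] < 1 | pts[, "y"] > nrow(channel)))
        stop("membrane polyline leaves the image bounds")
    memMean <- mean(.bilinear(channel, pts[, "x"], pts[, "y"]))
    diskMean <- vapply(cytosolDisks, function(dsk) {
        cx <- dsk[1L]; cy <- dsk[2L]; r <- dsk[3L]
        if (cx - r < 1 || cx + r > ncol(channel) ||
            cy - r < 1 || cy + r > nrow(channel))
            stop("cytosol disk leaves the image bounds")
        rows <- floor(cy - r):ceiling(cy + r)
        cols <- floor(cx - r):ceiling(cx + r)
        g <- expand.grid(y = rows, x = cols)
        inside <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
        mean(channel[cbind(g$y[inside], g$x[inside])])
    }, 0)
    cyt <- mean(diskMean)
    if (cyt == 0)
        stop("cytosol mean intensity is zero; ratio undefined")
    memMean / cyt
}

## connected-component labeling: EBImage bwlabel in 2-D (8-connectivity);
## BFS with 26-neighbourhood for 3-D stacks
.labelComponents <- function(mask) {
    d <- dim(mask)
    if (length(d) == 2L)
        return(EBImage::imageData(EBImage::bwlabel(mask * 1)))
    lab <- array(0L, d)
    off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    off <- off[rowSums(abs(off)) > 0L, , drop = FALSE]
    idx <- which(mask)
    cur <- 0L
    for (seed in idx) {
        if (lab[seed] != 0L) next
        cur <- cur + 1L
        frontier <- seed
        lab[seed] <- cur
        while (length(frontier)) {
            ai <- arrayInd(frontier, d)
            nb <- do.call(rbind, lapply(seq_len(nrow(off)), function(k)
                sweep(ai, 2L, off[k, ], "+")))
            ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
                  nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
                  nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
            nb <- nb[ok, , drop = FALSE]
            lin <- nb[, 1L] + (nb[, 2L] - 1L) * d[1L] +
                (nb[, 3L] - 1L) * d[1L] * d[2L]
            lin <- unique(lin[mask[lin] & lab[lin] == 0L])
            lab[lin] <- cur
            frontier <- lin
        }
    }
    lab
}

#' Mean signal intensity in marker-defined regions
#'
#' Thresholds the marker channel (Otsu), labels connected components
#' (8-connectivity in 2-D, 26-connectivity for stacks), discards regions
#' below the minimum size, and reports the mean of the signal channel in
#' each surviving region.
#'
#' @param signal,marker Numeric images of identical shape.
#' @param minSize Minimum region size in pixels/voxels (default 5).
#' @return \code{data.frame} with \code{region}, \code{size}, \code{mean};
#'   attribute \code{"overallMean"} holds the signal mean over all
#'   marker-positive pixels of surviving regions. Zero rows (with attribute
#'   \code{"empty" = TRUE}) when no region survives.
#' @export
markerRegionIntensity <- function(signal, marker, minSize = 5L) {
    stopifnot(all(dim(signal) == dim(marker)))
    mask <- otsuThreshold(marker)$mask
    lab <- .labelComponents(mask)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= minSize)
    if (length(keep) == 0L) {
        out <- data.frame(region = integer(), size = integer(),
                          mean = numeric())
        attr(out, "empty") <- TRUE
        return(out)
    }
    out <- data.frame(
        region = seq_along(keep),
        size = sizes[keep],
        mean = vapply(keep, function(k) mean(signal[lab == k]), 0))
    attr(out, "overallMean") <- mean(signal[lab %in% keep])
    out
}
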