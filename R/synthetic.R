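## Synthetic-data generators with planted ground truth. Every generator is
## a pure function of its parameters and seed: a single master seed drives
## named substreams so independent stages can be re-seeded independently.

.substreamSeed <- function(seed, name) {
    b <- utf8ToInt(name)
    h <- (sum(b * seq_along(b)) * 97 + as.numeric(seed) * 10007) %%
        2147483647
    as.integer(h)
}

.randomRotation <- function() {
    qr <- qr(matrix(stats::rnorm(9), 3L))
    Q <- qr.Q(qr)
    Q <- Q %*% diag(sign(diag(qr.R(qr))))
    if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
    Q
}

.AA_NO_K <- strsplit("ACDEFGHILMNPQRSTVWY", "")[[1]]

#' Generate a synthetic multi-chain complex with lysine positions
#'
#' Each protein chain is a 3-D random walk with fixed 3.8 Angstrom
#' Calpha-Calpha steps (chains may self-intersect; only pairwise distances
#' matter downstream). About 8\% of residues are lysines, mirroring the
#' typical yeast lysine frequency, at seeded positions (at least 2 per
#' protein). Homo-oligomer copies are rigid transforms of one conformation,
#' so copies superpose with zero RMSD. Proteins are offset from each other
#' so that both short- and long-range inter-protein lysine pairs exist.
#'
#' @param nProteins Number of distinct proteins (default 2).
#' @param copies Copies per protein (scalar or per-protein vector,
#'   default 1); chains are labelled A, B, C, ... across all copies.
#' @param residuesPerChain Residues per chain (default 120).
#' @param seed Master seed.
#' @param lysineFraction Probability a residue is a lysine (default 0.08).
#' @return List with \code{structure} (\linkS4class{StructureModel}),
#'   \code{sequences} (named character vector, accessions P01, P02, ...)
#'   and \code{chainMap} (\code{data.frame}: protein, chain, copy).
#' @export
makeComplex <- function(nProteins = 2L, copies = 1L,
                        residuesPerChain = 120L, seed = 1L,
                        lysineFraction = 0.08) {
    stopifnot(nProteins >= 1L, all(copies >= 1L), residuesPerChain >= 1L)
    set.seed(.substreamSeed(seed, "complex"))
    copies <- rep_len(as.integer(copies), nProteins)
    n <- as.integer(residuesPerChain)
    sequences <- character(nProteins)
    names(sequences) <- sprintf("P%02d", seq_len(nProteins))
    chainLetters <- c(LETTERS, letters)
    atoms <- list(); chainMap <- list(); ci <- 0L
    for (i in seq_len(nProteins)) {
        steps <- matrix(stats::rnorm(3L * n), ncol = 3L)
        steps <- steps / sqrt(rowSums(steps^2)) * 3.8
        steps[1L, ] <- 0
        xyz <- apply(steps, 2L, cumsum)
        if (n == 1L) xyz <- matrix(xyz, 1L)
        xyz <- sweep(xyz, 2L, c((i - 1L) * 40, 0, 0), "+")
        isLys <- stats::runif(n) < lysineFraction
        if (sum(isLys) < min(2L, n))
            isLys[sample.int(n, min(2L, n))] <- TRUE
        aa <- sample(.AA_NO_K, n, replace = TRUE)
        aa[isLys] <- "K"
        sequences[i] <- paste(aa, collapse = "")
        for (cp in seq_len(copies[i])) {
            ci <- ci + 1L
            cxyz <- if (cp == 1L) xyz else {
                R <- .randomRotation()
                shift <- stats::rnorm(3L)
                shift <- shift / sqrt(sum(shift^2)) * 50
                sweep(xyz %*% R, 2L, shift, "+")
            }
            atoms[[ci]] <- data.frame(
                chain = chainLetters[ci], resno = seq_len(n),
                resname = bio3d::aa123(aa), x = cxyz[, 1L], y = cxyz[, 2L],
                z = cxyz[, 3L], present = TRUE, stringsAsFactors = FALSE)
            chainMap[[ci]] <- data.frame(protein = names(sequences)[i],
                                         chain = chainLetters[ci], copy = cp,
                                         stringsAsFactors = FALSE)
        }
    }
    structure <- new("StructureModel", id = sprintf("synthetic-%d", seed),
                     atoms = do.call(rbind, atoms))
    list(structure = structure, sequences = sequences,
         chainMap = do.call(rbind, chainMap))
}

## all candidate lysine-lysine pairs of a complex with their mapped
## (min-over-copies) distances
.lysinePairs <- function(complex, assignment, maxDistance) {
    lys <- lapply(complex$sequences, function(s)
        which(strsplit(s, "")[[1]] == "K"))
    accs <- names(complex$sequences)
    cand <- list(); k <- 0L
    for (i in seq_along(accs)) for (j in i:length(accs)) {
        la <- lys[[i]]; lb <- lys[[j]]
        for (ra in la) for (rb in lb) {
            if (i == j && rb <= ra) next
            k <- k + 1L
            cand[[k]] <- data.frame(proteinA = accs[i], residueA = ra,
                                    proteinB = accs[j], residueB = rb,
                                    stringsAsFactors = FALSE)
        }
    }
    cand <- do.call(rbind, cand)
    tab <- CrossLinkTable(cand$proteinA, cand$residueA, cand$proteinB,
                          cand$residueB)
    mapped <- mapCrossLinks(tab, complex$structure, assignment, maxDistance)
    cbind(as.data.frame(tab@records)[, 1:4],
          distance = mapped$distance, status = mapped$status)
}

#' Sample a cross-link table with planted restraint outcomes
#'
#' Draws satisfying links from lysine pairs whose mapped (min-over-copies)
#' distance is at most \code{maxDistance - margin}, violating links from
#' pairs beyond \code{maxDistance + margin}, and decoy links between
#' proteins absent from the structure. All links are unique, so the table
#' is born deduplicated; the planted satisfied fraction is exactly
#' \code{nSatisfying / (nSatisfying + nViolating)}.
#'
#' @param complex Output of \code{\link{makeComplex}}.
#' @param nSatisfying,nViolating,nDecoyPairs Link counts per class.
#' @param maxDistance Restraint in Angstrom (default 35).
#' @param margin Guard band around the restraint (default 2 Angstrom), so
#'   planted classes are unambiguous under noise-free remeasurement.
#' @param seed Master seed.
#' @param assignment Optional precomputed \linkS4class{ChainAssignment}.
#' @return List with \code{links} (\linkS4class{CrossLinkTable}),
#'   \code{truth} (\code{data.frame} aligned with the records:
#'   \code{trueDistance}, \code{satisfied}; NA for decoys) and
#'   \code{assignment}.
#' @export
sampleCrossLinks <- function(complex, nSatisfying, nViolating,
                             nDecoyPairs = 0L, maxDistance = 35,
                             margin = 2, seed = 1L, assignment = NULL) {
    set.seed(.substreamSeed(seed, "links"))
    if (is.null(assignment))
        assignment <- buildChainAssignment(complex$structure,
                                           complex$sequences)
    pairs <- .lysinePairs(complex, assignment, maxDistance)
    pairs <- pairs[pairs$status == "mapped", , drop = FALSE]
    satPool <- which(pairs$distance <= maxDistance - margin)
    vioPool <- which(pairs$distance > maxDistance + margin)
    if (length(satPool) < nSatisfying)
        stop("only ", length(satPool), " satisfying lysine pairs available; ",
             nSatisfying, " requested")
    if (length(vioPool) < nViolating)
        stop("only ", length(vioPool), " violating lysine pairs available; ",
             nViolating, " requested")
    pick <- c(satPool[sample.int(length(satPool), nSatisfying)],
              vioPool[sample.int(length(vioPool), nViolating)])
    sel <- pairs[pick, , drop = FALSE]
    truth <- data.frame(trueDistance = sel$distance,
                        satisfied = sel$distance <= maxDistance)
    if (nDecoyPairs > 0L) {
        da <- sprintf("DECOY%02d", seq_len(nDecoyPairs))
        db <- sprintf("DECOY%02d", seq_len(nDecoyPairs) + nDecoyPairs)
        sel <- rbind(sel[, 1:4], data.frame(
            proteinA = da, residueA = sample.int(100L, nDecoyPairs, TRUE),
            proteinB = db, residueB = sample.int(100L, nDecoyPairs, TRUE),
            stringsAsFactors = FALSE))
        truth <- rbind(truth, data.frame(trueDistance = NA_real_,
                                         satisfied = NA)[rep(1L, nDecoyPairs), ])
    } else {
        sel <- sel[, 1:4]
    }
    n <- nrow(sel)
    links <- CrossLinkTable(sel$proteinA, sel$residueA, sel$proteinB,
                            sel$residueB,
                            score = round(stats::runif(n, 50, 150), 2),
                            fdr = round(stats::runif(n, 0, 0.02), 4),
                            csmCount = sample.int(3L, n, TRUE),
                            source = "synthetic", deduplicated = TRUE)
    rownames(truth) <- NULL
    list(links = links, truth = truth, assignment = assignment)
}

#' Synthetic SILAC protein-group table with planted enrichment
#'
#' Intensities are log-normal: per-protein base abundance plus replicate
#' channel noise on the log2 scale. Enriched proteins carry
#' \code{effectLog2} on the heavy channel (sign flipped in the
#' \code{"reverse"} labeling orientation, emulating a label swap).
#'
#' @param nProteins,nEnriched Protein counts (enriched are the first
#'   \code{nEnriched} after shuffling).
#' @param effectLog2 Planted log2 enrichment (default 2).
#' @param noiseSd Replicate noise SD on the log2 scale (default 0.25).
#' @param nReplicates Replicates per channel (default 3).
#' @param seed Master seed.
#' @param orientation \code{"forward"} or \code{"reverse"} labeling.
#' @return List with \code{records} (wide-layout \code{data.frame}) and
#'   \code{truth} (\code{protein}, \code{enriched}, \code{effectLog2}).
#' @export
makeSilacDataset <- function(nProteins = 1000L, nEnriched = 50L,
                             effectLog2 = 2, noiseSd = 0.25,
                             nReplicates = 3L, seed = 1L,
                             orientation = c("forward", "reverse")) {
    orientation <- match.arg(orientation)
    stopifnot(nEnriched <= nProteins, noiseSd > 0)
    set.seed(.substreamSeed(seed, "silac"))
    prot <- sprintf("Y%04d", seq_len(nProteins))
    enriched <- seq_len(nProteins) %in% sample.int(nProteins, nEnriched)
    base <- stats::rnorm(nProteins, mean = 25, sd = 2)   # log2 abundance
    sgn <- if (orientation == "forward") 1 else -1
    rec <- data.frame(protein = prot, stringsAsFactors = FALSE)
    for (r in seq_len(nReplicates)) {
        h <- base + sgn * effectLog2 * enriched +
            stats::rnorm(nProteins, 0, noiseSd)
        l <- base + stats::rnorm(nProteins, 0, noiseSd)
        rec[[paste0("heavy_", r)]] <- 2^h
        rec[[paste0("light_", r)]] <- 2^l
    }
    list(records = rec,
         truth = data.frame(protein = prot, enriched = enriched,
                            effectLog2 = sgn * effectLog2 * enriched,
                            stringsAsFactors = FALSE))
}

.addSpot <- function(img, x, y, sigma, amp = 1) {
    w <- ceiling(4 * sigma)
    rows <- max(1L, round(y) - w):min(nrow(img), round(y) + w)
    cols <- max(1L, round(x) - w):min(ncol(img), round(x) + w)
    g <- outer(rows - y, cols - x, function(dy, dx)
        exp(-(dx^2 + dy^2) / (2 * sigma^2)))
    img[rows, cols] <- img[rows, cols] + amp * g
    img
}

.placePoints <- function(n, size, minSep, margin, avoid = NULL) {
    pts <- matrix(numeric(0), 0L, 2L)
    tries <- 0L
    while (nrow(pts) < n) {
        p <- stats::runif(2L, margin, size - margin)
        all <- rbind(pts, avoid)
        if (nrow(all) == 0L ||
            min(sqrt(rowSums(sweep(all, 2L, p)^2))) >= minSep)
            pts <- rbind(pts, p)
        tries <- tries + 1L
        if (tries > 10000L * n)
            stop("could not place ", n, " puncta with separation ", minSep)
    }
    pts
}

#' Synthetic two-channel punctate images with planted overlap
#'
#' Channel A holds \code{nPuncta} Gaussian puncta; channel B holds the same
#' number, of which a fraction \code{overlapFraction} sit exactly on A
#' puncta and the rest are placed well away from them. Gaussian noise is
#' added and intensities clipped at 0. With well-separated puncta the
#' thresholded Manders coefficients recover \code{overlapFraction}.
#'
#' @param size Image side in pixels (default 128).
#' @param nPuncta Puncta per channel (default 30).
#' @param overlapFraction Planted overlap fraction in [0, 1].
#' @param psfSigma Gaussian spot sigma in pixels (default 1.5).
#' @param noiseSd Additive Gaussian noise SD (spot peak height is 1;
#'   default 0.01, i.e. SNR 100).
#' @param seed Master seed.
#' @param minSep Minimum center separation in pixels (default 9).
#' @return List with \code{channelA}, \code{channelB} (matrices) and
#'   \code{truth} (overlap fraction, puncta positions).
#' @export
makeColocImages <- function(size = 128L, nPuncta = 30L,
                            overlapFraction = 0.5, psfSigma = 1.5,
                            noiseSd = 0.01, seed = 1L, minSep = 9) {
    stopifnot(overlapFraction >= 0, overlapFraction <= 1)
    set.seed(.substreamSeed(seed, "coloc"))
    margin <- ceiling(4 * psfSigma) + 2
    posA <- .placePoints(nPuncta, size, minSep, margin)
    nShared <- round(overlapFraction * nPuncta)
    shared <- if (nShared > 0L)
        posA[sample.int(nPuncta, nShared), , drop = FALSE]
    else matrix(numeric(0), 0L, 2L)
    posBfree <- .placePoints(nPuncta - nShared, size, minSep, margin,
                             avoid = posA)
    posB <- rbind(shared, posBfree)
    a <- matrix(0, size, size); b <- matrix(0, size, size)
    for (k in seq_len(nrow(posA)))
        a <- .addSpot(a, posA[k, 1L], posA[k, 2L], psfSigma)
    for (k in seq_len(nrow(posB)))
        b <- .addSpot(b, posB[k, 1L], posB[k, 2L], psfSigma)
    a <- pmax(a + stats::rnorm(length(a), 0, noiseSd), 0)
    b <- pmax(b + stats::rnorm(length(b), 0, noiseSd), 0)
    list(channelA = a, channelB = b,
         truth = list(overlap = overlapFraction, positionsA = posA,
                      positionsB = posB))
}

#' Synthetic vacuole-membrane ring image with planted enrichment
#'
#' A ring (annulus) at \code{enrichmentRatio} times the uniform background
#' intensity, plus Gaussian noise. The ROI sidecar holds the membrane
#' polyline (points around the ring) and three interior cytosol disks, in
#' the layout \code{\link{membraneCytosolRatio}} consumes.
#'
#' @param size Image side in pixels (default 128).
#' @param ringRadius Ring radius in pixels (must fit inside the image).
#' @param enrichmentRatio Planted membrane/cytosol intensity ratio.
#' @param noiseSd Additive noise SD relative to a background of 0.2.
#' @param seed Master seed.
#' @param ringWidth Half-width of the annulus in pixels (default 1.5).
#' @return List with \code{channel}, \code{rois} (list: \code{membrane}
#'   polyline, \code{cytosol} list of 3 disks \code{c(x, y, r)}) and
#'   \code{truth} (the enrichment ratio).
#' @export
makeMembraneImage <- function(size = 128L, ringRadius = 40,
                              enrichmentRatio = 4, noiseSd = 0.005,
                              seed = 1L, ringWidth = 1.5) {
    cx <- (size + 1) / 2; cy <- (size + 1) / 2
    if (ringRadius + ringWidth >= size / 2)
        stop("ring does not fit inside the image")
    set.seed(.substreamSeed(seed, "membrane"))
    bg <- 0.2
    d <- sqrt(outer(seq_len(size) - cy, rep(1, size))^2 +
              outer(rep(1, size), seq_len(size) - cx)^2)
    img <- matrix(bg, size, size)
    img[abs(d - ringRadius) <= ringWidth] <- bg * enrichmentRatio
    img <- pmax(img + stats::rnorm(length(img), 0, noiseSd), 0)
    theta <- seq(0, 2 * pi, length.out = 73L)
    membrane <- cbind(x = cx + ringRadius * cos(theta),
                      y = cy + ringRadius * sin(theta))
    rd <- ringRadius / 2.5
    cytosol <- lapply(c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3),
                      function(a) c(cx + rd * cos(a), cy + rd * sin(a), 6))
    list(channel = img, rois = list(membrane = membrane, cytosol = cytosol),
         truth = enrichmentRatio)
}
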