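test_that("background subtraction removes flat and smooth backgrounds", {
    flat <- matrix(5, 64, 64)
    expect_equal(subtractBackground(flat, radius = 10),
                 matrix(0, 64, 64))
    expect_error(subtractBackground(flat, radius = 64), "exceeds")
    # a single bright peak narrower than the ball survives within 5%
    img <- matrix(10, 64, 64)
    img[32, 32] <- 110
    out <- subtractBackground(img, radius = 10)
    expect_gt(out[32, 32], 0.95 * 100)
    # gradient background + puncta: local contrast increases
    grad <- outer(seq(0, 20, length.out = 64), rep(1, 64))
    img2 <- grad
    img2[16, 16] <- img2[16, 16] + 50
    out2 <- subtractBackground(img2, radius = 10)
    contrastBefore <- img2[16, 16] - mean(img2[10:22, 10:22])
    contrastAfter <- out2[16, 16] - mean(out2[10:22, 10:22])
    expect_gt(contrastAfter, contrastBefore)
})

test_that("Otsu separates a clean bimodal image exactly", {
    set.seed(83)
    v <- c(rep(10, 900), rep(200, 100))
    img <- matrix(sample(v), 50, 20)
    res <- otsuThreshold(img)
    expect_identical(res$mask, img == 200)
    expect_error(otsuThreshold(matrix(3, 5, 5)), "constant")
})

test_that("Otsu equals the exhaustive 256-level search oracle", {
    set.seed(89)
    for (k in 1:10) {
        img <- matrix(c(rnorm(600, 0.3, 0.1), rnorm(424, 0.7, 0.1)), 32, 32)
        res <- otsuThreshold(img)
        expect_equal(res$threshold, otsuOracle(img), tolerance = 1e-12)
    }
})

test_that("inverting intensities complements the Otsu classes", {
    set.seed(97)
    img <- matrix(c(runif(800, 0, 0.2), runif(224, 0.7, 1)), 32, 32)
    m <- otsuThreshold(img)$mask
    mInv <- otsuThreshold(max(img) - img)$mask
    # foreground of the inverted image is the (strict) background of the
    # original up to pixels landing exactly on the threshold bin edge
    expect_gt(mean(mInv == !m), 0.999)
})

test_that("Manders coefficients satisfy their limiting contracts", {
    img <- matrix(runif(400), 20, 20)
    mask <- img > 0.5
    both <- manders(img, mask, img, mask)
    expect_equal(both$M1, 1)
    expect_equal(both$M2, 1)
    maskL <- maskR <- matrix(FALSE, 20, 20)
    maskL[, 1:8] <- TRUE; maskR[, 13:20] <- TRUE
    disjoint <- manders(img, maskL, img, maskR)
    expect_equal(disjoint$M1, 0)
    expect_equal(disjoint$M2, 0)
    none <- manders(img, matrix(FALSE, 20, 20), img, maskR)
    expect_true(is.na(none$M1))
})

test_that("Manders lie in [0,1] and are scale-invariant", {
    set.seed(101)
    for (k in 1:10) {
        a <- matrix(runif(1024), 32); b <- matrix(runif(1024), 32)
        ma <- a > runif(1); mb <- b > runif(1)
        if (!any(ma) || !any(mb)) next
        m <- manders(a, ma, b, mb)
        expect_gte(m$M1, 0); expect_lte(m$M1, 1)
        expect_gte(m$M2, 0); expect_lte(m$M2, 1)
        mScaled <- manders(a * 7.3, ma, b * 0.2, mb)
        expect_equal(mScaled$M1, m$M1)
        expect_equal(mScaled$M2, m$M2)
        mPlain <- manders(a, ma, b, mb, variant = "plain")
        expect_gte(mPlain$M1, 0); expect_lte(mPlain$M1, 1)
    }
})

test_that("line profiles normalize per channel and handle degeneracy", {
    flat <- matrix(4, 32, 32)
    prof <- lineProfile(list(ch = flat), cbind(c(2, 30), c(16, 16)))
    expect_true(all(prof$ch == 0))
    # axis-aligned line over a linear ramp: per-pixel oracle
    ramp <- matrix(rep(seq_len(32), each = 32), 32, 32, byrow = TRUE)
    ramp <- t(ramp)  # value = column index
    ramp <- outer(rep(1, 32), seq_len(32))
    prof2 <- lineProfile(list(ch = ramp), cbind(c(1, 32), c(10, 10)),
                         step = 1)
    expect_equal(prof2$ch, (seq(1, 32) - 1) / 31, tolerance = 1e-12)
    expect_equal(max(prof2$ch), 1)
    expect_error(lineProfile(list(ch = ramp), cbind(c(5, 5), c(7, 7))),
                 "zero-length")
})

test_that("a diameter line across a ring peaks at the two radii", {
    mem <- makeMembraneImage(size = 128, ringRadius = 40, noiseSd = 1e-4,
                             seed = 103)
    prof <- lineProfile(list(ch = mem$channel),
                        cbind(c(64.5 - 55, 64.5 + 55), c(64.5, 64.5)))
    peaks <- prof$position[prof$ch > 0.8]
    expect_true(any(abs(peaks - (55 - 40)) <= 2))
    expect_true(any(abs(peaks - (55 + 40)) <= 2))
    expect_false(any(abs(peaks - 55) <= 25))   # no peak at the center
})

test_that("membrane/cytosol ratios recover uniform and planted values", {
    flat <- matrix(3, 64, 64)
    disks <- list(c(20, 20, 4), c(40, 20, 4), c(30, 44, 4))
    line <- cbind(c(10, 54), c(32, 32))
    expect_equal(membraneCytosolRatio(flat, line, disks), 1.0)
    # membrane at 200 over cytosol at 50 gives exactly 4
    img <- matrix(50, 64, 64)
    img[32, ] <- 200
    expect_equal(membraneCytosolRatio(img, line, disks), 4.0)
    expect_error(membraneCytosolRatio(flat, line, disks[1:2]), "3")
    expect_error(membraneCytosolRatio(flat * 0, line, disks), "zero")
    # scale invariance
    mem <- makeMembraneImage(seed = 107)
    r1 <- membraneCytosolRatio(mem$channel, mem$rois$membrane,
                               mem$rois$cytosol)
    r2 <- membraneCytosolRatio(mem$channel * 3.7, mem$rois$membrane,
                               mem$rois$cytosol)
    expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("marker-defined regions report planted signal means", {
    marker <- matrix(0.05, 64, 64)
    marker[10:15, 10:15] <- 1
    marker[40:47, 40:47] <- 1
    signal <- matrix(7, 64, 64)
    signal[10:15, 10:15] <- 50
    signal[40:47, 40:47] <- 150
    out <- markerRegionIntensity(signal, marker)
    expect_equal(nrow(out), 2L)
    expect_setequal(out$mean, c(50, 150))
    expect_setequal(out$size, c(36L, 64L))
    # one blob with uniform signal
    m1 <- matrix(0, 32, 32); m1[5:9, 5:9] <- 1
    s1 <- matrix(100, 32, 32)
    expect_equal(markerRegionIntensity(s1, m1)$mean, 100)
    # blobs below the minimum size are excluded
    m2 <- matrix(0, 32, 32); m2[5:9, 5:9] <- 1; m2[20, 20] <- 1
    expect_equal(nrow(markerRegionIntensity(s1, m2, minSize = 5)), 1L)
})

test_that("3-D stacks use volume Otsu and 26-connected components", {
    marker <- array(0, c(16, 16, 4))
    marker[4:6, 4:6, 1:2] <- 1
    marker[12:14, 12:14, 3:4] <- 1
    # the two blobs touch nothing across slices except themselves
    signal <- array(1, c(16, 16, 4))
    signal[4:6, 4:6, 1:2] <- 30
    signal[12:14, 12:14, 3:4] <- 90
    out <- markerRegionIntensity(signal, marker)
    expect_equal(nrow(out), 2L)
    expect_setequal(out$mean, c(30, 90))
    expect_setequal(out$size, c(18L, 18L))
})
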