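## SILAC enrichment statistics: normalized log2 H/L ratios, Student tests,
## significance tiers, label-swap concordance.

.silacMatrices <- function(records) {
    hv <- grep("^heavy_", colnames(records), value = TRUE)
    lv <- grep("^light_", colnames(records), value = TRUE)
    if (length(hv) == 0L || length(hv) != length(lv))
        stop("records need matching heavy_<i> / light_<i> intensity columns")
    hv <- hv[order(as.integer(sub("heavy_", "", hv)))]
    lv <- lv[order(as.integer(sub("light_", "", lv)))]
    list(H = as.matrix(records[, hv, drop = FALSE]),
         L = as.matrix(records[, lv, drop = FALSE]),
         protein = as.character(records$protein))
}

#' Read a protein-groups table into the wide SILAC layout
#'
#' Maps arbitrary column names onto the layout the statistics functions
#' expect: a \code{protein} column plus per-replicate \code{heavy_<i>} and
#' \code{light_<i>} intensity columns.
#'
#' @param path TSV file with a header row.
#' @param proteinCol Name of the protein accession column.
#' @param heavyCols,lightCols Character vectors of per-replicate heavy and
#'   light intensity column names, in matching replicate order.
#' @return \code{data.frame} in the wide layout.
#' @export
readProteinGroups <- function(path, proteinCol, heavyCols, lightCols) {
    if (length(heavyCols) != length(lightCols))
        stop("heavyCols and lightCols must pair up per replicate")
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE,
                            quote = "", comment.char = "")
    for (nm in c(proteinCol, heavyCols, lightCols))
        if (!nm %in% colnames(df)) stop("column not found: ", nm)
    out <- data.frame(protein = as.character(df[[proteinCol]]),
                      stringsAsFactors = FALSE)
    for (i in seq_along(heavyCols)) {
        out[[paste0("heavy_", i)]] <- as.numeric(df[[heavyCols[i]]])
        out[[paste0("light_", i)]] <- as.numeric(df[[lightCols[i]]])
    }
    out
}

#' Per-protein normalized log2 heavy/light ratios
#'
#' A replicate's ratio is computable only when both channels are positive
#' (no pseudocounts; zero-intensity channels make the replicate missing for
#' that protein). With \code{normalization = "median"} the per-replicate
#' median of the log2 ratios is subtracted, so each replicate's median is 0.
#'
#' @param records Wide-layout \code{data.frame} (see
#'   \code{\link{readProteinGroups}}).
#' @param normalization \code{"median"} (default) or \code{"none"}.
#' @return List with \code{log2Ratios} (protein x replicate matrix, NA
#'   where not computable), \code{log2Ratio} (per-protein mean across
#'   replicates), \code{log10Intensity} (log10 of the summed heavy+light
#'   intensity), \code{protein}, and \code{nExcluded} (proteins with no
#'   computable replicate; these are dropped from all outputs).
#' @export
computeLogRatios <- function(records, normalization = c("median", "none")) {
    normalization <- match.arg(normalization)
    m <- .silacMatrices(records)
    ok <- m$H > 0 & m$L > 0
    lr <- matrix(NA_real_, nrow(m$H), ncol(m$H))
    lr[ok] <- log2(m$H[ok] / m$L[ok])
    if (normalization == "median") {
        med <- apply(lr, 2L, stats::median, na.rm = TRUE)
        lr <- sweep(lr, 2L, med)
    }
    testable <- rowSums(ok) > 0L
    tot <- rowSums(m$H + m$L, na.rm = TRUE)
    list(log2Ratios = lr[testable, , drop = FALSE],
         log2Ratio = rowMeans(lr, na.rm = TRUE)[testable],
         log10Intensity = log10(tot[testable]),
         protein = m$protein[testable],
         nExcluded = sum(!testable))
}

## equal-variance two-tailed Student's t with guarded degenerate cases:
## zero pooled variance with zero difference -> p = 1; with nonzero
## difference -> p at the numerical floor (certain difference)
.studentP <- function(x, y = NULL) {
    if (is.null(y)) {                       # one-sample against 0
        n <- length(x)
        if (n < 2L) return(NA_real_)
        s <- stats::sd(x)
        if (s == 0) return(if (mean(x) == 0) 1 else .Machine$double.xmin)
        tstat <- mean(x) / (s / sqrt(n))
        df <- n - 1
    } else {
        nx <- length(x); ny <- length(y)
        if (nx < 2L || ny < 2L) return(NA_real_)
        sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
            (nx + ny - 2)
        if (sp2 == 0)
            return(if (mean(x) == mean(y)) 1 else .Machine$double.xmin)
        tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
        df <- nx + ny - 2
    }
    max(2 * stats::pt(-abs(tstat), df), .Machine$double.xmin)
}

#' Per-protein enrichment test
#'
#' Equal-variance two-tailed Student's t-test per protein, in one of two
#' groupings: \code{"two_group"} (default) compares the log2 heavy
#' intensities against the log2 light intensities across replicates;
#' \code{"one_sample"} tests the replicate log2 ratios against 0. Proteins
#' with fewer than 2 usable replicates per group get \code{p = NA}, tier
#' \code{"ns"}, and \code{tested = FALSE}. A Benjamini-Hochberg adjusted
#' p-value column is emitted for reference but never gates the tiers (the
#' tiers annotate raw p-values).
#'
#' @param records Wide-layout \code{data.frame}.
#' @param mode \code{"two_group"} or \code{"one_sample"}.
#' @param normalization Ratio normalization passed to
#'   \code{\link{computeLogRatios}}.
#' @return \code{data.frame} with \code{protein}, \code{log2Ratio}
#'   (normalized), \code{log10Intensity}, \code{p}, \code{pAdj} (BH),
#'   \code{tier}, \code{tested}.
#' @export
testEnrichment <- function(records, mode = c("two_group", "one_sample"),
                           normalization = "median") {
    mode <- match.arg(mode)
    m <- .silacMatrices(records)
    cr <- computeLogRatios(records, normalization)
    idx <- match(cr$protein, m$protein)
    p <- vapply(seq_along(idx), function(k) {
        i <- idx[k]
        if (mode == "two_group") {
            h <- m$H[i, ]; l <- m$L[i, ]
            .studentP(log2(h[h > 0]), log2(l[l > 0]))
        } else {
            r <- cr$log2Ratios[k, ]
            .studentP(r[!is.na(r)])
        }
    }, 0)
    out <- data.frame(protein = cr$protein, log2Ratio = cr$log2Ratio,
                      log10Intensity = cr$log10Intensity, p = p,
                      pAdj = stats::p.adjust(p, "BH"),
                      tier = tierOf(p), tested = !is.na(p),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Significance tier of a p-value vector
#'
#' Tiers follow the volcano-plot color convention:
#' \code{red} for p < 1e-14, \code{orange} for p < 1e-4, \code{blue} for
#' p < 0.05, \code{ns} otherwise (boundaries are strict).
#'
#' @param p Numeric vector of p-values (NA allowed, mapped to \code{"ns"}).
#' @return Character vector of tiers.
#' @export
tierOf <- function(p) {
    out <- rep("ns", length(p))
    out[!is.na(p) & p < 0.05] <- "blue"
    out[!is.na(p) & p < 1e-4] <- "orange"
    out[!is.na(p) & p < 1e-14] <- "red"
    out
}

#' Tier counts over an enrichment result table
#'
#' @param results Output of \code{\link{testEnrichment}}.
#' @return List with \code{counts} (named: red, orange, blue, ns over the
#'   tested proteins) and \code{tiers} (per-protein tier vector). Counts
#'   sum to the number of tested proteins.
#' @export
tierSignificance <- function(results) {
    tested <- results[results$tested, , drop = FALSE]
    counts <- vapply(c("red", "orange", "blue", "ns"),
                     function(t) sum(tested$tier == t), 0L)
    list(counts = counts, tiers = stats::setNames(results$tier,
                                                  results$protein))
}

#' Concordance between forward and label-swapped runs
#'
#' In the swapped orientation the heavy and light labels are exchanged, so
#' a true enrichment flips sign. The reverse run's ratios are negated
#' before comparison; concordant experiments give a Pearson correlation
#' near 1 and high sign agreement.
#'
#' @param forward,reverse Outputs of \code{\link{testEnrichment}} for the
#'   two labeling orientations.
#' @return List with \code{pairs} (merged per-protein table:
#'   \code{log2Forward}, \code{log2ReverseFlipped}), \code{r} (Pearson
#'   correlation of forward vs negated reverse ratios),
#'   \code{signAgreement} (fraction of shared proteins with matching
#'   sign), and \code{nExcluded} (proteins missing in either run).
#' @export
labelSwapConcordance <- function(forward, reverse) {
    shared <- intersect(forward$protein, reverse$protein)
    if (length(shared) < 3L)
        stop("need at least 3 shared proteins; got ", length(shared))
    f <- forward$log2Ratio[match(shared, forward$protein)]
    r <- -reverse$log2Ratio[match(shared, reverse$protein)]
    list(
        pairs = data.frame(protein = shared, log2Forward = f,
                           log2ReverseFlipped = r,
                           stringsAsFactors = FALSE),
        r = stats::cor(f, r),
        signAgreement = mean(sign(f) == sign(r)),
        nExcluded = length(forward$protein) + length(reverse$protein) -
            2L * length(shared)
    )
}
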