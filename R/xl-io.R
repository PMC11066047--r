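## Cross-link table I/O, FDR filtering, deduplication, classification.

.canonicalOrder <- function(pa, ra, pb, rb) {
    swap <- pb < pa | (pb == pa & rb < ra)
    list(
        proteinA = ifelse(swap, pb, pa),
        residueA = ifelse(swap, rb, ra),
        proteinB = ifelse(swap, pa, pb),
        residueB = ifelse(swap, ra, rb)
    )
}

#' Construct a CrossLinkTable from raw endpoint columns
#'
#' Canonicalizes every record (endpoints sorted lexicographically by
#' accession, then residue) and validates invariants.
#'
#' @param proteinA,proteinB Accession strings.
#' @param residueA,residueB 1-based cross-linked residue positions (lysines).
#' @param score Optional search-engine score (NA allowed).
#' @param fdr Optional false discovery rate, as a fraction in [0, 1].
#' @param csmCount Number of cross-link spectrum matches supporting the pair.
#' @param source Name of the data source.
#' @param fdrThreshold FDR threshold already applied upstream, if any.
#' @param deduplicated Whether the input is already one row per unique pair.
#' @return A \linkS4class{CrossLinkTable}.
#' @export
CrossLinkTable <- function(proteinA, residueA, proteinB, residueB,
                           score = NA_real_, fdr = NA_real_, csmCount = 1L,
                           source = NA_character_, fdrThreshold = NA_real_,
                           deduplicated = FALSE) {
    n <- length(proteinA)
    can <- .canonicalOrder(as.character(proteinA), as.integer(residueA),
                           as.character(proteinB), as.integer(residueB))
    rec <- S4Vectors::DataFrame(
        proteinA = can$proteinA,
        residueA = can$residueA,
        proteinB = can$proteinB,
        residueB = can$residueB,
        score = rep_len(as.numeric(score), n),
        fdr = rep_len(as.numeric(fdr), n),
        csmCount = rep_len(as.integer(csmCount), n)
    )
    new("CrossLinkTable", records = rec, source = source,
        fdrThreshold = fdrThreshold, deduplicated = deduplicated)
}

.defaultColumnMap <- list(proteinA = "protein_a", residueA = "residue_a",
                          proteinB = "protein_b", residueB = "residue_b",
                          score = "score", fdr = "fdr",
                          csmCount = "csm_count")

#' Parse a cross-link identification table (TSV/CSV)
#'
#' Reads a delimited cross-link table into a canonical
#' \linkS4class{CrossLinkTable}. Supplementary-table layouts vary, so the
#' four mandatory endpoint columns are resolved through \code{columnMap};
#' optional score / FDR / CSM-count columns are picked up when mapped and
#' present. The delimiter is sniffed from the header (tab wins over comma)
#' unless forced.
#'
#' Endpoint fields holding multiple accessions separated by \code{";"} take
#' the first accession; such rows are flagged in the
#' \code{"multiAccessionRows"} attribute of the result (ambiguous protein
#' groups are out of scope).
#'
#' @param path Path to the delimited file (with header).
#' @param columnMap Named list mapping the canonical field names
#'   (\code{proteinA}, \code{residueA}, \code{proteinB}, \code{residueB},
#'   and optionally \code{score}, \code{fdr}, \code{csmCount}) to column
#'   names in the file. Defaults to the package's own canonical layout.
#' @param sep Field delimiter; \code{NULL} (default) sniffs it.
#' @param fdrPercent FDR dialect: \code{"auto"} divides the column by 100
#'   when its maximum exceeds 1 (percent dialect), \code{TRUE} always
#'   divides, \code{FALSE} never.
#' @param source Source label stored in the result; defaults to the file name.
#' @return A \linkS4class{CrossLinkTable}; row count equals the file's data
#'   row count.
#' @export
parseCrossLinkTable <- function(path, columnMap = list(), sep = NULL,
                                fdrPercent = "auto", source = basename(path)) {
    if (!file.exists(path))
        stop("file not found: ", path)
    cm <- utils::modifyList(.defaultColumnMap, columnMap)
    if (is.null(sep)) {
        hdr <- readLines(path, n = 1L)
        sep <- if (grepl("\t", hdr)) "\t" else ","
    }
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            quote = "", comment.char = "")
    mandatory <- c("proteinA", "residueA", "proteinB", "residueB")
    for (f in mandatory) {
        if (!cm[[f]] %in% colnames(df))
            stop(sprintf("mandatory column '%s' (mapped from field '%s') is missing",
                         cm[[f]], f))
    }
    getInt <- function(field) {
        raw <- df[[cm[[field]]]]
        val <- suppressWarnings(as.numeric(raw))
        bad <- which(is.na(val) | val != floor(val))
        if (length(bad))
            stop(sprintf("non-integer residue in column '%s' at data line(s): %s",
                         cm[[field]], paste(utils::head(bad, 10L), collapse = ", ")))
        as.integer(val)
    }
    firstAcc <- function(x) sub(";.*$", "", x)
    pa <- as.character(df[[cm$proteinA]])
    pb <- as.character(df[[cm$proteinB]])
    multi <- which(grepl(";", pa) | grepl(";", pb))
    if (length(multi)) {
        warning(length(multi),
                " row(s) carried multi-accession fields; first accession taken")
        pa <- firstAcc(pa); pb <- firstAcc(pb)
    }
    optNum <- function(field, default) {
        nm <- cm[[field]]
        if (!is.null(nm) && nm %in% colnames(df)) as.numeric(df[[nm]])
        else rep(default, nrow(df))
    }
    fdr <- optNum("fdr", NA_real_)
    if (any(!is.na(fdr))) {
        pct <- identical(fdrPercent, TRUE) ||
            (identical(fdrPercent, "auto") && max(fdr, na.rm = TRUE) > 1)
        if (pct) fdr <- fdr / 100
    }
    csm <- optNum("csmCount", 1)
    csm[is.na(csm)] <- 1
    tab <- CrossLinkTable(pa, getInt("residueA"), pb, getInt("residueB"),
                          score = optNum("score", NA_real_), fdr = fdr,
                          csmCount = as.integer(csm), source = source)
    attr(tab, "multiAccessionRows") <- multi
    tab
}

#' Write a CrossLinkTable in the canonical TSV layout
#'
#' Columns \code{protein_a, residue_a, protein_b, residue_b, score, fdr,
#' csm_count} in that stable order, tab-separated. Write/parse/write
#' round-trips are byte-identical for canonical tables.
#'
#' @param table A \linkS4class{CrossLinkTable}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeCrossLinkTable <- function(table, path) {
    rec <- as.data.frame(table@records)
    colnames(rec) <- c("protein_a", "residue_a", "protein_b", "residue_b",
                       "score", "fdr", "csm_count")
    utils::write.table(rec, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Filter cross-links by FDR
#'
#' Retains records with \code{fdr <= threshold}; the boundary is inclusive
#' (the conventional reading of "reported at 2\% FDR").
#'
#' @param table A \linkS4class{CrossLinkTable}.
#' @param threshold FDR threshold as a fraction (0.02 for 2\%).
#' @param keepMissing If \code{FALSE} (default), records without an FDR
#'   value are an error; if \code{TRUE} they are kept and their count is
#'   attached as attribute \code{"nMissingFdr"}.
#' @return The filtered \linkS4class{CrossLinkTable} with
#'   \code{fdrThreshold} set.
#' @export
filterFDR <- function(table, threshold, keepMissing = FALSE) {
    fdr <- table@records$fdr
    miss <- is.na(fdr)
    if (any(miss) && !keepMissing)
        stop(sum(miss), " record(s) lack an fdr value; ",
             "set keepMissing = TRUE to retain them")
    keep <- miss | fdr <= threshold
    out <- new("CrossLinkTable", records = table@records[keep, , drop = FALSE],
               source = table@source, fdrThreshold = threshold,
               deduplicated = table@deduplicated)
    if (keepMissing) attr(out, "nMissingFdr") <- sum(miss)
    out
}

#' Collapse a cross-link table to unique residue pairs
#'
#' One record per canonical endpoint pair ("unique lysine-lysine
#' connection"). CSM counts are summed across the collapsed rows; the best
#' evidence is retained for the scalar fields (maximum score, minimum FDR).
#'
#' @param table A \linkS4class{CrossLinkTable}.
#' @return A deduplicated \linkS4class{CrossLinkTable}. Idempotent.
#' @export
deduplicateUniquePairs <- function(table) {
    rec <- as.data.frame(table@records)
    if (nrow(rec) == 0L) {
        out <- table
        out@deduplicated <- TRUE
        return(out)
    }
    key <- paste(rec$proteinA, rec$residueA, rec$proteinB, rec$residueB,
                 sep = "\r")
    ord <- order(rec$proteinA, rec$residueA, rec$proteinB, rec$residueB)
    rec <- rec[ord, , drop = FALSE]
    key <- key[ord]
    grp <- match(key, unique(key))
    agg <- function(x, f) {
        vapply(split(x, grp), function(v)
            if (all(is.na(v))) NA_real_ else f(v, na.rm = TRUE), 0)
    }
    first <- !duplicated(grp)
    out <- S4Vectors::DataFrame(
        proteinA = rec$proteinA[first],
        residueA = rec$residueA[first],
        proteinB = rec$proteinB[first],
        residueB = rec$residueB[first],
        score = unname(agg(rec$score, max)),
        fdr = unname(agg(rec$fdr, min)),
        csmCount = as.integer(unname(vapply(split(rec$csmCount, grp), sum, 0)))
    )
    new("CrossLinkTable", records = out, source = table@source,
        fdrThreshold = table@fdrThreshold, deduplicated = TRUE)
}

#' Classify cross-links as intra- or inter-protein
#'
#' @param table A deduplicated \linkS4class{CrossLinkTable}.
#' @return A list with \code{nTotal}, \code{nIntra} (both endpoints in the
#'   same protein), \code{nInter}, and \code{nProteins} (distinct accessions
#'   over all endpoints). Always \code{nIntra + nInter == nTotal}.
#' @export
classifyLinks <- function(table) {
    if (!isDeduplicated(table))
        stop("classifyLinks expects a deduplicated table; ",
             "run deduplicateUniquePairs() first")
    rec <- table@records
    intra <- rec$proteinA == rec$proteinB
    list(
        nTotal = nrow(rec),
        nIntra = sum(intra),
        nInter = sum(!intra),
        nProteins = length(unique(c(rec$proteinA, rec$proteinB)))
    )
}
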