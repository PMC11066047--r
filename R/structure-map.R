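## Structure loading, chain assignment, Calpha-Calpha distance mapping.

#' Load a structure as a Calpha model
#'
#' Reads a PDB or mmCIF coordinate file (atom records only; hetero and
#' water records are ignored) and keeps every chain that carries at least
#' one Calpha. Polymer residues lacking a Calpha are retained, flagged
#' \code{present = FALSE}. When alternate conformers exist, the
#' highest-occupancy Calpha is taken (ties broken by altloc identifier
#' order).
#'
#' @param path Path to a \code{.pdb} or \code{.cif}/\code{.mmcif} file.
#' @param id Model identifier; defaults to the file base name.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or \code{"cif"}.
#' @return A \linkS4class{StructureModel}.
#' @export
loadStructure <- function(path, id = NULL,
                          format = c("auto", "pdb", "cif")) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("file not found: ", path)
    if (format == "auto")
        format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
            "cif" else "pdb"
    pdb <- tryCatch(
        if (format == "cif") suppressWarnings(
            bio3d::read.cif(path, verbose = FALSE))
        else bio3d::read.pdb(path, verbose = FALSE),
        error = function(e) stop("could not parse structure file '", path,
                                 "': ", conditionMessage(e)))
    at <- pdb$atom
    at <- at[at$type == "ATOM", , drop = FALSE]
    if (nrow(at) == 0L)
        stop("structure '", path, "' contains no polymer atom records")
    ## one row per (chain, resno) from all polymer atoms
    resKey <- paste(at$chain, at$resno, sep = "\r")
    first <- !duplicated(resKey)
    res <- data.frame(chain = at$chain[first], resno = at$resno[first],
                      resname = at$resid[first], stringsAsFactors = FALSE)
    ## pick the Calpha per residue: highest occupancy, then altloc order
    ca <- at[at$elety == "CA", , drop = FALSE]
    if (nrow(ca) > 0L) {
        occ <- ca$o
        occ[is.na(occ)] <- 1
        alt <- ca$alt
        alt[is.na(alt)] <- ""
        ord <- order(paste(ca$chain, ca$resno, sep = "\r"), -occ, alt)
        ca <- ca[ord, , drop = FALSE]
        ca <- ca[!duplicated(paste(ca$chain, ca$resno, sep = "\r")), ,
                 drop = FALSE]
    }
    idx <- match(paste(res$chain, res$resno, sep = "\r"),
                 paste(ca$chain, ca$resno, sep = "\r"))
    res$x <- ca$x[idx]; res$y <- ca$y[idx]; res$z <- ca$z[idx]
    res$present <- !is.na(idx)
    ## drop chains with no Calpha at all
    keep <- res$chain %in% unique(res$chain[res$present])
    res <- res[keep, , drop = FALSE]
    if (nrow(res) == 0L)
        stop("structure '", path, "' has no chain with a Calpha atom")
    rownames(res) <- NULL
    new("StructureModel", id = if (is.null(id))
        sub("\\.[^.]+$", "", basename(path)) else id, atoms = res)
}

#' Build a StructureModel from coordinate vectors
#'
#' Programmatic constructor used by the synthetic-data generators and by
#' tests; takes parallel vectors of per-residue Calpha records.
#'
#' @param id Model identifier.
#' @param chain,resno,resname,x,y,z,present Parallel per-residue vectors;
#'   \code{present} defaults to \code{TRUE} everywhere.
#' @return A \linkS4class{StructureModel}.
#' @export
StructureModel <- function(id, chain, resno, resname = "ALA",
                           x, y, z, present = TRUE) {
    n <- max(length(chain), length(resno), length(x))
    new("StructureModel", id = id, atoms = data.frame(
        chain = rep_len(as.character(chain), n),
        resno = rep_len(as.integer(resno), n),
        resname = rep_len(as.character(resname), n),
        x = rep_len(as.numeric(x), n), y = rep_len(as.numeric(y), n),
        z = rep_len(as.numeric(z), n),
        present = rep_len(as.logical(present), n),
        stringsAsFactors = FALSE))
}

.chainSequence <- function(structure, chain) {
    a <- structure@atoms
    a <- a[a$chain == chain, , drop = FALSE]
    a <- a[order(a$resno), , drop = FALSE]
    one <- bio3d::aa321(a$resname)
    one[is.na(one) | one == "X"] <- "X"
    list(seq = paste(one, collapse = ""), resno = a$resno)
}

#' Assign structure chains to protein sequences
#'
#' Globally aligns each chain's residue sequence (from the 3-letter codes)
#' against every candidate protein sequence and assigns the chain to the
#' best-identity protein, provided identity (exact matches over the protein
#' length) reaches \code{minIdentity}. A protein may own several chains —
#' the homo-oligomer copies. The per-copy residue map sends protein
#' positions to author residue numbers through the alignment, excluding gap
#' columns, so renumbered or truncated chains are reconciled automatically.
#'
#' @param structure A \linkS4class{StructureModel}.
#' @param sequences Named character vector or \link[Biostrings]{AAStringSet}
#'   of protein sequences (names are accessions).
#' @param minIdentity Minimum alignment identity for an assignment
#'   (default 0.9, tolerating tags and point mutants while rejecting
#'   paralogs).
#' @return A \linkS4class{ChainAssignment}; chains no protein claimed are
#'   listed in \code{unassigned} (with a warning if all chains are).
#' @export
buildChainAssignment <- function(structure, sequences, minIdentity = 0.9) {
    if (is(sequences, "AAStringSet"))
        sequences <- setNames(as.character(sequences), names(sequences))
    if (length(sequences) == 0L)
        stop("sequences must be non-empty")
    chains <- chainIds(structure)
    assignments <- list()
    unassigned <- character()
    for (ch in chains) {
        cs <- .chainSequence(structure, ch)
        best <- NULL
        for (acc in names(sequences)) {
            pa <- Biostrings::pairwiseAlignment(
                Biostrings::AAString(cs$seq),
                Biostrings::AAString(sequences[[acc]]),
                type = "global", substitutionMatrix = "BLOSUM62",
                gapOpening = 10, gapExtension = 0.5)
            aln <- .alignmentMap(pa)
            ident <- aln$nExact / nchar(sequences[[acc]])
            if (is.null(best) || ident > best$identity)
                best <- list(acc = acc, identity = ident, aln = aln)
        }
        if (!is.null(best) && best$identity >= minIdentity) {
            map <- setNames(cs$resno[best$aln$patternPos],
                            best$aln$subjectPos)
            storage.mode(map) <- "integer"
            assignments[[best$acc]] <- c(assignments[[best$acc]],
                list(list(chain = ch, map = map, identity = best$identity)))
        } else {
            unassigned <- c(unassigned, ch)
        }
    }
    if (length(assignments) == 0L)
        warning("no chain reached minIdentity = ", minIdentity,
                "; assignment is empty")
    new("ChainAssignment", assignments = assignments,
        unassigned = unassigned)
}

## aligned-column bookkeeping: positions paired by the global alignment
.alignmentMap <- function(pa) {
    p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    pi <- cumsum(p != "-")
    si <- cumsum(s != "-")
    both <- p != "-" & s != "-"
    list(patternPos = pi[both], subjectPos = si[both],
         nExact = sum(both & p == s))
}

.caLookup <- function(structure, chain, resno) {
    a <- structure@atoms
    i <- which(a$chain == chain & a$resno == resno)
    if (length(i) == 0L || !a$present[i[1L]])
        return(NULL)
    c(a$x[i[1L]], a$y[i[1L]], a$z[i[1L]])
}

#' Calpha-Calpha Euclidean distance between two residues
#'
#' @param structure A \linkS4class{StructureModel}.
#' @param endpoint1,endpoint2 Each a vector \code{c(chain, resno)} (chain id
#'   and author residue number).
#' @return Distance in Angstrom; symmetric in its arguments.
#' @export
caDistance <- function(structure, endpoint1, endpoint2) {
    p <- .caLookup(structure, endpoint1[[1L]], as.integer(endpoint1[[2L]]))
    if (is.null(p))
        stop(sprintf("no Calpha for chain %s residue %s",
                     endpoint1[[1L]], endpoint1[[2L]]))
    q <- .caLookup(structure, endpoint2[[1L]], as.integer(endpoint2[[2L]]))
    if (is.null(q))
        stop(sprintf("no Calpha for chain %s residue %s",
                     endpoint2[[1L]], endpoint2[[2L]]))
    sqrt(sum((p - q)^2))
}

## enumerate admissible copy-pair placements of one record and take the
## minimum distance (most-permissive homo-oligomer reading)
.mapOneLink <- function(proteinA, residueA, proteinB, residueB,
                        structure, assignment) {
    copiesA <- assignment@assignments[[proteinA]]
    copiesB <- assignment@assignments[[proteinB]]
    if (is.null(copiesA) || is.null(copiesB))
        return(list(status = "protein_absent"))
    best <- NULL
    for (ca in copiesA) {
        ra <- ca$map[as.character(residueA)]
        if (is.na(ra)) next
        pa <- .caLookup(structure, ca$chain, ra)
        if (is.null(pa)) next
        for (cb in copiesB) {
            rb <- cb$map[as.character(residueB)]
            if (is.na(rb)) next
            if (ca$chain == cb$chain && ra == rb) next  # a residue with itself
            pb <- .caLookup(structure, cb$chain, rb)
            if (is.null(pb)) next
            d <- sqrt(sum((pa - pb)^2))
            if (is.null(best) || d < best$distance)
                best <- list(chainA = ca$chain, resA = unname(ra),
                             chainB = cb$chain, resB = unname(rb),
                             distance = d)
        }
    }
    if (is.null(best))
        return(list(status = "endpoint_missing"))
    c(list(status = "mapped"), best)
}

#' Map cross-links onto a structure
#'
#' Every record is placed on the structure by evaluating all admissible
#' (chain copy, chain copy) combinations of its two endpoints — including
#' cross-copy combinations for intra-protein links in homo-oligomers, and
#' excluding only a residue paired with itself — and taking the minimum
#' Calpha-Calpha distance. Failure modes are encoded in \code{status}:
#' \code{protein_absent} (an accession owns no chain) or
#' \code{endpoint_missing} (no combination has both Calpha present).
#'
#' @param table A \linkS4class{CrossLinkTable}.
#' @param structure A \linkS4class{StructureModel}.
#' @param assignment A \linkS4class{ChainAssignment} built for
#'   \code{structure}.
#' @param maxDistance Restraint used for the \code{satisfied} flag
#'   (default 35 Angstrom, the DSBSO convention).
#' @return A \link[S4Vectors]{DataFrame} with one row per record: the
#'   endpoint columns, \code{status}, chosen \code{chainA}/\code{structResA}/
#'   \code{chainB}/\code{structResB}, \code{distance} (Angstrom, NA unless
#'   mapped) and \code{satisfied} (\code{distance <= maxDistance}).
#' @export
mapCrossLinks <- function(table, structure, assignment, maxDistance = 35) {
    rec <- as.data.frame(table@records)
    n <- nrow(rec)
    out <- data.frame(status = character(n), chainA = NA_character_,
                      structResA = NA_integer_, chainB = NA_character_,
                      structResB = NA_integer_, distance = NA_real_,
                      satisfied = NA, stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
        m <- .mapOneLink(rec$proteinA[i], rec$residueA[i],
                         rec$proteinB[i], rec$residueB[i],
                         structure, assignment)
        out$status[i] <- m$status
        if (m$status == "mapped") {
            out$chainA[i] <- m$chainA; out$structResA[i] <- m$resA
            out$chainB[i] <- m$chainB; out$structResB[i] <- m$resB
            out$distance[i] <- m$distance
            out$satisfied[i] <- m$distance <= maxDistance
        }
    }
    S4Vectors::DataFrame(cbind(rec[, c("proteinA", "residueA",
                                       "proteinB", "residueB")], out))
}

#' Summarize restraint satisfaction of mapped cross-links
#'
#' Agreement is computed over the mapped links only; links that failed to
#' map (absent protein or missing Calpha) count toward \code{nInput} but are
#' excluded from the denominator. With nothing mapped the agreement is
#' undefined and reported as \code{NA}, never 0. The satisfaction boundary
#' is inclusive: a distance exactly at the restraint satisfies it.
#'
#' @param mapped The \code{DataFrame} returned by \code{\link{mapCrossLinks}}.
#' @param maxDistance Distance restraint in Angstrom (default 35).
#' @param complexId Label stored in the report.
#' @return A \linkS4class{DistanceReport}.
#' @export
satisfactionReport <- function(mapped, maxDistance = 35, complexId = "") {
    d <- mapped$distance[mapped$status == "mapped"]
    nM <- length(d)
    nS <- sum(d <= maxDistance)
    new("DistanceReport", complexId = complexId,
        nInput = nrow(mapped), nMapped = nM, nSatisfied = as.integer(nS),
        agreement = if (nM > 0L) nS / nM else NA_real_,
        distances = as.numeric(d), maxDistance = maxDistance)
}

#' Histogram of mapped cross-link distances
#'
#' Left-closed right-open bins of equal width starting at 0 Angstrom (a
#' value exactly on an edge falls in the bin to its right); counts sum to
#' the number of mapped links.
#'
#' @param mapped Output of \code{\link{mapCrossLinks}}, a
#'   \linkS4class{DistanceReport}, or a plain numeric vector of distances.
#' @param binWidth Bin width in Angstrom (default 5; must be > 0).
#' @return List with \code{breaks} (bin edges, length \code{nBins + 1}) and
#'   \code{counts}.
#' @export
distanceDistribution <- function(mapped, binWidth = 5) {
    stopifnot(binWidth > 0)
    d <- if (is.numeric(mapped)) mapped
         else if (is(mapped, "DistanceReport")) mapped@distances
         else mapped$distance[mapped$status == "mapped"]
    nBins <- if (length(d)) max(1L, floor(max(d) / binWidth) + 1L) else 1L
    breaks <- seq(0, nBins * binWidth, by = binWidth)
    counts <- tabulate(floor(d / binWidth) + 1L, nbins = nBins)
    list(breaks = breaks, counts = counts)
}
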