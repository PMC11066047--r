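#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Cross-link identification table
#'
#' Container for residue-pair (lysine-lysine) cross-link identifications.
#' Each record is a canonicalized endpoint pair: endpoints are stored in
#' deterministic lexicographic order by (accession, residue), so the same
#' physical link always has the same representation regardless of the
#' orientation it was reported in.
#'
#' @slot records A \link[S4Vectors]{DataFrame} with columns \code{proteinA},
#'   \code{residueA}, \code{proteinB}, \code{residueB}, \code{score},
#'   \code{fdr}, \code{csmCount}.
#' @slot source Character scalar naming the data source.
#' @slot fdrThreshold Numeric scalar; the FDR threshold applied by
#'   \code{\link{filterFDR}}, or \code{NA} if none.
#' @slot deduplicated Logical; \code{TRUE} after
#'   \code{\link{deduplicateUniquePairs}}.
#'
#' @seealso \code{\link{CrossLinkTable}} (constructor),
#'   \code{\link{parseCrossLinkTable}}
#' @exportClass CrossLinkTable
setClass("CrossLinkTable",
    representation(
        records = "DataFrame",
        source = "character",
        fdrThreshold = "numeric",
        deduplicated = "logical"
    ),
    prototype(
        source = NA_character_,
        fdrThreshold = NA_real_,
        deduplicated = FALSE
    )
)

setValidity("CrossLinkTable", function(object) {
    rec <- object@records
    need <- c("proteinA", "residueA", "proteinB", "residueB",
              "score", "fdr", "csmCount")
    if (!all(need %in% colnames(rec)))
        return(paste("records must have columns:", paste(need, collapse = ", ")))
    if (nrow(rec) == 0L)
        return(TRUE)
    if (any(rec$residueA < 1L) || any(rec$residueB < 1L))
        return("residue positions must be >= 1")
    bad <- !is.na(rec$fdr) & (rec$fdr < 0 | rec$fdr > 1)
    if (any(bad))
        return("fdr values must lie in [0, 1]")
    swapped <- rec$proteinB < rec$proteinA |
        (rec$proteinB == rec$proteinA & rec$residueB < rec$residueA)
    if (any(swapped))
        return("records are not in canonical endpoint order")
    if (isTRUE(object@deduplicated)) {
        key <- paste(rec$proteinA, rec$residueA, rec$proteinB, rec$residueB)
        if (anyDuplicated(key))
            return("deduplicated table contains duplicate endpoint pairs")
    }
    TRUE
})

#' Calpha coordinate model of a (multi-chain) structure
#'
#' Holds one Calpha record per residue of every polypeptide chain of a
#' structure. Residues present in the polymer but lacking a Calpha atom are
#' retained with \code{present = FALSE} and missing coordinates, so that
#' mapping can distinguish "residue absent" from "residue outside the chain".
#'
#' @slot id Character scalar model identifier.
#' @slot atoms \code{data.frame} with columns \code{chain}, \code{resno}
#'   (author residue number), \code{resname} (3-letter code), \code{x},
#'   \code{y}, \code{z} (Angstrom), \code{present} (logical).
#'
#' @seealso \code{\link{loadStructure}}, \code{\link{caDistance}}
#' @exportClass StructureModel
setClass("StructureModel",
    representation(id = "character", atoms = "data.frame"))

setValidity("StructureModel", function(object) {
    a <- object@atoms
    need <- c("chain", "resno", "resname", "x", "y", "z", "present")
    if (!all(need %in% colnames(a)))
        return(paste("atoms must have columns:", paste(need, collapse = ", ")))
    if (nrow(a) == 0L)
        return("structure must contain at least one residue")
    ok <- a$present
    if (any(!is.finite(a$x[ok]) | !is.finite(a$y[ok]) | !is.finite(a$z[ok])))
        return("present residues must have finite coordinates")
    key <- paste(a$chain, a$resno)
    if (anyDuplicated(key))
        return("residue numbers must be unique within a chain")
    TRUE
})

#' Protein-to-chain assignment with residue renumbering maps
#'
#' The result of aligning protein sequences against structure chains. A
#' protein may own several chains (homo-oligomer copies); each copy carries
#' an injective residue map from protein (UniProt-style, 1-based) numbering
#' to the author residue numbering of the coordinate file.
#'
#' @slot assignments Named list, one element per assigned accession. Each
#'   element is a list of copies; each copy is a list with \code{chain}
#'   (chain id), \code{map} (named integer vector: names are protein residue
#'   positions, values structure residue numbers) and \code{identity}
#'   (alignment identity fraction).
#' @slot unassigned Character vector of chain ids no protein claimed.
#'
#' @seealso \code{\link{buildChainAssignment}}
#' @exportClass ChainAssignment
setClass("ChainAssignment",
    representation(assignments = "list", unassigned = "character"))

setValidity("ChainAssignment", function(object) {
    for (acc in names(object@assignments)) {
        for (cp in object@assignments[[acc]]) {
            if (anyDuplicated(cp$map))
                return(sprintf("residue map for %s/%s is not injective",
                               acc, cp$chain))
        }
    }
    TRUE
})

#' Restraint-satisfaction report for a set of mapped cross-links
#'
#' @slot complexId Character scalar.
#' @slot nInput,nMapped,nSatisfied Integer counts; always
#'   \code{nSatisfied <= nMapped <= nInput}.
#' @slot agreement \code{nSatisfied / nMapped}, or \code{NA} when nothing
#'   mapped (undefined, never reported as 0).
#' @slot distances Numeric vector of mapped Calpha-Calpha distances (Angstrom).
#' @slot maxDistance The distance restraint used (35 Angstrom for DSBSO).
#'
#' @seealso \code{\link{satisfactionReport}}
#' @exportClass DistanceReport
setClass("DistanceReport",
    representation(
        complexId = "character",
        nInput = "integer",
        nMapped = "integer",
        nSatisfied = "integer",
        agreement = "numeric",
        distances = "numeric",
        maxDistance = "numeric"
    )
)

setValidity("DistanceReport", function(object) {
    if (object@nSatisfied > object@nMapped || object@nMapped > object@nInput)
        return("require nSatisfied <= nMapped <= nInput")
    if (object@nMapped > 0L &&
        !isTRUE(all.equal(object@agreement,
                          object@nSatisfied / object@nMapped)))
        return("agreement must equal nSatisfied/nMapped when nMapped > 0")
    if (object@nMapped == 0L && !is.na(object@agreement))
        return("agreement must be NA when nMapped == 0")
    TRUE
})

#' Protein-protein interaction network from inter-protein cross-links
#'
#' @slot nodes Character vector of accessions with at least one surviving
#'   edge (isolated nodes are omitted unless requested).
#' @slot edges \code{data.frame} with columns \code{proteinA},
#'   \code{proteinB}, \code{nUniqueLinks} (edge weight: unique residue
#'   pairs), \code{csmTotal}.
#' @slot residuePairs \code{data.frame} with one row per unique residue pair
#'   (\code{proteinA}, \code{residueA}, \code{proteinB}, \code{residueB},
#'   \code{edgeId}).
#'
#' @seealso \code{\link{buildNetwork}}, \code{\link{exportGraph}}
#' @exportClass InteractionNetwork
setClass("InteractionNetwork",
    representation(nodes = "character", edges = "data.frame",
                   residuePairs = "data.frame"))

setValidity("InteractionNetwork", function(object) {
    e <- object@edges
    if (nrow(e) > 0L) {
        if (any(e$proteinA == e$proteinB))
            return("self-loop edges are not allowed")
        if (!all(c(e$proteinA, e$proteinB) %in% object@nodes))
            return("every edge endpoint must be a node")
        if (nrow(object@residuePairs) > 0L) {
            tab <- table(object@residuePairs$edgeId)
            if (!all(e$nUniqueLinks ==
                     as.integer(tab[as.character(seq_len(nrow(e)))])))
                return("nUniqueLinks must equal the residue-pair list length per edge")
        }
    }
    TRUE
})

## ---- accessors ----

#' @describeIn CrossLinkTable-class number of records
#' @param x,object a \code{CrossLinkTable}
#' @export
nLinks <- function(x) nrow(x@records)

#' Extract the record table of a CrossLinkTable
#' @param x a \code{CrossLinkTable}
#' @return A \link[S4Vectors]{DataFrame} of canonical records.
#' @export
linkRecords <- function(x) x@records

#' Has a table been collapsed to unique residue pairs?
#' @param x a \code{CrossLinkTable}
#' @export
isDeduplicated <- function(x) isTRUE(x@deduplicated)

#' Chain identifiers of a StructureModel
#' @param x a \code{StructureModel}
#' @export
chainIds <- function(x) unique(x@atoms$chain)

#' Residue table of a StructureModel
#' @param x a \code{StructureModel}
#' @return \code{data.frame} of per-residue Calpha records.
#' @export
structureAtoms <- function(x) x@atoms

#' Agreement fraction of a DistanceReport
#' @param x a \code{DistanceReport}
#' @export
agreement <- function(x) x@agreement

#' Mapped distances of a DistanceReport
#' @param x a \code{DistanceReport}
#' @export
mappedDistances <- function(x) x@distances

#' Edge table of an InteractionNetwork
#' @param x an \code{InteractionNetwork}
#' @export
networkEdges <- function(x) x@edges

#' Node set of an InteractionNetwork
#' @param x an \code{InteractionNetwork}
#' @export
networkNodes <- function(x) x@nodes

## ---- show methods ----

setMethod("show", "CrossLinkTable", function(object) {
    cat(sprintf("CrossLinkTable with %d record(s)\n", nLinks(object)))
    cat(sprintf("  source: %s | fdrThreshold: %s | deduplicated: %s\n",
        object@source,
        ifelse(is.na(object@fdrThreshold), "none",
               format(object@fdrThreshold)),
        object@deduplicated))
    if (nLinks(object) > 0L) {
        show(utils::head(as.data.frame(object@records), 5L))
        if (nLinks(object) > 5L) cat("  ...\n")
    }
})

setMethod("show", "StructureModel", function(object) {
    a <- object@atoms
    cat(sprintf("StructureModel '%s': %d chain(s), %d residue(s), %d with Calpha\n",
        object@id, length(unique(a$chain)), nrow(a), sum(a$present)))
})

setMethod("show", "ChainAssignment", function(object) {
    cat(sprintf("ChainAssignment: %d protein(s) assigned\n",
                length(object@assignments)))
    for (acc in names(object@assignments)) {
        cps <- object@assignments[[acc]]
        cat(sprintf("  %s -> %s\n", acc,
            paste(vapply(cps, function(cp)
                sprintf("%s (id %.2f)", cp$chain, cp$identity), ""),
                collapse = ", ")))
    }
    if (length(object@unassigned))
        cat("  unassigned chains:", paste(object@unassigned, collapse = ", "), "\n")
})

setMethod("show", "DistanceReport", function(object) {
    cat(sprintf("DistanceReport '%s' (restraint %.1f A)\n",
                object@complexId, object@maxDistance))
    cat(sprintf("  input %d | mapped %d | satisfied %d | agreement %s\n",
        object@nInput, object@nMapped, object@nSatisfied,
        ifelse(is.na(object@agreement), "undefined",
               sprintf("%.3f", object@agreement))))
})

setMethod("show", "InteractionNetwork", function(object) {
    cat(sprintf("InteractionNetwork: %d node(s), %d edge(s), %d residue pair(s)\n",
        length(object@nodes), nrow(object@edges), nrow(object@residuePairs)))
})
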