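## Protein-protein interaction network from inter-protein cross-links.

#' Build a PPI network from inter-protein cross-links
#'
#' Edges come from inter-protein links only (self-pairs never create
#' edges); the edge weight is the number of unique residue pairs supporting
#' the protein pair, with summed CSM counts kept as an attribute. Edges
#' supported by fewer than \code{minLinks} unique links are dropped, and by
#' default the node set is restricted to proteins with surviving edges.
#'
#' @param table A deduplicated \linkS4class{CrossLinkTable}.
#' @param minLinks Minimum unique residue pairs per edge (default 1).
#' @param keepIsolated Keep proteins whose edges were all dropped
#'   (default \code{FALSE}).
#' @return An \linkS4class{InteractionNetwork}.
#' @export
buildNetwork <- function(table, minLinks = 1L, keepIsolated = FALSE) {
    if (!isDeduplicated(table))
        stop("buildNetwork expects a deduplicated table")
    rec <- as.data.frame(table@records)
    inter <- rec[rec$proteinA != rec$proteinB, , drop = FALSE]
    if (nrow(inter) == 0L)
        return(new("InteractionNetwork", nodes = character(),
                   edges = data.frame(proteinA = character(),
                                      proteinB = character(),
                                      nUniqueLinks = integer(),
                                      csmTotal = integer()),
                   residuePairs = data.frame(proteinA = character(),
                                             residueA = integer(),
                                             proteinB = character(),
                                             residueB = integer(),
                                             edgeId = integer())))
    key <- paste(inter$proteinA, inter$proteinB, sep = "\r")
    inter <- inter[order(key), , drop = FALSE]
    key <- sort(key)
    grp <- match(key, unique(key))
    first <- !duplicated(grp)
    edges <- data.frame(proteinA = inter$proteinA[first],
                        proteinB = inter$proteinB[first],
                        nUniqueLinks = as.integer(table(grp)),
                        csmTotal = as.integer(vapply(
                            split(inter$csmCount, grp), sum, 0)),
                        stringsAsFactors = FALSE)
    keep <- edges$nUniqueLinks >= minLinks
    edgeId <- ifelse(keep[grp], cumsum(keep)[grp], NA_integer_)
    rp <- data.frame(proteinA = inter$proteinA, residueA = inter$residueA,
                     proteinB = inter$proteinB, residueB = inter$residueB,
                     edgeId = edgeId, stringsAsFactors = FALSE)
    rp <- rp[!is.na(rp$edgeId), , drop = FALSE]
    rownames(rp) <- NULL
    edges <- edges[keep, , drop = FALSE]
    rownames(edges) <- NULL
    nodes <- sort(unique(c(edges$proteinA, edges$proteinB)))
    if (keepIsolated)
        nodes <- sort(unique(c(nodes, rec$proteinA, rec$proteinB)))
    new("InteractionNetwork", nodes = nodes, edges = edges,
        residuePairs = rp)
}

#' Residue-to-residue edge table of a network
#'
#' One row per unique residue pair supporting an edge, for
#' residue-resolution network visualisation; row count equals the sum of
#' edge weights.
#'
#' @param network An \linkS4class{InteractionNetwork}.
#' @return \code{data.frame} with \code{proteinA}, \code{residueA},
#'   \code{proteinB}, \code{residueB}, \code{edgeId}.
#' @export
residueEdgeTable <- function(network) network@residuePairs

#' Export a PPI network to GraphML, SIF or edge-list TSV
#'
#' GraphML and TSV exports are loss-free for nodes, edges and weights and
#' can be re-imported with \code{\link{importGraph}}; SIF uses the
#' interaction type \code{"xl"}.
#'
#' @param network An \linkS4class{InteractionNetwork}.
#' @param path Output file path.
#' @param format One of \code{"graphml"}, \code{"sif"}, \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
exportGraph <- function(network, path, format = c("graphml", "sif", "tsv")) {
    format <- match.arg(format)
    e <- network@edges
    if (format == "sif") {
        lines <- if (nrow(e)) paste(e$proteinA, "xl", e$proteinB)
                 else character()
        writeLines(lines, path)
    } else if (format == "tsv") {
        utils::write.table(e, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    } else {
        g <- igraph::graph_from_data_frame(
            e[, c("proteinA", "proteinB")], directed = FALSE,
            vertices = data.frame(name = network@nodes))
        igraph::E(g)$weight <- e$nUniqueLinks
        igraph::E(g)$csmTotal <- e$csmTotal
        igraph::write_graph(g, path, format = "graphml")
    }
    invisible(path)
}

#' Import a network written by exportGraph (graphml or tsv)
#'
#' Residue-pair detail is not stored in graph files; the returned network
#' carries nodes, edges and weights only.
#'
#' @param path File produced by \code{\link{exportGraph}}.
#' @param format \code{"graphml"} or \code{"tsv"}.
#' @return An \linkS4class{InteractionNetwork} (empty residue-pair table).
#' @export
importGraph <- function(path, format = c("graphml", "tsv")) {
    format <- match.arg(format)
    if (format == "tsv") {
        e <- utils::read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
        nodes <- sort(unique(c(e$proteinA, e$proteinB)))
    } else {
        g <- igraph::read_graph(path, format = "graphml")
        nodes <- sort(igraph::V(g)$name)
        el <- igraph::as_data_frame(g, what = "edges")
        e <- data.frame(proteinA = pmin(el$from, el$to),
                        proteinB = pmax(el$from, el$to),
                        nUniqueLinks = as.integer(el$weight),
                        csmTotal = as.integer(el$csmTotal),
                        stringsAsFactors = FALSE)
    }
    if (nrow(e)) {
        e <- e[order(e$proteinA, e$proteinB), , drop = FALSE]
        rownames(e) <- NULL
    }
    rp <- data.frame(proteinA = character(), residueA = integer(),
                     proteinB = character(), residueB = integer(),
                     edgeId = integer())
    net <- new("InteractionNetwork", nodes = nodes, edges = e,
               residuePairs = rp)
    net
}
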