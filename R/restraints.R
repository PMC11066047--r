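## Docking restraint export and cross-link-based model ranking.

#' Export cross-links as unambiguous docking restraints
#'
#' Writes one restraint line per resolvable link in the
#' ambiguous-interaction-restraint text dialect:
#'
#' \preformatted{assign (segid A and resid 12 and name CA)
#'   (segid B and resid 80 and name CA) 35.0 35.0 0.0}
#'
#' (single line; target, lower margin, upper margin). The defaults encode
#' "anything up to 35 Angstrom satisfies": target 35, lower margin 35
#' (effective lower bound 0), upper margin 0. Docking restraints must be
#' unambiguous, so a link whose endpoints map to several homo-oligomer
#' copies is pinned to the first copy in canonical chain order; links with
#' an unresolvable endpoint are skipped with a warning. Line order follows
#' canonical link order.
#'
#' @param links A \linkS4class{CrossLinkTable}.
#' @param assignment A \linkS4class{ChainAssignment}.
#' @param path Optional output file; when \code{NULL} the lines are only
#'   returned.
#' @param target,lower,upper Restraint distance and margins in Angstrom.
#' @return Character vector of restraint lines, invisibly when written to
#'   \code{path}. Attribute \code{"nSkipped"} counts unresolvable links.
#' @export
exportRestraints <- function(links, assignment, path = NULL,
                             target = 35, lower = 35, upper = 0) {
    stopifnot(target > 0, lower >= 0, upper >= 0)
    rec <- as.data.frame(links@records)
    rec <- rec[order(rec$proteinA, rec$residueA, rec$proteinB, rec$residueB), ,
               drop = FALSE]
    resolve <- function(acc, res) {
        copies <- assignment@assignments[[acc]]
        if (is.null(copies)) return(NULL)
        for (cp in copies[order(vapply(copies, `[[`, "", "chain"))]) {
            r <- cp$map[as.character(res)]
            if (!is.na(r)) return(list(chain = cp$chain, resno = unname(r)))
        }
        NULL
    }
    lines <- character(); skipped <- 0L
    for (i in seq_len(nrow(rec))) {
        a <- resolve(rec$proteinA[i], rec$residueA[i])
        b <- resolve(rec$proteinB[i], rec$residueB[i])
        if (is.null(a) || is.null(b)) { skipped <- skipped + 1L; next }
        lines <- c(lines, sprintf(
            "assign (segid %s and resid %d and name CA) (segid %s and resid %d and name CA) %.1f %.1f %.1f",
            a$chain, a$resno, b$chain, b$resno, target, lower, upper))
    }
    if (skipped > 0L)
        warning(skipped, " link(s) had unresolvable endpoints and were skipped")
    if (length(lines) == 0L)
        stop("no link could be resolved to a restraint")
    attr(lines, "nSkipped") <- skipped
    if (!is.null(path)) {
        writeLines(lines, path)
        return(invisible(lines))
    }
    lines
}

#' Parse a restraint file written by exportRestraints
#'
#' @param path Restraint text file (or character vector of lines).
#' @return \code{data.frame} with \code{chainA}, \code{resA}, \code{chainB},
#'   \code{resB}, \code{target}, \code{lower}, \code{upper}.
#' @export
parseRestraints <- function(path) {
    lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
             else path
    pat <- paste0("^assign \\(segid (\\S+) and resid (\\d+) and name CA\\) ",
                  "\\(segid (\\S+) and resid (\\d+) and name CA\\) ",
                  "([0-9.]+) ([0-9.]+) ([0-9.]+)$")
    m <- regmatches(lines, regexec(pat, lines))
    bad <- which(lengths(m) != 8L)
    if (length(bad))
        stop("unparseable restraint line(s): ",
             paste(utils::head(bad, 5L), collapse = ", "))
    g <- function(k) vapply(m, `[[`, "", k)
    data.frame(chainA = g(2L), resA = as.integer(g(3L)),
               chainB = g(4L), resB = as.integer(g(5L)),
               target = as.numeric(g(6L)), lower = as.numeric(g(7L)),
               upper = as.numeric(g(8L)), stringsAsFactors = FALSE)
}

#' Score a candidate model by cross-link agreement
#'
#' Maps every link onto the model (minimum over homo-oligomer copy pairs)
#' and measures violations beyond the restraint:
#' \code{sumViolation = sum(max(0, d - maxDistance))}.
#'
#' @param structure Candidate \linkS4class{StructureModel} (a docked pose).
#' @param links A \linkS4class{CrossLinkTable}.
#' @param assignment A \linkS4class{ChainAssignment} valid for the model.
#' @param maxDistance Restraint in Angstrom (default 35).
#' @param modelId Identifier stored in the score; defaults to the
#'   structure's id.
#' @return One-row \code{data.frame}: \code{modelId}, \code{nEvaluated}
#'   (links that mapped), \code{nSatisfied}, \code{sumViolation},
#'   \code{maxViolation} (both Angstrom).
#' @export
scoreModel <- function(structure, links, assignment, maxDistance = 35,
                       modelId = structure@id) {
    mapped <- mapCrossLinks(links, structure, assignment, maxDistance)
    d <- mapped$distance[mapped$status == "mapped"]
    viol <- pmax(0, d - maxDistance)
    data.frame(modelId = modelId, nEvaluated = length(d),
               nSatisfied = sum(d <= maxDistance),
               sumViolation = sum(viol),
               maxViolation = if (length(viol)) max(viol) else 0,
               stringsAsFactors = FALSE)
}

#' Rank candidate models by cross-link agreement
#'
#' Deterministic total order: satisfied count descending, then total
#' violation ascending, then model id ascending. A model with all links
#' satisfied and zero violation always ranks first.
#'
#' @param scores \code{data.frame} of rows from \code{\link{scoreModel}}
#'   (or a list of such rows).
#' @return The score table sorted into rank order, with a \code{rank}
#'   column prepended.
#' @export
rankModels <- function(scores) {
    if (is.list(scores) && !is.data.frame(scores))
        scores <- do.call(rbind, scores)
    if (is.null(scores) || nrow(scores) == 0L)
        stop("no model scores to rank")
    ord <- order(-scores$nSatisfied, scores$sumViolation, scores$modelId)
    out <- scores[ord, , drop = FALSE]
    rownames(out) <- NULL
    cbind(rank = seq_len(nrow(out)), out)
}
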