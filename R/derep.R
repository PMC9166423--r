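## Genome dereplication: single-linkage clustering of the pairwise ANI graph
## at a strict >99% threshold, then one representative per cluster chosen by
## a dRep-style score combining completeness, contamination, strain
## heterogeneity, N50 and within-cluster centrality.

#' Cluster genomes by pairwise ANI
#'
#' Single-linkage connected components of the graph whose edges join genome
#' pairs with ANI strictly above the threshold. Missing pairs (NA) count as
#' below threshold. The result is a partition: every genome appears in
#' exactly one cluster.
#'
#' @param ani symmetric numeric matrix of percent identities with genome
#'   names; asymmetry beyond 0.01 is an error.
#' @param threshold percent ANI; edges require ANI strictly greater.
#' @return list of clusters, each a sorted character vector of genome ids;
#'   clusters ordered by their first member.
#' @examples
#' m <- matrix(c(100, 99.5, 98, 99.5, 100, 98.2, 98, 98.2, 100), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' clusterByAni(m, 99)   # {A,B}, {C}
#' @export
clusterByAni <- function(ani, threshold = 99) {
    if (!is.matrix(ani) || nrow(ani) != ncol(ani))
        stop("ANI input must be a square matrix")
    if (is.null(rownames(ani)) || is.null(colnames(ani)) ||
        !identical(rownames(ani), colnames(ani)))
        stop("ANI matrix must carry identical row and column genome names")
    asym <- abs(ani - t(ani))
    if (any(asym[!is.na(asym)] > 0.01))
        stop("ANI matrix asymmetric beyond tolerance 0.01 (max deviation ",
             format(max(asym, na.rm = TRUE)), ")")
    adj <- !is.na(ani) & ani > threshold
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj | t(adj),
                                             mode = "undirected")
    comp <- igraph::components(g)$membership
    cl <- split(names(comp), comp)
    cl <- lapply(cl, function(x) sort(x))
    cl[order(vapply(cl, `[`, character(1), 1L))]
}

#' Score one genome for representative selection
#'
#' \deqn{score = w_1 comp - w_2 cont + w_3 (cont \cdot SH/100)
#'       + w_4 \log_{10} N50 + w_5 \log_{10} size + w_6 centrality}
#' with default weights (1, 5, 1, 0.5, 0, 1). Centrality is the genome's
#' mean ANI to the other members of its cluster (percent).
#'
#' @param completeness,contamination,strainHeterogeneity percents.
#' @param n50 assembly N50 in bases (> 0).
#' @param size assembly length in bases.
#' @param centrality mean ANI to the other cluster members, percent.
#' @param weights numeric vector of the six weights, in the order
#'   completeness, contamination, heterogeneity product, log10 N50,
#'   log10 size, centrality.
#' @return numeric score.
#' @examples
#' scoreGenome(90, 0, 0, 1e5, 1e6, 99.5)  # 192
#' @export
scoreGenome <- function(completeness, contamination = 0,
                        strainHeterogeneity = 0, n50 = 1, size = 1,
                        centrality = 0,
                        weights = c(1, 5, 1, 0.5, 0, 1)) {
    if (any(n50 <= 0)) stop("n50 must be > 0")
    weights[1] * completeness - weights[2] * contamination +
        weights[3] * (contamination * strainHeterogeneity / 100) +
        weights[4] * log10(n50) + weights[5] * log10(size) +
        weights[6] * centrality
}

#' Choose a scored representative per cluster
#'
#' The representative is the member with the maximal score; exact ties go to
#' the lexicographically smallest genome id. Singleton clusters represent
#' themselves (their centrality is 0).
#'
#' @param clusters list of character vectors, as from
#'   \code{\link{clusterByAni}}.
#' @param stats data.frame with columns \code{genome_id},
#'   \code{completeness}, \code{contamination}, \code{strain_heterogeneity},
#'   \code{n50}, \code{size}; every cluster member must be present.
#' @param ani optional ANI matrix used to compute within-cluster centrality;
#'   when NULL centrality is 0 for all genomes.
#' @param weights passed to \code{\link{scoreGenome}}.
#' @return data.frame with columns \code{genome_id}, \code{cluster},
#'   \code{representative}, \code{score}, \code{centrality}.
#' @export
chooseRepresentatives <- function(clusters, stats, ani = NULL,
                                  weights = c(1, 5, 1, 0.5, 0, 1)) {
    members <- unlist(clusters, use.names = FALSE)
    missing <- setdiff(members, stats$genome_id)
    if (length(missing))
        stop("no stats for genome(s): ", paste(missing, collapse = ", "))
    rows <- lapply(seq_along(clusters), function(k) {
        ids <- clusters[[k]]
        st <- stats[match(ids, stats$genome_id), , drop = FALSE]
        centr <- if (length(ids) > 1L && !is.null(ani)) {
            vapply(ids, function(i)
                mean(ani[i, setdiff(ids, i)], na.rm = TRUE), numeric(1))
        } else stats::setNames(rep(0, length(ids)), ids)
        sc <- scoreGenome(st$completeness, st$contamination,
                          st$strain_heterogeneity, st$n50, st$size,
                          centr, weights)
        best <- ids[order(-sc, ids)][1]
        data.frame(genome_id = ids, cluster = k, representative = best,
                   score = sc, centrality = unname(centr),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Dereplicate a genome set
#'
#' Convenience wrapper: cluster at the configured ANI threshold, then pick
#' representatives.
#'
#' @param ani ANI matrix (see \code{\link{clusterByAni}}).
#' @param stats genome statistics (see \code{\link{chooseRepresentatives}}).
#' @param config a \linkS4class{PipelineConfig}.
#' @return list with \code{clusters}, \code{assignment} (the
#'   \code{\link{chooseRepresentatives}} data.frame) and
#'   \code{representatives} (sorted unique ids).
#' @export
dereplicate <- function(ani, stats, config = pipelineConfig()) {
    cl <- clusterByAni(ani, config@aniThreshold)
    assign <- chooseRepresentatives(cl, stats, ani)
    list(clusters = cl, assignment = assign,
         representatives = sort(unique(assign$representative)))
}
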