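## Clonotype similarity networks (Hamming-distance-1 edges), cluster
## metrics and cross-subject sharing (publicity).

## Hamming-1 neighbour finding: within each junction-length group, masking
## one position at a time buckets exactly the string pairs that differ only
## there. O(n * L) keys instead of O(n^2) comparisons; junctions are unique
## within a locus, so a bucketed pair always has distance exactly 1.
.hamming1Edges <- function(junctions) {
  edges <- list()
  by_len <- split(junctions, nchar(junctions))
  for (grp in by_len) {
    if (length(grp) < 2L) next
    L <- nchar(grp[1L])
    for (p in seq_len(L)) {
      masked <- paste0(substr(grp, 1L, p - 1L), "\r", substr(grp, p + 1L, L))
      buckets <- split(grp, masked)
      for (b in buckets) {
        if (length(b) < 2L) next
        b <- sort(b)
        cmb <- utils::combn(b, 2L)
        edges[[length(edges) + 1L]] <- data.frame(
          from = cmb[1L, ], to = cmb[2L, ], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(edges) == 0L) {
    return(data.frame(from = character(), to = character()))
  }
  out <- unique(do.call(rbind, edges))
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the per-locus clonotype similarity network
#'
#' Nodes are the locus's clonotypes; an edge joins two clonotypes of
#' identical junction length that differ at exactly one amino-acid position.
#' Edges are junction-only (V/J-agnostic) and may join clonotypes from
#' different subjects and subsets. Connected components with at least two
#' nodes become clusters with deterministic ids: components are ranked by
#' size (descending), ties by their lexicographically smallest junction.
#'
#' @param clonotypes output of [defineClonotypes()].
#' @param locus one of TRA/TRB/TRG/TRD.
#' @return A [ClonotypeGraph-class].
#' @export
buildNetwork <- function(clonotypes, locus) {
  stopifnot(is.data.frame(clonotypes), locus %in% TR_LOCI)
  cl <- clonotypes[clonotypes$locus == locus, , drop = FALSE]
  junctions <- sort(unique(cl$junction_aa))
  edges <- .hamming1Edges(junctions)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = junctions))
  comp <- igraph::components(g)
  member <- comp$membership[junctions]
  sizes <- comp$csize[member]
  cluster_id <- rep(NA_integer_, length(junctions))
  multi <- unique(member[sizes >= 2L])
  if (length(multi) > 0L) {
    rep_junction <- vapply(multi, function(m)
      min(junctions[member == m]), character(1L))
    ord <- order(-comp$csize[multi], rep_junction)
    ranks <- setNames(seq_along(multi), multi[ord])
    cluster_id <- unname(ranks[as.character(member)])
  }
  deg <- igraph::degree(g)[junctions]
  idx <- match(junctions, cl$junction_aa)
  nodes <- data.frame(
    junction_aa = junctions,
    junction_length = nchar(junctions),
    cell_count = cl$cell_count[idx],
    n_subjects = cl$n_subjects[idx],
    degree = as.integer(unname(deg)),
    cluster_id = cluster_id,
    stringsAsFactors = FALSE
  )
  rownames(nodes) <- NULL
  new("ClonotypeGraph", locus = locus, graph = g, nodes = nodes)
}

#' @describeIn buildNetwork The node table (junction, counts, degree,
#'   cluster id; \code{NA} cluster id marks singletons).
#' @param g A [ClonotypeGraph-class].
#' @export
networkNodes <- function(g) {
  stopifnot(is(g, "ClonotypeGraph"))
  g@nodes
}

#' @describeIn buildNetwork The edge list as a two-column data.frame.
#' @export
networkEdges <- function(g) {
  stopifnot(is(g, "ClonotypeGraph"))
  el <- igraph::as_edgelist(g@graph)
  data.frame(from = el[, 1L], to = el[, 2L], stringsAsFactors = FALSE)
}

#' Per-cluster size, mean centrality and density
#'
#' Mean centrality is the mean raw node degree within the cluster; density
#' is \eqn{2E / (n(n-1))}. Raw degree is used rather than degree centrality
#' normalised by \eqn{n-1}, which would be algebraically identical to
#' density and make the two metrics redundant.
#'
#' @param g A [ClonotypeGraph-class].
#' @return data.frame (cluster_id, size, n_edges, mean_centrality, density,
#'   n_subjects, representative junction), one row per cluster of size >= 2.
#' @export
clusterMetrics <- function(g) {
  stopifnot(is(g, "ClonotypeGraph"))
  nodes <- g@nodes
  nodes <- nodes[!is.na(nodes$cluster_id), , drop = FALSE]
  if (nrow(nodes) == 0L) {
    return(data.frame(cluster_id = integer(), size = integer(),
                      n_edges = integer(), mean_centrality = numeric(),
                      density = numeric(), representative = character()))
  }
  idx <- split(seq_len(nrow(nodes)), nodes$cluster_id)
  out <- data.frame(
    cluster_id = as.integer(names(idx)),
    size = lengths(idx),
    n_edges = vapply(idx, function(i)
      as.integer(sum(nodes$degree[i])) %/% 2L, integer(1L)),
    mean_centrality = vapply(idx, function(i) mean(nodes$degree[i]), numeric(1L)),
    representative = vapply(idx, function(i) min(nodes$junction_aa[i]),
                            character(1L)),
    stringsAsFactors = FALSE
  )
  out$density <- 2 * out$n_edges / (out$size * (out$size - 1L))
  out <- out[order(out$cluster_id),
             c("cluster_id", "size", "n_edges", "mean_centrality",
               "density", "representative")]
  rownames(out) <- NULL
  out
}

#' Clonotypes shared across subjects (public clonotypes)
#'
#' @param clonotypes output of [defineClonotypes()].
#' @param min_subjects minimum number of subjects sharing, at least 2.
#' @return data.frame (locus, junction_aa, n_subjects, subjects, cell_count)
#'   sorted by locus, sharing count (descending), junction.
#' @export
sharedClonotypes <- function(clonotypes, min_subjects = 2L) {
  stopifnot(is.data.frame(clonotypes), min_subjects >= 2L)
  out <- clonotypes[clonotypes$n_subjects >= min_subjects,
                    c("locus", "junction_aa", "n_subjects", "subjects",
                      "cell_count"), drop = FALSE]
  out <- out[order(out$locus, -out$n_subjects, out$junction_aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}
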