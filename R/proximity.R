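#' Count simple causal paths from a node into a target set
#'
#' Exact count of distinct simple directed paths of length 1 to `maxLen`
#' from `node` to any member of `targetSet`. A path terminates at the first
#' target member it reaches, so paths passing through one target on the way
#' to another are not double-counted.
#'
#' @param net a [CausalNetwork-class]. Edge signs are ignored here: the
#'   screen asks for connectivity in either direction of regulation.
#' @param node source node id.
#' @param targetSet character vector of target node ids.
#' @param maxLen maximal path length (edges), >= 1.
#' @return integer path count.
#' @examples
#' net <- CausalNetwork(
#'   nodes = data.frame(id = c("A", "B", "C")),
#'   edges = data.frame(source = c("A", "B", "A"),
#'                      target = c("B", "C", "C"), sign = 1L))
#' countCausalPaths(net, "A", "C", maxLen = 3)  # A>C and A>B>C
#' @export
countCausalPaths <- function(net, node, targetSet, maxLen = 4L) {
  nd <- networkNodes(net)
  if (!node %in% nd$id) stop("node not in network: ", node)
  missing <- setdiff(targetSet, nd$id)
  if (length(missing))
    stop("target(s) not in network: ", paste(missing, collapse = ", "))
  stopifnot(maxLen >= 1)
  adj <- split(networkEdges(net)$target, networkEdges(net)$source)
  tset <- unique(targetSet)
  count <- 0L
  visit <- function(v, depth, onPath) {
    for (w in unique(adj[[v]])) {
      if (w %in% tset) {
        count <<- count + 1L          # path ends at first target reached
      } else if (depth < maxLen && !(w %in% onPath)) {
        visit(w, depth + 1L, c(onPath, w))
      }
    }
  }
  visit(node, 1L, c(node))
  count
}

#' Proximity of every network node to a target pathway
#'
#' For each node outside `targetSet`, computes the number of capped simple
#' causal paths into the target set, the shortest directed distance to any
#' target member, and the distance Z-score standardized over the nodes with
#' finite distance (sample sd; if the sd is zero all Z-scores are 0).
#' A node is `selected` iff its Z-score is negative (closer than average)
#' and it is druggable.
#'
#' @param net a [CausalNetwork-class].
#' @param targetSet non-empty character vector of target node ids.
#' @param cfg an [analysisConfig()]; `proximityMaxPathLen` caps the path
#'   length.
#' @return a data.frame with columns `node_id`, `path_count`,
#'   `shortest_distance` (`Inf` when unreachable), `z_score` (`NA` when
#'   unreachable), `druggable`, `selected`, ordered by descending
#'   `path_count` with lexicographic ties.
#' @export
proximityTable <- function(net, targetSet, cfg = analysisConfig()) {
  if (length(targetSet) == 0) stop("empty target set")
  nd <- networkNodes(net)
  missing <- setdiff(targetSet, nd$id)
  if (length(missing))
    stop("target(s) not in network: ", paste(missing, collapse = ", "))
  g <- .asIgraph(net)
  query <- setdiff(nd$id, targetSet)
  dmat <- igraph::distances(g, v = query, to = unique(targetSet),
                            mode = "out")
  dist <- apply(dmat, 1, min)
  dist[dist > cfg$proximityMaxPathLen] <- Inf  # beyond the path cap = none
  counts <- vapply(query, function(v)
    countCausalPaths(net, v, targetSet, cfg$proximityMaxPathLen), 1L)
  finite <- is.finite(dist)
  z <- rep(NA_real_, length(dist))
  if (sum(finite) > 0) {
    dd <- dist[finite]
    s <- if (length(dd) > 1) sd(dd) else 0
    z[finite] <- if (s > 0) (dd - mean(dd)) / s else 0
  }
  drug <- nd$is_druggable[match(query, nd$id)]
  out <- data.frame(node_id = query, path_count = unname(counts),
                    shortest_distance = unname(dist),
                    z_score = unname(z), druggable = drug,
                    selected = !is.na(z) & z < 0 & drug,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$path_count, out$node_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select candidate kinases from a proximity table
#'
#' Nodes proximal to the target pathway (Z-score < 0) with an available
#' inhibitor (druggable), ordered by descending path count.
#'
#' @param scores output of [proximityTable()].
#' @param druggableSet optional character vector overriding the table's
#'   druggable flag.
#' @return character vector of selected node ids.
#' @export
selectCandidateKinases <- function(scores, druggableSet = NULL) {
  drug <- if (is.null(druggableSet)) scores$druggable
          else scores$node_id %in% druggableSet
  sel <- scores[!is.na(scores$z_score) & scores$z_score < 0 & drug, ,
                drop = FALSE]
  sel <- sel[order(-sel$path_count, sel$node_id), , drop = FALSE]
  sel$node_id
}
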