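# Leader-follower graphs over selected channel pairs: normalised edge
# strengths, subject-vote direction consistency, layered (longest-path)
# layout after cycle breaking, and between-group direction flips.

#' Normalise a lead matrix to the range [-1, 1]
#'
#' Divides by the maximum absolute entry, removing overall scale so that
#' subjects with different signal amplitudes can be averaged.
#'
#' @param lm antisymmetric matrix, not identically zero.
#' @return antisymmetric matrix with maximum absolute entry 1.
#' @export
normalize_lead <- function(lm) {
  mx <- max(abs(lm))
  if (mx == 0) stop("zero lead matrix cannot be normalized", call. = FALSE)
  lm / mx
}

#' Sign matrix of a lead matrix
#'
#' Elements set to +/-1 by direction; exact zeros stay 0 (they carry no
#' direction and are excluded from vote tallies).
#'
#' @param lm antisymmetric matrix.
#' @return antisymmetric matrix with entries in \{-1, 0, 1\}.
#' @export
sign_matrix <- function(lm) {
  sign(lm)
}

#' Leader-follower consistency graph for one group
#'
#' For each selected pair, each subject casts one vote: the sign of the
#' subject's run-mean normalised lead entry (runs averaged first so a
#' subject counts once; exact-zero votes are dropped).  The edge points in
#' the majority direction, its weight is the winning vote proportion, and
#' its strength is the group mean of the normalised entries.  Ties go to
#' the lower-ordered direction (i -> j).
#'
#' @param lead_list list of per-run lead matrices for the group.
#' @param subject subject id per run.
#' @param pairs two-column (i, j) index matrix of selected pairs (i < j).
#' @return list of class \code{leader_follower_graph} with \code{edges}
#'   (data frame: from, to, weight, strength, n_votes), \code{nodes}, and
#'   \code{layers} (from [assign_layers()]).
#' @export
consistency_graph <- function(lead_list, subject, pairs) {
  stopifnot(length(lead_list) == length(subject))
  m <- nrow(lead_list[[1L]])
  labels <- rownames(lead_list[[1L]])
  if (is.null(labels)) labels <- paste0("ch", seq_len(m))
  pairs <- as.matrix(pairs)
  if (any(pairs < 1L | pairs > m)) stop("pair index out of range", call. = FALSE)
  norm_list <- lapply(lead_list, normalize_lead)
  subj_lev <- unique(subject)
  # subject-mean normalised matrices
  subj_mean <- lapply(subj_lev, function(s) {
    keep <- which(subject == s)
    Reduce(`+`, norm_list[keep]) / length(keep)
  })
  group_mean <- Reduce(`+`, norm_list) / length(norm_list)

  edges <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    votes <- vapply(subj_mean, function(a) sign(a[i, j]), 0)
    votes <- votes[votes != 0]
    n_pos <- sum(votes > 0)
    n_votes <- length(votes)
    prop_pos <- if (n_votes) n_pos / n_votes else 0.5
    # A[i,j] > 0: i leads, j follows -> edge i -> j
    fwd <- prop_pos >= 0.5
    data.frame(from = labels[if (fwd) i else j],
               to = labels[if (fwd) j else i],
               weight = if (fwd) prop_pos else 1 - prop_pos,
               strength = group_mean[i, j],
               n_votes = n_votes,
               stringsAsFactors = FALSE)
  }))
  nodes <- unique(labels[as.vector(t(pairs))])
  g <- list(nodes = nodes, edges = edges)
  g$layers <- assign_layers(g)
  class(g) <- "leader_follower_graph"
  g
}

#' Longest-path layer assignment for a leader-follower graph
#'
#' Activity flows downward: each node is placed as soon as all its
#' predecessors have appeared (sources at layer 0, every other node one
#' past its deepest in-neighbour).  Cycles among majority directions are
#' broken first by repeatedly removing the lowest-weight edge inside a
#' strongly connected component, with a message naming each dropped edge.
#'
#' @param graph a \code{leader_follower_graph} (or list with
#'   \code{nodes}/\code{edges}).
#' @return named integer vector of layers.
#' @export
assign_layers <- function(graph) {
  edges <- graph$edges
  nodes <- graph$nodes
  if (is.null(edges) || nrow(edges) == 0L)
    return(stats::setNames(rep(0L, length(nodes)), nodes))
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     vertices = nodes, directed = TRUE)
  w <- edges$weight
  while (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    el <- igraph::as_edgelist(g)
    memb <- comp$membership
    cyc_edges <- which(memb[el[, 1L]] == memb[el[, 2L]] &
                         comp$csize[memb[el[, 1L]]] > 1L)
    drop <- cyc_edges[order(w[cyc_edges], cyc_edges)][1L]
    message("breaking cycle: dropping edge ", el[drop, 1L], " -> ",
            el[drop, 2L], " (weight ", signif(w[drop], 3), ")")
    g <- igraph::delete_edges(g, drop)
    w <- w[-drop]
  }
  ord <- igraph::topo_sort(g, mode = "out")
  layers <- stats::setNames(rep(0L, length(nodes)), nodes)
  el <- igraph::as_edgelist(g)
  for (v in names(ord)) {
    preds <- el[el[, 2L] == v, 1L]
    if (length(preds)) layers[v] <- 1L + max(layers[preds])
  }
  layers
}

#' Pairs whose leader-follower direction flips between two groups
#'
#' @param graph_a,graph_b consistency graphs over the same pair set.
#' @return data frame of flipped pairs (from/to as in graph_a).
#' @export
flipped_edges <- function(graph_a, graph_b) {
  ea <- graph_a$edges; eb <- graph_b$edges
  key <- function(e) ifelse(e$from < e$to, paste(e$from, e$to),
                            paste(e$to, e$from))
  ka <- key(ea); kb <- key(eb)
  if (!setequal(ka, kb)) stop("graphs cover different pair sets", call. = FALSE)
  flip <- vapply(seq_len(nrow(ea)), function(r) {
    b <- which(kb == ka[r])[1L]
    ea$from[r] != eb$from[b]
  }, TRUE)
  ea[flip, c("from", "to")]
}
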