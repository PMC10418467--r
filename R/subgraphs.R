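# Connected subgraph enumeration for the Kier-Hall connectivity indices.
#
# A subgraph of order k is a connected set of k edges. Its type is decided
# by the degree signature *within the subgraph*:
#   path          all internal degrees <= 2 (a simple chain; k+1 atoms)
#   cluster       star-like: no atom of degree 2 (defined for k >= 3)
#   path-cluster  a branched tree with both a branch point and a chain
#                 atom (defined for k >= 4)
# Cyclic edge subsets (k edges on k atoms) fall outside these three tree
# types and are never returned.

.valid_subgraph_type <- function(k, type) {
  switch(type,
    path = TRUE,
    cluster = k >= 3,
    `path-cluster` = k >= 4,
    FALSE
  )
}

.classify_subgraph <- function(deg, n_atoms, k) {
  if (k >= n_atoms) return("cycle")
  if (max(deg) <= 2) return("path")
  if (!any(deg == 2)) return("cluster")
  "path-cluster"
}

#' Enumerate connected subgraphs of a given order and type
#'
#' All connected edge subgraphs with exactly `k` edges whose internal
#' degree signature matches the requested type, each reported once. Order
#' 0 returns the single atoms.
#'
#' @param g A [mol_graph].
#' @param k Subgraph order (number of edges), 0 to 4 in descriptor use,
#'   any non-negative integer accepted.
#' @param type `"path"`, `"cluster"` (k >= 3) or `"path-cluster"`
#'   (k >= 4).
#' @return A list of integer vectors of atom indices (sorted).
#' @export
#' @examples
#' length(enumerate_subgraphs(parse_smiles("CCCC"), 2, "path"))       # 2
#' length(enumerate_subgraphs(parse_smiles("CC(C)C"), 3, "cluster"))  # 1
enumerate_subgraphs <- function(g, k,
                                type = c("path", "cluster", "path-cluster")) {
  stopifnot(inherits(g, "mol_graph"))
  type <- match.arg(type)
  if (!is.numeric(k) || length(k) != 1 || k < 0 || k != round(k)) {
    stop("`k` must be a non-negative integer", call. = FALSE)
  }
  k <- as.integer(k)
  if (k == 0L) {
    if (type != "path") {
      stop("order 0 subgraphs exist only for type 'path'", call. = FALSE)
    }
    return(as.list(seq_len(nrow(g$atoms))))
  }
  if (!.valid_subgraph_type(k, type)) {
    stop(sprintf("type '%s' is undefined for order %d", type, k),
         call. = FALSE)
  }
  sets <- .connected_edge_sets(g, k)
  out <- list()
  for (edges in sets) {
    atoms <- sort(unique(c(g$bonds$from[edges], g$bonds$to[edges])))
    deg <- integer(length(atoms))
    names(deg) <- atoms
    for (e in edges) {
      deg[as.character(g$bonds$from[e])] <-
        deg[as.character(g$bonds$from[e])] + 1L
      deg[as.character(g$bonds$to[e])] <-
        deg[as.character(g$bonds$to[e])] + 1L
    }
    if (.classify_subgraph(deg, length(atoms), k) == type) {
      out[[length(out) + 1L]] <- atoms
    }
  }
  out
}

# Enumerate connected k-edge subsets, each once. Grows sets one adjacent
# edge at a time and deduplicates by sorted edge key; descriptor orders are
# tiny (k <= 4), so the redundancy is cheap and the code obviously correct.
.connected_edge_sets <- function(g, k) {
  m <- nrow(g$bonds)
  if (m < k) return(list())
  inc <- lapply(seq_len(nrow(g$atoms)), function(a) {
    which(g$bonds$from == a | g$bonds$to == a)
  })
  edge_nbrs <- lapply(seq_len(m), function(e) {
    setdiff(unique(c(inc[[g$bonds$from[e]]], inc[[g$bonds$to[e]]])), e)
  })
  current <- lapply(seq_len(m), function(e) e)
  for (size in seq_len(k - 1)) {
    nxt <- list()
    seen <- new.env(parent = emptyenv())
    for (set in current) {
      frontier <- setdiff(unique(unlist(edge_nbrs[set])), set)
      for (e in frontier) {
        grown <- sort(c(set, e))
        key <- paste(grown, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          nxt[[length(nxt) + 1L]] <- grown
        }
      }
    }
    current <- nxt
  }
  current
}
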