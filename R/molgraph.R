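#' Hydrogen-depleted molecular graph
#'
#' The substrate of every descriptor in the package: heavy atoms as
#' vertices, bonds as edges, with per-atom element data and implicit
#' hydrogen counts. The constructor validates the structure, requires the
#' graph to be connected, and precomputes the adjacency matrix `A` and the
#' topological (shortest-path, bond-count) distance matrix `D`.
#'
#' @param atoms A data frame with columns `element`, `formal_charge`,
#'   `implicit_h`, `aromatic`, `Z`, `Zv` (one row per heavy atom).
#' @param bonds A data frame with columns `from`, `to` (atom indices),
#'   `order` (1, 2 or 3) and `aromatic` (logical).
#' @param smiles Optional source string, kept for printing only.
#' @return An object of class `mol_graph`: a list with elements `atoms`,
#'   `bonds`, `adjacency` and `distances`.
#' @export
#' @examples
#' propane <- parse_smiles("CCC")
#' propane$distances
mol_graph <- function(atoms, bonds, smiles = NULL) {
  atoms <- tibble::as_tibble(atoms)
  bonds <- tibble::as_tibble(bonds)
  n <- nrow(atoms)
  stopifnot(n >= 1)
  if (nrow(bonds)) {
    stopifnot(all(bonds$from >= 1), all(bonds$to >= 1),
              all(bonds$from <= n), all(bonds$to <= n),
              all(bonds$from != bonds$to),
              all(bonds$order %in% 1:3))
    key <- paste(pmin(bonds$from, bonds$to), pmax(bonds$from, bonds$to))
    if (anyDuplicated(key)) stop("duplicate bonds", call. = FALSE)
  }
  stopifnot(all(atoms$implicit_h >= 0), all(atoms$Zv <= atoms$Z))

  A <- matrix(0, n, n)
  if (nrow(bonds)) {
    A[cbind(bonds$from, bonds$to)] <- 1
    A[cbind(bonds$to, bonds$from)] <- 1
  }
  D <- .graph_distances(A)
  if (any(is.infinite(D))) {
    stop("molecular graph must be connected", call. = FALSE)
  }
  structure(
    list(atoms = atoms, bonds = bonds, adjacency = A, distances = D),
    smiles = smiles,
    class = "mol_graph"
  )
}

# BFS shortest paths on an unweighted graph, via igraph.
.graph_distances <- function(A) {
  n <- nrow(A)
  if (n == 1) return(matrix(0, 1, 1))
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  unname(igraph::distances(ig, algorithm = "unweighted"))
}

#' @export
print.mol_graph <- function(x, ...) {
  smi <- attr(x, "smiles")
  cat("<mol_graph> ", nrow(x$atoms), " heavy atoms, ", nrow(x$bonds),
      " bonds", if (!is.null(smi)) paste0("  [", smi, "]"), "\n", sep = "")
  counts <- table(x$atoms$element)
  cat("  formula (heavy): ",
      paste0(names(counts), ifelse(counts > 1, counts, ""), collapse = ""),
      ", implicit H: ", sum(x$atoms$implicit_h), "\n", sep = "")
  if (any(x$atoms$aromatic)) {
    cat("  aromatic atoms: ", sum(x$atoms$aromatic), "\n", sep = "")
  }
  invisible(x)
}

#' Topological distance matrix
#'
#' Shortest-path length in bonds between every pair of heavy atoms,
#' computed by breadth-first search. This is the `D` matrix of the charge
#' term matrix `M = A Q`, `Q = 1/D^2`.
#'
#' @param g A [mol_graph].
#' @return An integer-valued symmetric matrix with zero diagonal.
#' @export
distance_matrix <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  g$distances
}

# Heavy-atom degree of every atom.
.degrees <- function(g) {
  as.integer(rowSums(g$adjacency))
}

# All simple cycles of length min_len..max_len, as lists of vertex indices
# in ring order. Used for aromaticity perception; molecules are small, so a
# bounded DFS from each start vertex is plenty.
.simple_cycles <- function(g, min_len = 5L, max_len = 6L) {
  n <- nrow(g$atoms)
  adj <- lapply(seq_len(n), function(i) which(g$adjacency[i, ] > 0))
  found <- list()
  seen <- character(0)
  dfs <- function(start, path) {
    last <- path[length(path)]
    for (nb in adj[[last]]) {
      if (nb == start && length(path) >= min_len) {
        key <- paste(sort(path), collapse = "-")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          found[[length(found) + 1L]] <<- path
        }
      } else if (nb > start && !(nb %in% path) && length(path) < max_len) {
        dfs(start, c(path, nb))
      }
    }
  }
  for (s in seq_len(n)) dfs(s, s)
  found
}

#' Perceive aromatic rings
#'
#' Flags atoms and bonds of aromatic rings using a planarity-free Hueckel
#' rule on the Kekule graph. Candidate rings are simple cycles of 5 or 6
#' atoms. Within a ring, each atom contributes pi electrons as follows:
#' an atom with a double bond to any ring atom (its own ring or a fused
#' one) contributes 1; a nitrogen, oxygen or sulfur with no double bond
#' contributes its lone pair (2); a carbon with only single bonds is sp3
#' and disqualifies the ring; a carbon whose only double bond is exocyclic
#' to a non-ring atom (e.g. a ring carbonyl) contributes 0. A ring is
#' aromatic when it is not disqualified and its electron count satisfies
#' 4n+2. Bonds between adjacent atoms of an aromatic ring are flagged
#' aromatic; all other bonds keep their Kekule orders. The rule
#' distinguishes benzene, pyridine-, pyrimidine-, quinoline-, pyrazole- and
#' thiophene-type rings from cyclohexadiene and saturated heterocycles,
#' which is exactly the split the non-aromatic double-bond count `nDB`
#' depends on.
#'
#' @param g A [mol_graph] with Kekule bond orders.
#' @return The graph with `aromatic` flags set on atoms and bonds.
#' @export
#' @examples
#' all(parse_smiles("C1=CC=CC=C1")$bonds$aromatic)   # benzene
#' any(parse_smiles("C1CCCCC1")$bonds$aromatic)      # cyclohexane
perceive_aromaticity <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  g$atoms$aromatic <- FALSE
  g$bonds$aromatic <- FALSE
  if (!nrow(g$bonds)) return(g)

  cycles <- .simple_cycles(g)
  if (!length(cycles)) return(g)
  ring_atoms <- sort(unique(unlist(cycles)))

  # double-bond partners of every atom (Kekule orders)
  dbl <- g$bonds[g$bonds$order == 2L, , drop = FALSE]
  partners <- lapply(seq_len(nrow(g$atoms)), function(i) {
    c(dbl$to[dbl$from == i], dbl$from[dbl$to == i])
  })

  bond_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  keys <- bond_key(g$bonds$from, g$bonds$to)

  for (cyc in cycles) {
    pi_e <- 0L
    ok <- TRUE
    for (a in cyc) {
      p <- partners[[a]]
      el <- g$atoms$element[a]
      if (length(p) && any(p %in% ring_atoms)) {
        pi_e <- pi_e + 1L
      } else if (length(p)) {
        # exocyclic double bond only: no pi contribution, not disqualifying
      } else if (el %in% c("N", "O", "S")) {
        pi_e <- pi_e + 2L
      } else {
        ok <- FALSE
        break
      }
    }
    if (ok && pi_e >= 2L && (pi_e - 2L) %% 4L == 0L) {
      g$atoms$aromatic[cyc] <- TRUE
      edge <- bond_key(cyc, c(cyc[-1], cyc[1]))
      g$bonds$aromatic[keys %in% edge] <- TRUE
    }
  }
  g
}
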