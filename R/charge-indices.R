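# Galvez topological charge indices.
#
# M = A Q, where A is the adjacency matrix of the hydrogen-depleted graph
# and Q[i,j] = 1/D[i,j]^2 off the diagonal (0 on it). The charge transfer
# term for an atom pair is |M[i,j] - M[j,i]|; G_k sums it over unordered
# pairs at topological distance k.

#' Charge term matrix
#'
#' The matrix `M = A Q` behind the Galvez topological charge indices, with
#' `Q` the inverse square distance matrix. For the valence variant, the
#' diagonal of `A` carries a per-element electronegativity weight
#' (carbon-referenced Pauling values by default, see
#' [electronegativity_weights()]), so heteroatoms perturb the charge terms
#' of their neighbourhood.
#'
#' @param g A [mol_graph].
#' @param valence Use the electronegativity-modified adjacency?
#' @param weights Named per-element diagonal weights for the valence
#'   variant.
#' @return An `N x N` numeric matrix.
#' @export
#' @examples
#' charge_term_matrix(parse_smiles("CCC"))
charge_term_matrix <- function(g, valence = FALSE,
                               weights = electronegativity_weights()) {
  stopifnot(inherits(g, "mol_graph"))
  A <- g$adjacency
  D <- g$distances
  n <- nrow(A)
  if (n == 1) return(matrix(0, 1, 1))
  Q <- ifelse(D > 0, 1 / D^2, 0)
  if (valence) {
    w <- weights[g$atoms$element]
    if (anyNA(w)) {
      stop("no electronegativity weight for element(s): ",
           paste(unique(g$atoms$element[is.na(w)]), collapse = ", "),
           call. = FALSE)
    }
    diag(A) <- w
  }
  A %*% Q
}

#' Topological charge index G_k
#'
#' Sum of `|M[i,j] - M[j,i]|` over unordered atom pairs at topological
#' distance `k`, with `M` the (optionally valence-modified) charge term
#' matrix. Returns 0 when the graph has no pair at that distance. Known in
#' descriptor tables as `GGIk` (and `GGIkv` for the valence form).
#'
#' @inheritParams charge_term_matrix
#' @param k Topological distance, a positive integer.
#' @return A non-negative number.
#' @export
#' @examples
#' gk(parse_smiles("CCC"), 1)  # 0.5
gk <- function(g, k, valence = FALSE,
               weights = electronegativity_weights()) {
  stopifnot(inherits(g, "mol_graph"))
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  M <- charge_term_matrix(g, valence = valence, weights = weights)
  CT <- abs(M - t(M))
  sel <- g$distances == k & upper.tri(g$distances)
  sum(CT[sel])
}

#' Normalized topological charge index J_k
#'
#' `G_k` divided by a size normalizer; known in descriptor tables as `JGIk`.
#' The default (`normalize = "mean"`) divides by the number of atom pairs
#' at topological distance `k`, i.e. the mean charge-transfer term among
#' the pairs that contribute -- the convention of the descriptor software
#' whose values the packaged models were fitted on, and the one that
#' reproduces the shipped discriminant scores. `normalize = "classic"`
#' divides by `N - 1` as in the original charge-index formulation; the two
#' agree on acyclic graphs at `k = 1`. With `"mean"`, a distance with no
#' pairs yields 0.
#'
#' @inheritParams gk
#' @param normalize `"mean"` (pair count) or `"classic"` (`N - 1`).
#' @return A non-negative number.
#' @export
#' @examples
#' jk(parse_smiles("CCC"), 1)  # 0.25
jk <- function(g, k, valence = FALSE,
               normalize = c("mean", "classic"),
               weights = electronegativity_weights()) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(g, "mol_graph"))
  n <- nrow(g$atoms)
  if (normalize == "classic" && n < 2) {
    stop("classic normalization needs at least 2 atoms", call. = FALSE)
  }
  val <- gk(g, k, valence = valence, weights = weights)
  denom <- switch(normalize,
    mean = sum(g$distances == k & upper.tri(g$distances)),
    classic = n - 1
  )
  if (denom == 0) 0 else val / denom
}

# All charge indices 1..kmax at once (used by descriptor_vector); one
# matrix product instead of kmax.
.charge_indices_all <- function(g, kmax = 10L, valence = FALSE,
                                weights = electronegativity_weights()) {
  M <- charge_term_matrix(g, valence = valence, weights = weights)
  CT <- abs(M - t(M))
  up <- upper.tri(g$distances)
  gg <- jj <- numeric(kmax)
  for (k in seq_len(kmax)) {
    sel <- g$distances == k & up
    npair <- sum(sel)
    gg[k] <- sum(CT[sel])
    jj[k] <- if (npair == 0) 0 else gg[k] / npair
  }
  list(g = gg, j = jj)
}
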