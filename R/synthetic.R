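# Synthetic inputs for property tests: random labelled molecular graphs
# (descriptor-invariance and oracle checks) and linear-response QSAR
# datasets (model-recovery checks). Every generator is a pure function of
# its seed: RNG state is sandboxed and restored.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# elements compatible with a given heavy-atom degree under single bonds
.element_pool <- function(degree) {
  switch(min(degree, 4L) + 1L,
    c("C", "N", "O", "S", "Cl"),        # degree 0 (unused: graphs connected)
    c("C", "N", "O", "S", "Cl"),        # degree 1
    c("C", "N", "O", "S"),              # degree 2
    c("C", "N"),                        # degree 3
    "C"                                  # degree 4
  )
}

#' Random labelled molecular graph
#'
#' A connected random graph built as a random spanning tree plus optional
#' extra edges, degree capped at 4, all bonds single, elements sampled
#' from {C, N, O, S, Cl} compatibly with each atom's degree. Chemically
#' plausible enough for descriptor invariance and oracle tests; not a
#' molecule generator.
#'
#' @param n_atoms Number of heavy atoms (>= 2, <= 12 keeps brute-force
#'   oracles instantaneous).
#' @param seed Integer seed; the result is a pure function of it.
#' @param extra_edges Expected number of additional (ring-forming) edges.
#' @return A [mol_graph].
#' @export
#' @examples
#' random_molecular_graph(6, seed = 1)
random_molecular_graph <- function(n_atoms, seed, extra_edges = 1) {
  stopifnot(n_atoms >= 2)
  .with_seed(seed, {
    from <- integer(0); to <- integer(0)
    deg <- integer(n_atoms)
    for (v in 2:n_atoms) {
      open <- which(deg[seq_len(v - 1)] < 4L)
      u <- if (length(open) == 1) open else sample(open, 1)
      from <- c(from, u); to <- c(to, v)
      deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
    }
    n_extra <- stats::rpois(1, extra_edges)
    for (dummy in seq_len(n_extra)) {
      open <- which(deg < 4L)
      if (length(open) < 2) break
      cand <- utils::combn(open, 2)
      have <- paste(pmin(from, to), pmax(from, to))
      new <- which(!(paste(cand[1, ], cand[2, ]) %in% have))
      if (!length(new)) break
      pick <- cand[, if (length(new) == 1) new else sample(new, 1)]
      from <- c(from, pick[1]); to <- c(to, pick[2])
      deg[pick[1]] <- deg[pick[1]] + 1L
      deg[pick[2]] <- deg[pick[2]] + 1L
    }
    element <- vapply(seq_len(n_atoms), function(v) {
      pool <- .element_pool(deg[v])
      # carbon-biased so graphs look organic
      probs <- ifelse(pool == "C", 4, 1)
      sample(pool, 1, prob = probs)
    }, character(1))
    info <- lapply(element, .element_info)
    valence <- vapply(info, function(x) max(x$valences), integer(1))
    atoms <- tibble::tibble(
      element = element,
      formal_charge = 0L,
      implicit_h = pmax(0L, vapply(info, function(x) min(x$valences),
                                   integer(1)) - deg),
      aromatic = FALSE,
      Z = vapply(info, `[[`, integer(1), "Z"),
      Zv = vapply(info, `[[`, integer(1), "Zv")
    )
    bonds <- tibble::tibble(from = from, to = to, order = 1L,
                            aromatic = FALSE)
    mol_graph(atoms, bonds)
  })
}

#' Permute the atom order of a molecular graph
#'
#' Relabels atoms by a random (or given) permutation, producing an
#' isomorphic graph. Every descriptor is invariant under this operation;
#' the generator exists so tests can assert it.
#'
#' @param g A [mol_graph].
#' @param seed Integer seed for a random permutation.
#' @param perm Optional explicit permutation (ignores `seed`): `perm[i]`
#'   is the new index of old atom `i`.
#' @return A [mol_graph] isomorphic to `g`.
#' @export
permute_atoms <- function(g, seed = NULL, perm = NULL) {
  stopifnot(inherits(g, "mol_graph"))
  n <- nrow(g$atoms)
  if (is.null(perm)) {
    stopifnot(!is.null(seed))
    perm <- .with_seed(seed, sample.int(n))
  }
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  atoms <- g$atoms[order(perm), ]
  bonds <- g$bonds
  bonds$from <- perm[bonds$from]
  bonds$to <- perm[bonds$to]
  mol_graph(atoms, bonds, smiles = attr(g, "smiles"))
}

#' Synthetic linear-response QSAR dataset
#'
#' Draws a standard-normal design matrix and a response
#' `y = intercept + X beta + N(0, sigma^2)` -- the data-generating model the
#' regression analysis assumes. Used for coefficient-recovery and
#' cross-validation properties.
#'
#' @param n Sample size (must exceed `length(beta) + 2`).
#' @param beta Coefficient vector; its length sets the number of
#'   predictors, named `x1..xp`.
#' @param sigma Noise standard deviation (>= 0).
#' @param intercept Intercept (default 0).
#' @param seed Integer seed.
#' @return A tibble with columns `x1..xp` and `y`, with the true
#'   parameters in attribute `truth`.
#' @export
synthetic_qsar_dataset <- function(n, beta, sigma, seed, intercept = 0) {
  p <- length(beta)
  stopifnot(n > p + 2, sigma >= 0)
  .with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    y <- intercept + drop(X %*% beta) + stats::rnorm(n, sd = sigma)
    out <- tibble::as_tibble(as.data.frame(X))
    out$y <- y
    attr(out, "truth") <- list(beta = beta, sigma = sigma,
                               intercept = intercept)
    out
  })
}

#' Synthetic two-class dataset with a controllable separation
#'
#' Labels come from thresholding a noisy linear score whose class means
#' are `df_gap` apart (in units of the noise SD), emulating an
#' active/inactive split along a discriminant axis.
#'
#' @inheritParams synthetic_qsar_dataset
#' @param df_gap Separation between the class mean scores.
#' @return A tibble with predictors `x1..xp` and a `class` column
#'   (`"A"`/`"I"`).
#' @export
synthetic_classification_dataset <- function(n, beta, df_gap, seed) {
  p <- length(beta)
  stopifnot(n > p + 2, df_gap >= 0)
  .with_seed(seed, {
    cls <- rep(c("A", "I"), length.out = n)
    shift <- ifelse(cls == "A", df_gap / 2, -df_gap / 2)
    dir <- beta / sqrt(sum(beta^2))
    X <- matrix(stats::rnorm(n * p), n, p) + outer(shift, dir)
    colnames(X) <- paste0("x", seq_len(p))
    out <- tibble::as_tibble(as.data.frame(X))
    out$class <- cls
    out
  })
}
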