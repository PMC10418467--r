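# Constitutional, connectivity and bulk descriptors.

#' Count non-aromatic double bonds (nDB)
#'
#' Number of bonds of order 2 that are not part of a perceived aromatic
#' ring. Carbonyls, sulfonyl S=O and isolated or cross-conjugated C=C count;
#' the Kekule double bonds of an aromatic ring do not.
#'
#' @param g A [mol_graph] with aromaticity perceived.
#' @return A non-negative integer.
#' @export
#' @examples
#' count_double_bonds(parse_smiles("C=C"))        # 1
#' count_double_bonds(parse_smiles("C1=CC=CC=C1")) # 0
count_double_bonds <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  sum(g$bonds$order == 2L & !g$bonds$aromatic)
}

#' Count nitrogen atoms (nN)
#'
#' @param g A [mol_graph].
#' @return The number of nitrogen atoms, whatever their charge.
#' @export
count_nitrogens <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  sum(g$atoms$element == "N")
}

# Kier-Hall simple delta: heavy-atom degree.
.delta_simple <- function(g) {
  .degrees(g)
}

# Kier-Hall valence delta: (Zv - h) for second-row atoms, scaled by the
# core electron count (Z - Zv - 1) beyond. Formal charge is not subtracted
# from Zv, so a quaternary [N+] has delta_v = 5.
.delta_valence <- function(g) {
  zv <- g$atoms$Zv
  z <- g$atoms$Z
  h <- g$atoms$implicit_h
  ifelse(z <= 10, zv - h, (zv - h) / (z - zv - 1))
}

#' Kier--Hall connectivity index
#'
#' The Randic-type connectivity index of order `k` and subgraph type `t`:
#' the sum over all connected `k`-edge subgraphs of that type of
#' \eqn{\prod_{i \in S} \delta_i^{-1/2}}, where \eqn{\delta_i} is the
#' heavy-atom degree (simple form) or the Kier--Hall valence delta
#' \eqn{\delta^v_i} (valence form). Order 0 runs over single atoms.
#'
#' @param g A [mol_graph].
#' @param k Order (number of edges in the subgraph), 0 to 4.
#' @param type Subgraph type: `"path"`, `"cluster"` or `"path-cluster"`.
#' @param valence Use valence deltas?
#' @return A non-negative number (0 when no subgraph of the type exists).
#' @export
#' @examples
#' chi_index(parse_smiles("CCCC"), 1, "path")          # 1.9142
#' chi_index(parse_smiles("CCO"), 0, valence = TRUE)   # X0v of ethanol
chi_index <- function(g, k, type = c("path", "cluster", "path-cluster"),
                      valence = FALSE) {
  type <- match.arg(type)
  stopifnot(inherits(g, "mol_graph"))
  delta <- if (valence) .delta_valence(g) else .delta_simple(g)
  subs <- enumerate_subgraphs(g, k, type)
  if (!length(subs)) return(0)
  used <- sort(unique(unlist(subs)))
  bad <- used[delta[used] <= 0]
  if (length(bad)) {
    stop(sprintf("non-positive %s delta on atom %d (%s)",
                 if (valence) "valence" else "simple",
                 bad[1], g$atoms$element[bad[1]]), call. = FALSE)
  }
  sum(vapply(subs, function(s) 1 / sqrt(prod(delta[s])), numeric(1)))
}

#' Connectivity difference and quotient
#'
#' `D = chi - chi_v` and `C = chi / chi_v` for the given order and type.
#' The quotient is undefined when the valence index is 0.
#'
#' @inheritParams chi_index
#' @return A named list with elements `difference` and `quotient`.
#' @export
chi_difference_quotient <- function(g, k,
                                    type = c("path", "cluster",
                                             "path-cluster")) {
  type <- match.arg(type)
  x <- chi_index(g, k, type, valence = FALSE)
  xv <- chi_index(g, k, type, valence = TRUE)
  if (xv == 0) {
    stop(sprintf("connectivity quotient undefined: %d-%s valence index is 0",
                 k, type), call. = FALSE)
  }
  list(difference = x - xv, quotient = x / xv)
}

#' Mean atomic van der Waals volume (Mv)
#'
#' Mean carbon-scaled van der Waals volume over all atoms of the molecule,
#' hydrogens included: implicit hydrogens enter both the numerator and the
#' atom count. Volumes come from [vdw_volume_table()] and can be replaced.
#'
#' @param g A [mol_graph].
#' @param volume_table A data frame with columns `element` and `volume`.
#' @return A positive number, bounded by the smallest and largest atomic
#'   volume present in the molecule.
#' @export
#' @examples
#' mean_vdw_volume(parse_smiles("C"))  # (1 + 4 * v_H) / 5
mean_vdw_volume <- function(g, volume_table = vdw_volume_table()) {
  stopifnot(inherits(g, "mol_graph"))
  vol <- stats::setNames(volume_table$volume, volume_table$element)
  missing <- setdiff(unique(g$atoms$element), names(vol))
  if (length(missing)) {
    stop("no van der Waals volume for element(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n_h <- sum(g$atoms$implicit_h)
  heavy <- sum(vol[g$atoms$element])
  (heavy + n_h * vol[["H"]]) / (nrow(g$atoms) + n_h)
}

# (k, type) grid of the connectivity families: path for k = 0..4, cluster
# from 3, path-cluster from 4. Names follow the descriptor-table
# convention: X1 ... X2, X3p, X3c, X4p, X4c, X4pc, with v/D/C variants.
.chi_grid <- function() {
  tibble::tibble(
    k = c(0L, 1L, 2L, 3L, 3L, 4L, 4L, 4L),
    type = c("path", "path", "path", "path", "cluster",
             "path", "cluster", "path-cluster"),
    suffix = c("0", "1", "2", "3p", "3c", "4p", "4c", "4pc")
  )
}

#' Full descriptor vector for one molecule
#'
#' Computes every descriptor family the packaged models draw on: the
#' constitutional counts `nDB` and `nN`, the heavy-atom count `N`, the mean
#' van der Waals volume `Mv`, the Galvez charge indices `GGI1..GGI10` /
#' `JGI1..JGI10` and their valence variants (`GGI1v`, ...), and the
#' connectivity indices `X0, X1, X2, X3p, X3c, X4p, X4c, X4pc` with their
#' valence forms (`X0v`, ...), differences (`D0`, ...) and quotients
#' (`C0`, ...). Quotients whose valence index is 0 are `NA`.
#'
#' @param g A [mol_graph] (aromaticity perceived).
#' @param volume_table Volume table for `Mv`.
#' @param kmax_charge Highest charge-index order (default 10; the shipped
#'   models use orders up to 9).
#' @return A named list of descriptor values.
#' @seealso [compute_descriptors()] for the data-frame interface.
#' @export
descriptor_vector <- function(g, volume_table = vdw_volume_table(),
                              kmax_charge = 10L) {
  stopifnot(inherits(g, "mol_graph"))
  out <- list(
    N = nrow(g$atoms),
    nDB = count_double_bonds(g),
    nN = count_nitrogens(g),
    Mv = mean_vdw_volume(g, volume_table)
  )
  ci <- .charge_indices_all(g, kmax = kmax_charge)
  civ <- .charge_indices_all(g, kmax = kmax_charge, valence = TRUE)
  for (k in seq_len(kmax_charge)) {
    out[[paste0("GGI", k)]] <- ci$g[k]
    out[[paste0("JGI", k)]] <- ci$j[k]
    out[[paste0("GGI", k, "v")]] <- civ$g[k]
    out[[paste0("JGI", k, "v")]] <- civ$j[k]
  }
  grid <- .chi_grid()
  for (i in seq_len(nrow(grid))) {
    x <- chi_index(g, grid$k[i], grid$type[i], valence = FALSE)
    xv <- chi_index(g, grid$k[i], grid$type[i], valence = TRUE)
    sfx <- grid$suffix[i]
    out[[paste0("X", sfx)]] <- x
    out[[paste0("X", sfx, "v")]] <- xv
    out[[paste0("D", sfx)]] <- x - xv
    out[[paste0("C", sfx)]] <- if (xv == 0) NA_real_ else x / xv
  }
  out
}

#' Compute descriptors for a table of compounds
#'
#' Data-frame-first wrapper around the whole descriptor pipeline: parses
#' each SMILES, perceives aromaticity and appends one column per
#' descriptor.
#'
#' @param data A data frame with a SMILES column.
#' @param smiles Column holding SMILES strings (tidy-eval; default
#'   `smiles`).
#' @param volume_table Volume table for `Mv`.
#' @return The input with descriptor columns appended, as a tibble.
#' @export
#' @examples
#' compute_descriptors(tibble::tibble(smiles = c("CCO", "C=CC=C")))
compute_descriptors <- function(data, smiles = smiles,
                                volume_table = vdw_volume_table()) {
  smi <- dplyr::pull(data, {{ smiles }})
  desc <- purrr::map(smi, function(s) {
    tibble::as_tibble(descriptor_vector(parse_smiles(s),
                                        volume_table = volume_table))
  })
  dplyr::bind_cols(tibble::as_tibble(data), dplyr::bind_rows(desc))
}
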