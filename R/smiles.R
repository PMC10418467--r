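# Minimal SMILES parser for the Kekule dialect used by the packaged compound
# table: uppercase organic-subset atoms (B, C, N, O, P, S, F, Cl, Br, I),
# bracket atoms with explicit hydrogen counts and formal charges ([N+], [H],
# [NH2]), single/double/triple bonds (-, =, #), branches and ring-bond
# digits (including reuse of digits and %nn two-digit closures). No
# aromatic lowercase atoms, stereochemistry or isotopes: descriptor values
# must not depend on drawing conventions the graph model cannot represent.

.parse_error <- function(smiles, pos, msg) {
  stop(sprintf("SMILES parse error at position %d ('%s'): %s", pos,
               substr(smiles, pos, min(nchar(smiles), pos + 5)), msg),
       call. = FALSE)
}

# Tokenize and build atom/bond lists in one pass.
.parse_smiles_one <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  if (is.na(smiles) || !nzchar(smiles)) {
    stop("empty SMILES string", call. = FALSE)
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)

  atoms <- list()   # each: element, charge, h (NA = implicit by valence)
  bonds <- list()   # each: from, to, order
  prev <- NA_integer_
  pending_order <- NA_integer_
  stack <- integer(0)
  ring <- list()    # digit -> list(atom, order, pos)

  add_atom <- function(element, charge = 0L, h = NA_integer_, pos = 1L) {
    .element_info(element)  # validates symbol
    atoms[[length(atoms) + 1L]] <<- list(element = element, charge = charge,
                                         h = h)
    idx <- length(atoms)
    if (!is.na(prev)) {
      ord <- if (is.na(pending_order)) 1L else pending_order
      bonds[[length(bonds) + 1L]] <<- list(from = prev, to = idx, order = ord)
    }
    pending_order <<- NA_integer_
    prev <<- idx
    idx
  }

  close_ring <- function(digit, pos) {
    key <- as.character(digit)
    if (is.null(ring[[key]])) {
      ring[[key]] <<- list(atom = prev, order = pending_order, pos = pos)
      pending_order <<- NA_integer_
      return(invisible())
    }
    open <- ring[[key]]
    ring[[key]] <<- NULL
    ord <- c(open$order, pending_order)
    ord <- ord[!is.na(ord)]
    if (length(ord) == 2 && ord[1] != ord[2]) {
      .parse_error(smiles, pos, "conflicting ring-bond orders")
    }
    ord <- if (length(ord)) ord[1] else 1L
    if (open$atom == prev) .parse_error(smiles, pos, "ring bond to itself")
    bonds[[length(bonds) + 1L]] <<- list(from = open$atom, to = prev,
                                         order = ord)
    pending_order <<- NA_integer_
    invisible()
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (is.na(prev)) .parse_error(smiles, i, "branch before any atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) .parse_error(smiles, i, "unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == "-") {
      pending_order <- 1L; i <- i + 1L
    } else if (ch == "=") {
      pending_order <- 2L; i <- i + 1L
    } else if (ch == "#") {
      pending_order <- 3L; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      if (is.na(prev)) .parse_error(smiles, i, "ring digit before any atom")
      close_ring(as.integer(ch), i)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L]))) {
        .parse_error(smiles, i, "'%' must be followed by two digits")
      }
      close_ring(as.integer(paste0(chars[i + 1L], chars[i + 2L])), i)
      i <- i + 3L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) .parse_error(smiles, i, "unclosed bracket atom")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body,
        regexec("^([A-Z][a-z]?)(H([0-9])?)?(([+-])([0-9])?)?$", body))[[1]]
      if (!length(m)) .parse_error(smiles, i, "malformed bracket atom")
      element <- m[2]
      hcount <- if (nzchar(m[3])) {
        if (nzchar(m[4])) as.integer(m[4]) else 1L
      } else 0L
      charge <- if (nzchar(m[5])) {
        mag <- if (nzchar(m[7])) as.integer(m[7]) else 1L
        if (m[6] == "+") mag else -mag
      } else 0L
      if (element == "H" && hcount > 0L) {
        .parse_error(smiles, i, "hydrogen count on [H] atom")
      }
      add_atom(element, charge = charge, h = hcount, pos = i)
      i <- j + 1L
    } else if (grepl("[A-Z]", ch)) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, pos = i)
        i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(ch, pos = i)
        i <- i + 1L
      } else {
        .parse_error(smiles, i, "unknown element")
      }
    } else {
      .parse_error(smiles, i, "unexpected character")
    }
  }
  if (length(stack)) .parse_error(smiles, n, "unmatched '('")
  if (length(ring)) {
    .parse_error(smiles, ring[[1]]$pos,
                 sprintf("unclosed ring bond '%s'", names(ring)[1]))
  }
  if (!length(atoms)) stop("SMILES contains no atoms", call. = FALSE)
  list(atoms = atoms, bonds = bonds)
}

# Fold explicit [H] vertices into the implicit-hydrogen count of their
# single heavy neighbour, then assign implicit hydrogens by normal valence.
.finalize_atoms <- function(parsed, smiles) {
  atoms <- parsed$atoms
  bonds <- parsed$bonds
  is_h <- vapply(atoms, function(a) a$element == "H", logical(1))

  if (any(is_h)) {
    keep <- which(!is_h)
    if (!length(keep)) stop("molecule has no heavy atoms", call. = FALSE)
    remap <- integer(length(atoms))
    remap[keep] <- seq_along(keep)
    new_bonds <- list()
    for (b in bonds) {
      hf <- is_h[b$from]; ht <- is_h[b$to]
      if (hf && ht) stop("H-H bond is not supported", call. = FALSE)
      if (hf || ht) {
        if (b$order != 1L) {
          stop("explicit hydrogen must be single-bonded", call. = FALSE)
        }
        heavy <- if (hf) b$to else b$from
        a <- atoms[[heavy]]
        a$fold <- if (is.null(a$fold)) 1L else a$fold + 1L
        atoms[[heavy]] <- a
      } else {
        b$from <- remap[b$from]; b$to <- remap[b$to]
        new_bonds[[length(new_bonds) + 1L]] <- b
      }
    }
    # an isolated [H] bonded to nothing is malformed
    h_deg <- integer(length(atoms))
    for (b in bonds) {
      h_deg[b$from] <- h_deg[b$from] + 1L
      h_deg[b$to] <- h_deg[b$to] + 1L
    }
    if (any(is_h & h_deg != 1L)) {
      stop("explicit [H] must have exactly one bond", call. = FALSE)
    }
    atoms <- atoms[keep]
    bonds <- new_bonds
  }

  # folded explicit hydrogens count toward the bond sum: [H]C(R)R is a CH2
  bond_sum <- vapply(atoms, function(a) {
    if (is.null(a$fold)) 0 else as.numeric(a$fold)
  }, numeric(1))
  for (b in bonds) {
    if (b$from == b$to) stop("self-bond in SMILES", call. = FALSE)
    bond_sum[b$from] <- bond_sum[b$from] + b$order
    bond_sum[b$to] <- bond_sum[b$to] + b$order
  }
  dup <- duplicated(vapply(bonds, function(b) {
    paste(sort(c(b$from, b$to)), collapse = "-")
  }, character(1)))
  if (any(dup)) stop("duplicate bond between the same atoms", call. = FALSE)

  out <- vector("list", length(atoms))
  for (k in seq_along(atoms)) {
    a <- atoms[[k]]
    info <- .element_info(a$element)
    folded <- if (is.null(a$fold)) 0L else a$fold
    h <- a$h
    if (is.na(h)) {
      # organic-subset atom: fill up to the smallest normal valence; the
      # folded explicit hydrogens are already in the bond sum
      fit <- info$valences[info$valences >= bond_sum[k]]
      if (!length(fit)) {
        stop(sprintf("valence overflow on atom %d (%s): %g bonds", k,
                     a$element, bond_sum[k]), call. = FALSE)
      }
      h <- as.integer(fit[1] - bond_sum[k]) + folded
    } else {
      h <- h + folded
      if (a$charge == 0L && a$element != "H" &&
          bond_sum[k] + a$h > max(info$valences)) {
        stop(sprintf("valence overflow on atom %d (%s)", k, a$element),
             call. = FALSE)
      }
    }
    out[[k]] <- list(element = a$element, formal_charge = a$charge,
                     implicit_h = h, Z = info$Z, Zv = info$Zv)
  }
  list(atoms = out, bonds = bonds)
}

#' Parse a SMILES string into a molecular graph
#'
#' Builds the hydrogen-depleted labelled graph that every descriptor in the
#' package is computed from. Explicit `[H]` atoms are folded into the
#' implicit-hydrogen count of their heavy neighbour; implicit hydrogens on
#' organic-subset atoms are assigned by the usual SMILES normal-valence
#' rules. Aromaticity is then perceived from the Kekule bond orders (see
#' [perceive_aromaticity()]).
#'
#' @param smiles A single SMILES string in the Kekule dialect (uppercase
#'   atoms, `=`/`#` bonds, ring digits, branches, bracket atoms with charge).
#' @param aromaticity Perceive aromatic rings after parsing? Almost always
#'   `TRUE`; `FALSE` gives the raw Kekule graph.
#' @return A [mol_graph] object.
#' @export
#' @examples
#' g <- parse_smiles("C1=CC=CC=C1")  # benzene
#' g
#' sum(g$atoms$implicit_h)
parse_smiles <- function(smiles, aromaticity = TRUE) {
  parsed <- .finalize_atoms(.parse_smiles_one(smiles), smiles)
  atoms <- tibble::tibble(
    element = vapply(parsed$atoms, `[[`, character(1), "element"),
    formal_charge = vapply(parsed$atoms, `[[`, integer(1), "formal_charge"),
    implicit_h = vapply(parsed$atoms, `[[`, integer(1), "implicit_h"),
    aromatic = FALSE,
    Z = vapply(parsed$atoms, `[[`, integer(1), "Z"),
    Zv = vapply(parsed$atoms, `[[`, integer(1), "Zv")
  )
  bonds <- if (length(parsed$bonds)) {
    tibble::tibble(
      from = vapply(parsed$bonds, `[[`, integer(1), "from"),
      to = vapply(parsed$bonds, `[[`, integer(1), "to"),
      order = vapply(parsed$bonds, `[[`, integer(1), "order"),
      aromatic = FALSE
    )
  } else {
    tibble::tibble(from = integer(), to = integer(), order = integer(),
                   aromatic = logical())
  }
  g <- mol_graph(atoms, bonds, smiles = smiles)
  if (aromaticity) g <- perceive_aromaticity(g)
  g
}
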