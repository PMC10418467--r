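# Independent brute-force oracles. These deliberately avoid the package's
# optimized code paths: explicit loops instead of matrix products, exhaustive
# edge-subset enumeration instead of incremental growth, refit loops instead
# of hat-matrix identities.

# Charge index G_k by elementwise loops.
oracle_gk <- function(g, k, valence = FALSE,
                      weights = electronegativity_weights()) {
  A <- g$adjacency
  D <- g$distances
  n <- nrow(A)
  if (valence) diag(A) <- weights[g$atoms$element]
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- 0
      for (l in seq_len(n)) {
        if (l != j && D[l, j] > 0) s <- s + A[i, l] / D[l, j]^2
      }
      M[i, j] <- s
    }
  }
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (D[i, j] == k) tot <- tot + abs(M[i, j] - M[j, i])
    }
  }
  tot
}

# Chi index by exhaustive combn over edge subsets.
oracle_chi <- function(g, k, type, valence = FALSE) {
  delta <- if (valence) {
    ifelse(g$atoms$Z <= 10, g$atoms$Zv - g$atoms$implicit_h,
           (g$atoms$Zv - g$atoms$implicit_h) /
             (g$atoms$Z - g$atoms$Zv - 1))
  } else {
    rowSums(g$adjacency)
  }
  if (k == 0) return(sum(1 / sqrt(delta)))
  m <- nrow(g$bonds)
  if (m < k) return(0)
  total <- 0
  for (idx in utils::combn(m, k, simplify = FALSE)) {
    atoms <- sort(unique(c(g$bonds$from[idx], g$bonds$to[idx])))
    # connectivity of the edge-induced subgraph
    sub <- igraph::graph_from_edgelist(
      cbind(match(g$bonds$from[idx], atoms),
            match(g$bonds$to[idx], atoms)),
      directed = FALSE
    )
    if (!igraph::is_connected(sub)) next
    deg <- igraph::degree(sub)
    stype <- if (k >= length(atoms)) {
      "cycle"
    } else if (max(deg) <= 2) {
      "path"
    } else if (!any(deg == 2)) {
      "cluster"
    } else {
      "path-cluster"
    }
    if (stype == type) total <- total + 1 / sqrt(prod(delta[atoms]))
  }
  total
}

# Shortest paths by repeated matrix powering.
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  P <- diag(n)
  for (k in seq_len(n)) {
    P <- P %*% A
    D[P > 0 & is.infinite(D)] <- k
  }
  D
}

# Leave-one-out Q^2 by naive refitting.
oracle_loo_q2 <- function(data, response, predictors) {
  n <- nrow(data)
  fml <- stats::reformulate(sprintf("`%s`", predictors),
                            response = sprintf("`%s`", response))
  press <- 0
  y <- data[[response]]
  for (i in seq_len(n)) {
    fit <- stats::lm(fml, data = data[-i, ])
    press <- press + unname(y[i] - stats::predict(fit, data[i, ]))^2
  }
  1 - press / sum((y - mean(y))^2)
}

# Wilks' lambda by SSCP determinant ratio.
oracle_wilks <- function(X, labels) {
  X <- as.matrix(X)
  center <- function(M) sweep(M, 2, colMeans(M))
  W <- Reduce(`+`, lapply(unique(labels), function(l) {
    crossprod(center(X[labels == l, , drop = FALSE]))
  }))
  det(W) / det(crossprod(center(X)))
}

# Printed reference values of the study table (discriminant scores and
# regression predictions), used by pipeline-level checks.
table1_reference <- function() {
  tibble::tibble(
    id = c("5", "12", "13a", "15a", "16a", "17a", "23a", "23b", "23d",
           "24a", "24b", "24c", "24d", "25c", "25d", "28d", "31d"),
    df = c(3.743, -2.443, 1.586, -0.922, -2.225, 0.024, -3.163, -2.123,
           -1.255, -2.431, -1.527, -0.338, -0.338, 2.299, 2.299, 2.886,
           3.931),
    pred_class = c("A", "I", "A", "I", "I", "NC", "I", "I", "I", "I", "I",
                   "I", "I", "A", "A", "A", "A"),
    pic50_pred = c(5.033, 3.258, 5.620, 5.147, 4.180, 4.536, 3.142, 4.199,
                   3.843, 4.932, 4.673, 4.314, 5.244, 6.795, 7.688, 8.352,
                   8.612)
  )
}

eq2_predictors <- function() c("JGI4", "GGI7", "Mv", "X0v")
eq1_predictors <- function() c("nDB", "nN", "GGI9", "JGI4")
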