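## Independent oracles. Deliberately brute-force / closed-form; they never
## call the code paths they check.

## all basic solutions of max obj.v s.t. S v = rhs, lb <= v <= ub,
## by enumerating bases of the standard-form system (vertex enumeration)
oracle_lp_vertices <- function(obj, S, lb, ub, rhs = NULL) {
  S <- as.matrix(S)
  n <- ncol(S); m <- nrow(S)
  if (is.null(rhs)) rhs <- numeric(m)
  A <- rbind(cbind(S, matrix(0, m, n)), cbind(diag(n), diag(n)))
  b <- c(rhs - S %*% lb, ub - lb)
  N <- 2L * n; M <- m + n
  verts <- list()
  for (cols in utils::combn(N, M, simplify = FALSE)) {
    B <- A[, cols, drop = FALSE]
    d <- determinant(B, logarithm = FALSE)
    if (abs(d$modulus * d$sign) < 1e-10) next
    z <- solve(B, b)
    if (any(z < -1e-9)) next
    full <- numeric(N); full[cols] <- z
    verts[[length(verts) + 1L]] <- full[seq_len(n)] + lb
  }
  if (!length(verts)) return(list(feasible = FALSE))
  vals <- vapply(verts, function(v) sum(obj * v), 0)
  best <- max(vals)
  list(feasible = TRUE, objective = best,
       optima = verts[vals > best - 1e-8],
       vertices = verts)
}

## exact two-sided Mann-Whitney p by exhaustive enumeration of all
## C(n1+n2, n1) group labelings (permutation distribution of U)
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  U_of <- function(ix) {
    a <- pooled[ix]; b <- pooled[-ix]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  obs <- U_of(seq_len(n1))
  Us <- vapply(utils::combn(length(pooled), n1, simplify = FALSE), U_of, 0)
  min(1, 2 * min(mean(Us <= obs + 1e-12), mean(Us >= obs - 1e-12)))
}

## brute-force |r| > threshold Pearson edge filter
oracle_edge_set <- function(mat, threshold) {
  mets <- colnames(mat)
  out <- character(0)
  for (i in seq_len(ncol(mat) - 1)) {
    for (j in seq(i + 1, ncol(mat))) {
      r <- cor(mat[, i], mat[, j])
      if (abs(r) > threshold)
        out <- c(out, paste(mets[i], mets[j], sep = "~"))
    }
  }
  sort(out)
}

## dense eigendecomposition centrality, per connected component,
## normalized max = 1 (mirrors the documented contract, not the code)
oracle_centrality <- function(nodes, edges) {
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges)))
    A[edges$met_a[k], edges$met_b[k]] <-
      A[edges$met_b[k], edges$met_a[k]] <- abs(edges$r[k])
  ## components via matrix powers of the reachability pattern
  reach <- (A > 0) | diag(TRUE, nrow(A))
  for (i in seq_len(nrow(A))) reach <- (reach %*% reach) > 0
  comp <- match(apply(reach, 1, paste, collapse = ""),
                unique(apply(reach, 1, paste, collapse = "")))
  scores <- setNames(numeric(length(nodes)), nodes)
  for (cid in unique(comp)) {
    ix <- which(comp == cid)
    if (length(ix) == 1) { scores[ix] <- 1; next }
    ev <- eigen(A[ix, ix], symmetric = TRUE)
    v <- abs(ev$vectors[, which.max(ev$values)])
    scores[ix] <- v / max(v)
  }
  scores
}

## spreadsheet-style delta-delta-Ct recomputation
oracle_ddct <- function(ct_target, ct_reference, group, control) {
  dct <- ct_target - ct_reference
  ctrl_mean <- sum(dct[group == control]) / sum(group == control)
  2^(-(dct - ctrl_mean))
}
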