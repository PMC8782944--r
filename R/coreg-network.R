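#' Default metabolite functional class mapping
#'
#' Mirrors the panel groupings used for tissue metabolite profiles:
#' redox/energetics, TCA cycle, carbohydrate, lipid and amino acid
#' metabolism. Editable: pass any `metabolite, class` data.frame to
#' [build_coreg_network()].
#'
#' @return data.frame with columns metabolite, class.
#' @export
default_metabolite_classes <- function() {
  cls <- list(
    `redox/energetics` = c("ATP", "ADP", "AMP", "PCr", "creatine", "NAD",
                           "NADH", "TAN", "PCr_ATP", "NAD_NADH"),
    TCA = c("succinate", "fumarate", "citrate", "malate",
            "succinate_fumarate"),
    carbohydrate = c("glucose", "glycogen", "lactate"),
    lipid = c("acetate", "acetylcarnitine", "carnitine", "choline",
              "phosphocholine"),
    `amino acid` = c("glycine", "alanine", "valine", "leucine",
                     "isoleucine", "glutamine", "glutamate", "aspartate",
                     "taurine"))
  data.frame(metabolite = unlist(cls, use.names = FALSE),
             class = rep(names(cls), lengths(cls)), row.names = NULL)
}

#' Build a metabolite co-regulation network
#'
#' Nodes are the significantly altered metabolites; an edge joins a pair
#' when the absolute Pearson correlation of their concentrations across
#' samples exceeds the threshold (strictly; default 0.7). Correlations
#' use pairwise-complete observations; pairs with fewer than 3 complete
#' samples are skipped and logged. Nodes left without any retained edge
#' are dropped from the graph ("only the strongly correlated nodes") but
#' reported in the `isolated` field.
#'
#' @param table concentration table (optionally subset to one tissue
#'   first; pass `tissue` to subset here).
#' @param significant character vector of significant metabolite names.
#' @param threshold absolute-correlation threshold in (0, 1].
#' @param tissue optional tissue to subset to before correlating.
#' @param classes metabolite class mapping data.frame.
#' @return object of class "coreg_network": list(nodes = data.frame
#'   (metabolite, class, centrality), edges = data.frame (met_a, met_b,
#'   r), isolated = character, threshold).
#' @export
build_coreg_network <- function(table, significant, threshold = 0.7,
                                tissue = NULL,
                                classes = default_metabolite_classes()) {
  if (length(significant) < 2L)
    stop("need at least 2 significant metabolites to build a network")
  .check_scalar_num(threshold, "threshold", 0, 1, strict_lower = TRUE)
  dat <- if (is.null(tissue)) table else table[table$tissue == tissue, ]
  missing_m <- setdiff(significant, names(dat))
  if (length(missing_m))
    stop("metabolite(s) absent from table: ",
         paste(missing_m, collapse = ", "))
  mets <- significant
  edges <- NULL
  for (i in seq_len(length(mets) - 1L)) {
    for (j in seq(i + 1L, length(mets))) {
      x <- dat[[mets[i]]]; y <- dat[[mets[j]]]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < 3L) {
        cm_log("coreg_network", "warn",
               sprintf("pair (%s, %s) skipped: %d complete observations",
                       mets[i], mets[j], sum(ok)))
        next
      }
      r <- stats::cor(x[ok], y[ok], method = "pearson")
      if (is.finite(r) && abs(r) > threshold)
        edges <- rbind(edges, data.frame(met_a = mets[i], met_b = mets[j],
                                         r = r))
    }
  }
  if (is.null(edges))
    edges <- data.frame(met_a = character(), met_b = character(),
                        r = numeric())
  connected <- union(edges$met_a, edges$met_b)
  isolated <- setdiff(mets, connected)
  nodes <- data.frame(metabolite = connected,
                      class = classes$class[match(connected,
                                                  classes$metabolite)],
                      stringsAsFactors = FALSE)
  nodes$class[is.na(nodes$class)] <- "unclassified"
  net <- structure(list(nodes = nodes, edges = edges, isolated = isolated,
                        threshold = threshold),
                   class = "coreg_network")
  if (nrow(nodes) > 0)
    net$nodes$centrality <-
      eigenvector_centrality(net)[net$nodes$metabolite]
  else net$nodes$centrality <- numeric(0)
  net
}

#' @export
print.coreg_network <- function(x, ...) {
  cat(sprintf("<coreg_network> %d nodes, %d edges (|r| > %g), %d isolated\n",
              nrow(x$nodes), nrow(x$edges), x$threshold,
              length(x$isolated)))
  invisible(x)
}

## weighted adjacency matrix (|r| weights) of a coreg_network
.adjacency <- function(network) {
  mets <- network$nodes$metabolite
  A <- matrix(0, length(mets), length(mets), dimnames = list(mets, mets))
  for (k in seq_len(nrow(network$edges))) {
    i <- network$edges$met_a[k]; j <- network$edges$met_b[k]
    A[i, j] <- A[j, i] <- abs(network$edges$r[k])
  }
  A
}

## connected components of an adjacency matrix by BFS
.components <- function(A) {
  n <- nrow(A)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(A[v, ] > 0 & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Eigenvector centrality by power iteration
#'
#' Principal eigenvector of the |r|-weighted adjacency, computed by power
#' iteration to a relative tolerance of 1e-10 and normalized so the
#' maximum score is 1. Each connected component is scored independently
#' by the same procedure (so every component's maximum is 1).
#'
#' @param network a coreg_network.
#' @param tol convergence tolerance.
#' @param max_iter iteration cap.
#' @return named numeric vector of scores in \[0, 1\].
#' @export
eigenvector_centrality <- function(network, tol = 1e-10,
                                   max_iter = 100000L) {
  stopifnot(inherits(network, "coreg_network"))
  A <- .adjacency(network)
  if (nrow(A) == 0) stop("empty network")
  comp <- .components(A)
  scores <- stats::setNames(numeric(nrow(A)), rownames(A))
  for (cid in unique(comp)) {
    ix <- which(comp == cid)
    if (length(ix) == 1L) { scores[ix] <- 1; next }
    Ak <- A[ix, ix, drop = FALSE]
    ## positive diagonal shift: preserves eigenvectors, makes the
    ## principal eigenvalue strictly dominant (bipartite components
    ## would otherwise oscillate with period 2)
    Ak <- Ak + diag(max(rowSums(Ak)), nrow(Ak))
    v <- rep(1 / sqrt(length(ix)), length(ix))
    for (it in seq_len(max_iter)) {
      w <- drop(Ak %*% v)
      nw <- sqrt(sum(w^2))
      if (nw == 0) { w <- v; break }
      w <- w / nw
      if (max(abs(w - v)) < tol) { v <- w; break }
      v <- w
    }
    v <- abs(v)
    scores[ix] <- v / max(v)
  }
  scores
}

#' Export / import a co-regulation network as GraphML
#'
#' Node attributes `class` and `centrality`, edge attribute `r`. The
#' export round-trips losslessly through [read_coreg_graphml()].
#'
#' @param network a coreg_network.
#' @param path output file path.
#' @export
write_coreg_graphml <- function(network, path) {
  stopifnot(inherits(network, "coreg_network"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  if (nrow(network$nodes) > 0) {
    g <- igraph::add_vertices(g, nrow(network$nodes),
                              name = network$nodes$metabolite,
                              class = network$nodes$class,
                              centrality = network$nodes$centrality)
    if (nrow(network$edges) > 0)
      g <- igraph::add_edges(
        g, rbind(match(network$edges$met_a, network$nodes$metabolite),
                 match(network$edges$met_b, network$nodes$metabolite)),
        r = network$edges$r)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_coreg_graphml
#' @param threshold threshold recorded on the re-imported network.
#' @return `read_coreg_graphml` returns a coreg_network (without the
#'   isolated-node sidecar, which the format does not carry).
#' @export
read_coreg_graphml <- function(path, threshold = 0.7) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(
    metabolite = igraph::vertex_attr(g, "name"),
    class = igraph::vertex_attr(g, "class"),
    centrality = igraph::vertex_attr(g, "centrality"),
    stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(met_a = el[, 1], met_b = el[, 2],
                      r = if (igraph::ecount(g)) igraph::edge_attr(g, "r")
                          else numeric(0))
  structure(list(nodes = nodes, edges = edges, isolated = character(0),
                 threshold = threshold),
            class = "coreg_network")
}

#' Write the edge list as CSV (`met_a, met_b, r`)
#' @inheritParams write_coreg_graphml
#' @export
write_edge_list <- function(network, path) {
  utils::write.csv(network$edges, path, row.names = FALSE)
  invisible(path)
}
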