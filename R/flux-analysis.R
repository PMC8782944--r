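#' PCA, clustering and readouts over per-sample flux distributions
#'
#' Fluxes are standardized per reaction (zero-variance reactions dropped
#' and logged), decomposed by SVD-based PCA, and clustered by
#' agglomerative hierarchical clustering (Ward linkage on Euclidean
#' distances). Readouts: per-sample ROS flux (summed flux through
#' reactions tagged `ros_producing`) and lactate efflux (flux of the
#' lactate exchange reaction).
#'
#' @param distributions list of flux_distribution over the same reaction
#'   set (>= 3 samples, >= 2 per group).
#' @param groups named character vector sample_id -> group label.
#' @param k number of clusters to cut the dendrogram into (default:
#'   number of distinct groups).
#' @return object of class "flux_analysis": list(scores, loadings, sdev,
#'   hclust, dendrogram_order, cluster_labels, ros_flux, lactate_efflux,
#'   dropped_reactions, groups).
#' @export
analyze_flux_distributions <- function(distributions, groups, k = NULL) {
  ok <- vapply(distributions, function(d) d$status == "optimal", TRUE)
  if (!all(ok)) {
    cm_log("flux_model", "warn",
           sprintf("%d non-optimal distribution(s) dropped", sum(!ok)))
    distributions <- distributions[ok]
  }
  if (length(distributions) < 3L) stop("need at least 3 samples")
  rxn <- names(distributions[[1]]$flux)
  same <- vapply(distributions, function(d)
    identical(names(d$flux), rxn), TRUE)
  if (!all(same)) stop("mismatched reaction sets across distributions")
  ids <- vapply(distributions, `[[`, "", "sample_id")
  grp <- groups[ids]
  if (any(is.na(grp))) stop("group label missing for some sample(s)")
  if (any(table(grp) < 2L)) stop("need >= 2 samples per group")
  X <- do.call(rbind, lapply(distributions, `[[`, "flux"))
  rownames(X) <- ids
  sds <- apply(X, 2, stats::sd)
  drop <- sds == 0
  if (any(drop))
    cm_log("flux_model", "info",
           sprintf("%d zero-variance reaction(s) dropped from PCA",
                   sum(drop)))
  Xs <- scale(X[, !drop, drop = FALSE])
  pca <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  hc <- stats::hclust(stats::dist(Xs), method = "ward.D2")
  if (is.null(k)) k <- length(unique(grp))
  labels <- stats::cutree(hc, k = max(k, 1L))
  net <- NULL
  ros <- lact <- stats::setNames(rep(NA_real_, length(ids)), ids)
  ## readouts need the network's tags; recover them from the problem if
  ## attached, else from reaction naming conventions via attributes
  ros_rxns <- attr(distributions, "ros_reactions")
  lact_rxn <- attr(distributions, "lactate_exchange")
  if (!is.null(ros_rxns))
    ros <- rowSums(X[, intersect(ros_rxns, colnames(X)), drop = FALSE])
  if (!is.null(lact_rxn) && lact_rxn %in% colnames(X))
    lact <- X[, lact_rxn]
  structure(list(scores = pca$x, loadings = pca$rotation,
                 sdev = pca$sdev, hclust = hc,
                 dendrogram_order = hc$order,
                 cluster_labels = labels,
                 ros_flux = ros, lactate_efflux = lact,
                 dropped_reactions = colnames(X)[drop],
                 groups = grp),
            class = "flux_analysis")
}

#' Attach readout metadata from a network to a distribution list
#'
#' Marks which reactions feed the ROS readout (tag `ros_producing`) and
#' which exchange carries lactate, so [analyze_flux_distributions()] can
#' compute the readouts without re-threading the network.
#'
#' @param distributions list of flux_distribution.
#' @param network the metabolic_network they were solved on.
#' @return the list, with attributes set.
#' @export
tag_readouts <- function(distributions, network) {
  attr(distributions, "ros_reactions") <-
    reactions_with_tag(network, "ros_producing")
  exch <- reactions_with_tag(network, "exchange")
  em <- vapply(network$reactions, function(r)
    if ("exchange" %in% r$tags) r$exchange_metabolite else NA_character_,
    "")
  lac <- reaction_ids(network)[which(em == "lactate")]
  attr(distributions, "lactate_exchange") <-
    if (length(lac)) lac[1] else NULL
  distributions
}

#' Mean silhouette width of a 1-D embedding
#'
#' Used to ask whether the first principal component separates the two
#' cohorts: positive mean silhouette means samples sit closer to their
#' own group than to the other.
#'
#' @param x numeric vector (e.g. PC1 scores).
#' @param labels group labels, same length.
#' @return mean silhouette width in \[-1, 1\].
#' @export
silhouette_width <- function(x, labels) {
  stopifnot(length(x) == length(labels))
  labels <- as.character(labels)
  s <- vapply(seq_along(x), function(i) {
    same <- labels == labels[i]; same[i] <- FALSE
    if (!any(same)) return(0)
    a <- mean(abs(x[i] - x[same]))
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g)
      mean(abs(x[i] - x[labels == g])), 0))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)
  mean(s)
}

#' Subsystem enrichment of a reaction selection
#'
#' For each subsystem, the hypergeometric upper-tail probability of the
#' observed overlap between the selected reactions and the subsystem,
#' given subsystem size and selection size, with Benjamini-Hochberg
#' adjustment across subsystems.
#'
#' @param selected_reactions character vector of reaction ids (non-empty
#'   subset of the network's reactions).
#' @param network metabolic_network.
#' @param randomized logical; if TRUE return randomized p-values
#'   (`P(X > k) + U * P(X = k)`), which are exactly uniform under the
#'   null -- used to check calibration of the discrete test, not for
#'   reporting.
#' @return data.frame: subsystem, size, overlap, expected, p, p_adj.
#' @export
subsystem_enrichment <- function(selected_reactions, network,
                                 randomized = FALSE) {
  stopifnot(inherits(network, "metabolic_network"))
  if (!length(selected_reactions)) stop("empty reaction selection")
  all_rxn <- reaction_ids(network)
  bad <- setdiff(selected_reactions, all_rxn)
  if (length(bad))
    stop("selection contains unknown reaction(s): ",
         paste(bad, collapse = ", "))
  sub <- subsystems(network)
  N <- length(all_rxn)
  n_sel <- length(selected_reactions)
  out <- do.call(rbind, lapply(unique(sub), function(s) {
    members <- all_rxn[sub == s]
    K <- length(members)
    k <- length(intersect(selected_reactions, members))
    p <- if (randomized) {
      stats::phyper(k, K, N - K, n_sel, lower.tail = FALSE) +
        stats::runif(1) * stats::dhyper(k, K, N - K, n_sel)
    } else {
      stats::phyper(k - 1, K, N - K, n_sel, lower.tail = FALSE)
    }
    data.frame(subsystem = s, size = K, overlap = k,
               expected = n_sel * K / N, p = p)
  }))
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), ]
}

#' Write per-sample fluxes as a long CSV (`sample_id, reaction_id, flux`)
#'
#' @param distributions list of flux_distribution.
#' @param path output path.
#' @export
write_flux_csv <- function(distributions, path) {
  rows <- do.call(rbind, lapply(distributions, function(d) {
    if (is.null(d$flux)) return(NULL)
    data.frame(sample_id = d$sample_id, reaction_id = names(d$flux),
               flux = unname(d$flux))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
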