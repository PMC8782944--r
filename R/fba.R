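#' Constrain exchange bounds from measured metabolite levels
#'
#' NMR gives relative pool sizes, not fluxes, so measured levels enter
#' the optimization as proportional caps on nutrient availability: for
#' each measured metabolite with a flagged exchange reaction, the upper
#' bound of that exchange is set to `v_max * c_sample / c_reference`,
#' where the reference is the control-group mean. Internal (enzymatic)
#' reactions keep their default wide bounds -- enzymatic activities are
#' deliberately unconstrained -- and unmeasured exchanges keep their
#' defaults.
#'
#' @param network metabolic_network.
#' @param sample named vector of measured concentrations.
#' @param reference named vector of control-group mean concentrations
#'   (all > 0).
#' @param v_max uptake bound assigned at ratio 1.
#' @return object of class "flux_problem": list(S, lb, ub, objective
#'   (reaction id of the ATP demand), network, sample_id).
#' @export
constrain_from_concentrations <- function(network, sample, reference,
                                          v_max = 10) {
  stopifnot(inherits(network, "metabolic_network"))
  .check_scalar_num(v_max, "v_max", 0, strict_lower = TRUE)
  common <- intersect(names(sample), names(reference))
  if (any(reference[common] <= 0))
    stop("reference concentrations must be > 0")
  exch_map <- vapply(network$reactions, function(r)
    if ("exchange" %in% r$tags) r$exchange_metabolite else NA_character_,
    "")
  lb <- vapply(network$reactions, `[[`, 0, "lb")
  ub <- vapply(network$reactions, `[[`, 0, "ub")
  names(lb) <- names(ub) <- reaction_ids(network)
  for (m in common) {
    j <- which(exch_map == m)
    if (!length(j)) {
      cm_log("flux_model", "warn",
             sprintf("measured metabolite '%s' has no mapped exchange; skipped",
                     m))
      next
    }
    ub[j] <- v_max * sample[[m]] / reference[[m]]
    lb[j] <- pmin(lb[j], ub[j])
  }
  unmapped <- setdiff(names(sample), names(reference))
  if (length(unmapped))
    cm_log("flux_model", "info",
           sprintf("%d sample metabolite(s) missing from reference ignored",
                   length(unmapped)))
  structure(list(S = stoich_matrix(network), lb = lb, ub = ub,
                 objective = reactions_with_tag(network, "atp_demand"),
                 network = network, sample_id = NA_character_),
            class = "flux_problem")
}

#' Build an unconstrained flux problem (default bounds)
#' @param network metabolic_network.
#' @return flux_problem.
#' @export
flux_problem <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  lb <- vapply(network$reactions, `[[`, 0, "lb")
  ub <- vapply(network$reactions, `[[`, 0, "ub")
  names(lb) <- names(ub) <- reaction_ids(network)
  structure(list(S = stoich_matrix(network), lb = lb, ub = ub,
                 objective = reactions_with_tag(network, "atp_demand"),
                 network = network, sample_id = NA_character_),
            class = "flux_problem")
}

#' Flux balance analysis with a parsimonious secondary step
#'
#' Maximizes the flux through the designated ATP-demand reaction subject
#' to steady state (`S v = 0`) and the bounds. Linear programs are
#' degenerate in general, so among the optima a secondary minimization
#' of total absolute flux (parsimonious FBA) selects a unique, solver-
#' independent representative: reversible reactions are split into
#' forward/backward parts and the summed parts are minimized with the
#' objective flux pinned at its optimum.
#'
#' @param problem a flux_problem.
#' @param parsimonious logical; skip the secondary step if FALSE.
#' @return object of class "flux_distribution": list(sample_id, flux
#'   (named), objective, status). On infeasible/unbounded problems the
#'   flux vector is NULL and only the status is set.
#' @export
solve_fba <- function(problem, parsimonious = TRUE) {
  stopifnot(inherits(problem, "flux_problem"))
  n <- ncol(problem$S)
  obj <- numeric(n)
  obj[match(problem$objective, colnames(problem$S))] <- 1
  res <- solve_lp(obj, problem$S, problem$lb, problem$ub, maximize = TRUE)
  if (res$status != "optimal")
    return(structure(list(sample_id = problem$sample_id, flux = NULL,
                          objective = if (res$status == "unbounded") Inf
                                      else NA_real_,
                          status = res$status),
                     class = "flux_distribution"))
  v <- res$v
  if (parsimonious) {
    ## split v = p - q over doubled variables; minimize 1'(p+q) with the
    ## ATP objective pinned to its optimum
    S2 <- cbind(problem$S, -problem$S)
    S2 <- rbind(S2, c(obj, -obj))               # pin objective row
    lb2 <- rep(0, 2 * n)
    ub2 <- c(pmax(problem$ub, 0), pmax(-problem$lb, 0))
    rhs <- c(numeric(nrow(problem$S)), res$objective)
    res2 <- solve_lp(rep(1, 2 * n), S2, lb2, ub2, rhs = rhs,
                     maximize = FALSE)
    if (res2$status == "optimal") {
      v <- res2$v[seq_len(n)] - res2$v[n + seq_len(n)]
    } else {
      cm_log("flux_model", "warn",
             "parsimonious step failed; returning primary optimum",
             status = res2$status)
    }
  }
  names(v) <- colnames(problem$S)
  structure(list(sample_id = problem$sample_id, flux = v,
                 objective = res$objective, status = "optimal"),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("<flux_distribution> status %s | ATP provision %.6g\n",
              x$status, x$objective))
  invisible(x)
}

#' Run constrained FBA for every sample of a concentration table
#'
#' The reference is the control-group mean of each measured metabolite
#' within the chosen tissue; one LP is solved per sample.
#'
#' @param network metabolic_network.
#' @param table concentration table.
#' @param tissue tissue to model.
#' @param reference_group control group label (reference = its means).
#' @param v_max uptake scale (see [constrain_from_concentrations()]).
#' @param parsimonious passed to [solve_fba()].
#' @return list of flux_distribution, one per sample, named by
#'   sample_id.
#' @export
fba_cohort <- function(network, table, tissue = "maternal_heart",
                       reference_group = "sham", v_max = 10,
                       parsimonious = TRUE) {
  dat <- table[table$tissue == tissue, , drop = FALSE]
  if (!nrow(dat)) stop("no samples for tissue '", tissue, "'")
  if (!reference_group %in% dat$group)
    stop("reference group '", reference_group, "' absent")
  meta_cols <- c("sample_id", "tissue", "group", "wet_weight_g")
  mets <- setdiff(names(dat)[vapply(dat, is.numeric, TRUE)], meta_cols)
  ref <- colMeans(dat[dat$group == reference_group, mets, drop = FALSE])
  out <- list()
  for (i in seq_len(nrow(dat))) {
    smp <- unlist(dat[i, mets])
    prob <- constrain_from_concentrations(network, smp, ref, v_max)
    prob$sample_id <- dat$sample_id[i]
    out[[dat$sample_id[i]]] <- solve_fba(prob, parsimonious)
  }
  out
}
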