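#' Default baseline tissue metabolite concentrations
#'
#' Plausible resting-tissue pool sizes in umol per gram wet weight for the
#' metabolite panel quantified in heart and placenta extracts. Glycogen is
#' expressed in mobile-1H glucosyl-equivalent units and is treated like any
#' other column downstream.
#'
#' @return named numeric vector, umol/g wet weight.
#' @export
default_baselines <- function() {
  c(ATP = 5, ADP = 1.5, AMP = 0.5, PCr = 8, creatine = 10,
    NAD = 0.8, NADH = 0.15,
    succinate = 0.5, fumarate = 0.1, citrate = 0.3, malate = 0.4,
    glucose = 2, glycogen = 10, lactate = 4,
    glycine = 1.5, alanine = 2, valine = 0.3, leucine = 0.3,
    isoleucine = 0.15, glutamine = 5, glutamate = 6, aspartate = 2,
    taurine = 30, acetate = 0.5, acetylcarnitine = 0.8, carnitine = 1,
    choline = 0.3, phosphocholine = 0.8)
}

#' Default group-effect table for the sham vs RUPP design
#'
#' Encodes the direction of every reported significant tissue change as a
#' fold change (RUPP mean over sham mean). The only printed magnitude is
#' the 51% reduction of fetal myocardial glucose (fold 0.49); all other
#' effects use neutral defaults of 1.5 (up) or 0.67 (down).
#'
#' @param up fold change used for increased metabolites (default 1.5).
#' @param down fold change used for decreased metabolites (default 0.67).
#' @return data.frame with columns metabolite, tissue, fold_change.
#' @export
default_effects <- function(up = 1.5, down = 0.67) {
  rbind(
    data.frame(metabolite = c("NADH", "glucose", "glycogen", "acetate",
                              "acetylcarnitine", "succinate", "aspartate"),
               tissue = "maternal_heart",
               fold_change = c(up, up, up, up, up, down, down)),
    data.frame(metabolite = c("ATP", "glycogen", "carnitine", "choline",
                              "phosphocholine", "valine"),
               tissue = "placenta",
               fold_change = c(up, up, up, up, up, down)),
    data.frame(metabolite = c("glucose", "glycine"),
               tissue = "fetal_heart",
               fold_change = c(0.49, down))
  )
}

#' Construct and validate a two-group study design
#'
#' @param tissues character vector of tissue labels.
#' @param groups character vector of group labels, control first.
#' @param n_per_group named integer vector (one entry per tissue) or a
#'   single integer recycled over tissues; samples per tissue x group.
#' @param baseline_means named numeric vector of metabolite baselines
#'   (umol/g wet weight), all positive.
#' @param cv coefficient of variation of the log-normal biological noise.
#' @param effects data.frame with columns metabolite, tissue, fold_change.
#' @param seed integer seed for the generator.
#' @param wet_weight_range length-2 positive range (g) for sampled tissue
#'   wet weights.
#' @return object of class "study_design".
#' @export
study_design <- function(tissues = c("maternal_heart", "placenta", "fetal_heart"),
                         groups = c("sham", "rupp"),
                         n_per_group = c(maternal_heart = 5L, placenta = 5L,
                                         fetal_heart = 4L),
                         baseline_means = default_baselines(),
                         cv = 0.15,
                         effects = default_effects(),
                         seed = 1L,
                         wet_weight_range = c(0.08, 0.12)) {
  if (anyDuplicated(groups)) stop("group labels must be unique")
  if (length(groups) != 2L) stop("exactly two groups (control first) required")
  if (length(n_per_group) == 1L)
    n_per_group <- stats::setNames(rep(as.integer(n_per_group),
                                       length(tissues)), tissues)
  if (!all(tissues %in% names(n_per_group)))
    stop("n_per_group must name every tissue")
  if (any(n_per_group < 2L)) stop("n_per_group must be >= 2")
  .check_scalar_num(cv, "cv", 0, strict_lower = TRUE)
  if (is.null(names(baseline_means)) || any(baseline_means <= 0))
    stop("baseline_means must be a named vector of positive concentrations")
  if (nrow(effects) > 0) {
    stopifnot(all(c("metabolite", "tissue", "fold_change") %in% names(effects)))
    if (any(effects$fold_change <= 0)) stop("fold_change must be > 0")
    unknown <- setdiff(effects$metabolite, names(baseline_means))
    if (length(unknown))
      stop("effects reference unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    drop_t <- !(effects$tissue %in% tissues)
    if (any(drop_t)) {
      ## a design restricted to fewer tissues keeps only its own effects
      cm_log("synthetic_data", "info",
             sprintf("%d effect(s) for tissues outside the design dropped",
                     sum(drop_t)))
      effects <- effects[!drop_t, , drop = FALSE]
    }
  }
  stopifnot(length(wet_weight_range) == 2L, all(wet_weight_range > 0),
            diff(wet_weight_range) >= 0)
  structure(list(tissues = tissues, groups = groups,
                 n_per_group = n_per_group,
                 baseline_means = baseline_means, cv = cv,
                 effects = effects, seed = as.integer(seed),
                 wet_weight_range = wet_weight_range),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", paste(x$groups, collapse = " vs "), "\n")
  cat("  tissues:", paste(sprintf("%s (n=%d/group)", x$tissues,
                                  x$n_per_group[x$tissues]),
                          collapse = ", "), "\n")
  cat("  metabolites:", length(x$baseline_means),
      "| cv:", x$cv, "| effects:", nrow(x$effects), "\n")
  invisible(x)
}

#' Generate a synthetic concentration table
#'
#' Draws one row per sample. Concentrations are log-normal with mean
#' baseline x fold_change (fold 1 when no effect applies to that
#' metabolite/tissue) and the configured coefficient of variation; this
#' keeps every draw strictly positive and right-skewed, the standard
#' noise model for metabolite pools. Wet weights are uniform in the
#' configured range. Identical seed gives an identical table.
#'
#' @param design a [study_design()] object.
#' @return data.frame: sample_id, tissue, group, wet_weight_g, then one
#'   column per metabolite (class "concentration_table").
#' @export
generate_concentration_table <- function(design) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  mets <- names(design$baseline_means)
  ## log-normal with arithmetic mean mu and CV c:
  ## sdlog^2 = log(1+c^2), meanlog = log(mu) - sdlog^2/2
  sdlog <- sqrt(log(1 + design$cv^2))
  rows <- list()
  for (tis in design$tissues) {
    n <- design$n_per_group[[tis]]
    for (grp in design$groups) {
      fold <- stats::setNames(rep(1, length(mets)), mets)
      if (grp != design$groups[1] && nrow(design$effects) > 0) {
        eff <- design$effects[design$effects$tissue == tis, , drop = FALSE]
        fold[eff$metabolite] <- eff$fold_change
      }
      mu <- design$baseline_means * fold
      conc <- matrix(stats::rlnorm(n * length(mets),
                                   meanlog = rep(log(mu) - sdlog^2 / 2,
                                                 each = n),
                                   sdlog = sdlog),
                     nrow = n, ncol = length(mets),
                     dimnames = list(NULL, mets))
      ww <- stats::runif(n, design$wet_weight_range[1],
                         design$wet_weight_range[2])
      rows[[paste(tis, grp)]] <- data.frame(
        sample_id = sprintf("%s_%s_%02d", tis, grp, seq_len(n)),
        tissue = tis, group = grp, wet_weight_g = ww,
        conc, check.names = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("concentration_table", "data.frame")
  out
}
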