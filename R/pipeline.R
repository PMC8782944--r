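#' Read / write a concentration table CSV
#'
#' Schema: `sample_id, tissue, group, wet_weight_g, <metabolite>...`.
#' Missing values are empty fields, never sentinel numbers. Round trips
#' are lossless. Schema violations are reported with coordinates.
#'
#' @param path CSV path.
#' @param groups optional vector of allowed group labels; labels outside
#'   it are a schema error.
#' @return concentration_table data.frame.
#' @export
read_table <- function(path, groups = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "group", "wet_weight_g")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  dup <- tab$sample_id[duplicated(tab$sample_id)]
  if (length(dup))
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  if (!is.null(groups)) {
    bad <- setdiff(unique(tab$group), groups)
    if (length(bad))
      stop("unknown group label(s): ", paste(bad, collapse = ", "))
  }
  mets <- setdiff(names(tab), need)
  for (m in mets) {
    v <- tab[[m]]
    neg <- which(!is.na(v) & v < 0)
    if (length(neg))
      stop(sprintf("negative concentration at row %d, column '%s'",
                   neg[1], m))
  }
  class(tab) <- c("concentration_table", "data.frame")
  tab
}

#' @rdname read_table
#' @param table concentration table to write.
#' @export
write_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

## default values echoed into every resolved configuration
.config_defaults <- list(alpha = 0.05, threshold = 0.7, lb_hz = 0.3,
                         v_max = 10, reference_group = NULL,
                         tissue = "maternal_heart", seed = 1L,
                         stages = c("simulate", "stats", "network", "fba"))

#' Validate a pipeline run configuration
#'
#' Accepts a JSON file path or an R list. Defaults (alpha 0.05, network
#' threshold 0.7, line broadening 0.3 Hz, v_max 10) are filled in and
#' echoed to the log; all problems are aggregated into one validation
#' report. The resolved configuration re-validates to itself
#' (idempotence).
#'
#' @param config path to a JSON config file, or a named list.
#' @return validated config list of class "run_config".
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  for (nm in names(.config_defaults))
    if (is.null(config[[nm]])) config[[nm]] <- .config_defaults[[nm]]
  problems <- character(0)
  if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha >= 1)
    problems <- c(problems, "alpha must be in (0, 1)")
  if (!is.numeric(config$threshold) || config$threshold <= 0 ||
      config$threshold > 1)
    problems <- c(problems, "threshold must be in (0, 1]")
  if (!is.numeric(config$lb_hz) || config$lb_hz < 0)
    problems <- c(problems, "lb_hz must be >= 0")
  if (!is.numeric(config$v_max) || config$v_max <= 0)
    problems <- c(problems, "v_max must be > 0")
  if (!is.null(config$table) && !file.exists(config$table))
    problems <- c(problems, paste0("table file not found: ", config$table))
  if (!is.null(config$network_path) && !file.exists(config$network_path))
    problems <- c(problems,
                  paste0("network file not found: ", config$network_path))
  unknown_stage <- setdiff(config$stages, .config_defaults$stages)
  if (length(unknown_stage))
    problems <- c(problems, paste0("unknown stage(s): ",
                                   paste(unknown_stage, collapse = ", ")))
  if (length(problems))
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  cm_log("pipeline", "info", "configuration validated",
         alpha = config$alpha, threshold = config$threshold,
         lb_hz = config$lb_hz, v_max = config$v_max, seed = config$seed)
  structure(config, class = c("run_config", "list"))
}

#' Serialize a resolved configuration back to JSON
#' @param config run_config.
#' @param path output path.
#' @export
dump_config <- function(config, path) {
  jsonlite::write_json(unclass(config)[order(names(unclass(config)))],
                       path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages in dependency order: `simulate` (or load the configured
#' table), `stats` (per-tissue routed comparisons), `network`
#' (co-regulation graph of the significant metabolites in the configured
#' tissue), `fba` (per-sample constrained flux optimization, PCA,
#' clustering, enrichment). Every output file enters a manifest with its
#' MD5 hash; the same config and seed yield identical hashes. A stage
#' failure is recorded in the manifest and later stages are skipped;
#' prior outputs are preserved.
#'
#' @param config run_config (or path/list accepted by
#'   [validate_config()]).
#' @param out_dir output directory (created if needed).
#' @return manifest data.frame: stage, file, md5, status.
#' @export
run_pipeline <- function(config, out_dir = config$out_dir) {
  config <- validate_config(config)
  if (is.null(out_dir)) stop("out_dir required (config$out_dir or argument)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(stage = character(), file = character(),
                         md5 = character(), status = character())
  note <- function(stage, file, status = "ok") {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, file = basename(file),
      md5 = if (file.exists(file)) unname(tools::md5sum(file)) else NA,
      status = status))
  }
  failed <- FALSE
  run_stage <- function(stage, fn) {
    if (failed || !(stage %in% config$stages)) return(invisible(NULL))
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      cm_log("pipeline", "error", conditionMessage(res), stage = stage)
      note(stage, file.path(out_dir, "FAILED"), conditionMessage(res))
      failed <<- TRUE
      NULL
    } else res
  }

  table <- NULL
  run_stage("simulate", function() {
    if (!is.null(config$table)) {
      table <<- read_table(config$table)
    } else {
      design <- study_design(seed = derive_seed(config$seed, "simulate"))
      table <<- generate_concentration_table(design)
    }
    f <- file.path(out_dir, "concentration_table.csv")
    write_table(table, f)
    note("simulate", f)
  })

  stats_res <- NULL
  run_stage("stats", function() {
    per_tissue <- lapply(unique(table$tissue), function(tis)
      compare_all(derived_indices(table), tissue = tis,
                  alpha = config$alpha))
    stats_res <<- do.call(rbind, per_tissue)
    f <- file.path(out_dir, "group_stats.csv")
    utils::write.csv(stats_res, f, row.names = FALSE)
    note("stats", f)
  })

  run_stage("network", function() {
    sig <- stats_res$metabolite[stats_res$significant &
                                  stats_res$tissue == config$tissue]
    if (length(sig) < 2L) {
      cm_log("pipeline", "warn",
             "fewer than 2 significant metabolites; network skipped")
      return(invisible(NULL))
    }
    net <- build_coreg_network(derived_indices(table), sig,
                               threshold = config$threshold,
                               tissue = config$tissue)
    f1 <- file.path(out_dir, "coreg_network.graphml")
    f2 <- file.path(out_dir, "coreg_edges.csv")
    write_coreg_graphml(net, f1); write_edge_list(net, f2)
    note("network", f1); note("network", f2)
  })

  run_stage("fba", function() {
    net <- if (!is.null(config$network_path)) {
      if (grepl("\\.xml$|\\.sbml$", config$network_path))
        read_network_sbml(config$network_path)
      else load_network(config$network_path)
    } else cardiomyocyte_network()
    ref_grp <- if (is.null(config$reference_group))
      table$group[1] else config$reference_group
    dists <- fba_cohort(net, table, tissue = config$tissue,
                        reference_group = ref_grp,
                        v_max = config$v_max)
    f1 <- file.path(out_dir, "fluxes.csv")
    write_flux_csv(dists, f1); note("fba", f1)
    groups <- stats::setNames(table$group, table$sample_id)
    ana <- analyze_flux_distributions(tag_readouts(dists, net), groups)
    f2 <- file.path(out_dir, "pca_scores.csv")
    utils::write.csv(data.frame(sample_id = rownames(ana$scores),
                                group = ana$groups,
                                cluster = ana$cluster_labels,
                                ana$scores), f2, row.names = FALSE)
    note("fba", f2)
    ## enrich the reactions loading most on PC1 (top quartile)
    l1 <- abs(ana$loadings[, 1])
    sel <- names(l1)[l1 >= stats::quantile(l1, 0.75)]
    enr <- subsystem_enrichment(sel, net)
    f3 <- file.path(out_dir, "enrichment.csv")
    utils::write.csv(enr, f3, row.names = FALSE)
    note("fba", f3)
  })

  fm <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, fm, row.names = FALSE)
  manifest
}
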