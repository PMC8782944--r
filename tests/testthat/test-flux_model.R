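test_that("network validation enforces the schema", {
  mets <- data.frame(id = "a_c", name = "a", compartment = "cytosol")
  demand <- list(id = "DM", stoich = c(a_c = -1), reversible = FALSE,
                 lb = 0, ub = 10, subsystem = "s", tags = "atp_demand",
                 exchange_metabolite = NA_character_)
  expect_error(metabolic_network(
    data.frame(id = "a_c", name = "a", compartment = "nucleus"),
    list(demand)), "nucleus")
  bad_ref <- demand; bad_ref$stoich <- c(ghost = -1)
  expect_error(metabolic_network(mets, list(bad_ref)), "ghost")
  expect_error(metabolic_network(mets, list()), "atp_demand")
  two <- demand; two$id <- "DM2"
  expect_error(metabolic_network(mets, list(demand, two)), "found 2")
  rev_bad <- demand; rev_bad$id <- "R"; rev_bad$lb <- -1
  rev_bad$tags <- character(0)
  expect_error(metabolic_network(mets, list(demand, rev_bad)),
               "irreversible")
})

test_that("bundled reduced cardiomyocyte network loads and is consistent", {
  net <- cardiomyocyte_network()
  expect_gte(length(unique(subsystems(net))), 5)
  expect_length(reactions_with_tag(net, "atp_demand"), 1)
  expect_gte(length(reactions_with_tag(net, "exchange")), 5)
  expect_setequal(unique(net$metabolites$compartment),
                  c("extracellular", "cytosol", "mitochondria",
                    "microsome", "lysosome"))
  sol <- solve_fba(flux_problem(net))
  expect_equal(sol$status, "optimal")
  expect_gt(sol$objective, 0)
  expect_lt(max(abs(stoich_matrix(net) %*% sol$flux)), 1e-9)
})

test_that("JSON and SBML representations round trip to the same network", {
  net <- cardiomyocyte_network()
  pj <- withr::local_tempfile(fileext = ".json")
  px <- withr::local_tempfile(fileext = ".xml")
  write_network(net, pj)
  back <- load_network(pj)
  expect_equal(stoich_matrix(back), stoich_matrix(net))
  write_network_sbml(net, px)
  back2 <- read_network_sbml(px)
  expect_equal(stoich_matrix(back2)[rownames(stoich_matrix(net)),
                                    colnames(stoich_matrix(net))],
               stoich_matrix(net))
  expect_equal(vapply(back2$reactions, `[[`, 0, "ub"),
               vapply(net$reactions, `[[`, 0, "ub"))
  expect_identical(sort(subsystems(back2)), sort(subsystems(net)))
  expect_setequal(reactions_with_tag(back2, "ros_producing"),
                  reactions_with_tag(net, "ros_producing"))
})

test_that("FBA solves the toy networks to their known optima", {
  expect_equal(solve_fba(flux_problem(generate_toy_network("chain")))$objective,
               20)
  expect_equal(solve_fba(flux_problem(generate_toy_network("blocked")))$objective,
               0)
  branched <- solve_fba(flux_problem(generate_toy_network("branched")))
  expect_equal(branched$objective, 20)
  expect_equal(unname(branched$flux["HIGH"]), 10)
  expect_equal(unname(branched$flux["LOW"]), 0)
})

test_that("FBA objective and support match vertex enumeration", {
  for (kind in c("chain", "branched")) {
    net <- generate_toy_network(kind)
    S <- stoich_matrix(net)
    lb <- vapply(net$reactions, `[[`, 0, "lb")
    ub <- vapply(net$reactions, `[[`, 0, "ub")
    obj <- as.numeric(reaction_ids(net) == "ATP_DEMAND")
    oracle <- oracle_lp_vertices(obj, S, lb, ub)
    sol <- solve_fba(flux_problem(net))
    expect_equal(sol$objective, oracle$objective, tolerance = 1e-9)
    ## parsimonious step picks the minimal-L1 optimal vertex
    l1 <- vapply(oracle$optima, function(v) sum(abs(v)), 0)
    expect_equal(sum(abs(sol$flux)), min(l1), tolerance = 1e-8)
  }
})

test_that("concentration constraints scale uptake bounds proportionally", {
  net <- generate_toy_network("chain")
  ref <- c(substrate = 4)
  p_eq <- constrain_from_concentrations(net, ref, ref, v_max = 7)
  expect_equal(unname(p_eq$ub["UPT"]), 7)
  p_half <- constrain_from_concentrations(net, c(substrate = 2), ref,
                                          v_max = 7)
  expect_equal(unname(p_half$ub["UPT"]), 3.5)
  ## halved substrate halves the optimum on the chain
  expect_equal(solve_fba(p_half)$objective, solve_fba(p_eq)$objective / 2)
  expect_error(constrain_from_concentrations(net, c(substrate = 1),
                                             c(substrate = 0)), "> 0")
  ## unmapped measured metabolite is skipped with a log entry
  cm_get_log(clear = TRUE)
  constrain_from_concentrations(net, c(substrate = 4, unicorn = 1),
                                c(substrate = 4, unicorn = 1))
  expect_true(any(grepl("unicorn", vapply(cm_get_log(), `[[`, "",
                                          "message"))))
})

test_that("optimality, monotonicity and scaling hold on the bundled model", {
  net <- cardiomyocyte_network()
  prob <- flux_problem(net)
  base <- solve_fba(prob, parsimonious = FALSE)
  ## random feasible points never beat the optimum: on the branched toy,
  ## draw 1000 random convex combinations of the polytope's vertices
  toy <- generate_toy_network("branched")
  S <- stoich_matrix(toy)
  lbt <- vapply(toy$reactions, `[[`, 0, "lb")
  ubt <- vapply(toy$reactions, `[[`, 0, "ub")
  objt <- as.numeric(reaction_ids(toy) == "ATP_DEMAND")
  verts <- oracle_lp_vertices(objt, S, lbt, ubt)$vertices
  opt_toy <- solve_fba(flux_problem(toy))$objective
  set.seed(14)
  for (i in seq_len(1000)) {
    w <- stats::rexp(length(verts)); w <- w / sum(w)
    v <- Reduce(`+`, Map(`*`, verts, w))
    expect_lte(sum(objt * v), opt_toy + 1e-9)
  }
  ## relaxing any uptake bound never decreases the optimum
  for (rid in c("EX_glc", "EX_o2", "EX_pl")) {
    prob2 <- prob
    prob2$ub[rid] <- prob2$ub[rid] * 2
    expect_gte(solve_fba(prob2, parsimonious = FALSE)$objective,
               base$objective - 1e-7)
  }
  ## homogeneous scaling: all bounds x k scales the optimum by exactly k
  for (k in c(0.25, 3)) {
    probk <- prob
    probk$lb <- probk$lb * k; probk$ub <- probk$ub * k
    expect_equal(solve_fba(probk, parsimonious = FALSE)$objective,
                 base$objective * k, tolerance = 1e-8)
  }
})

test_that("flux analysis separates a planted group effect", {
  net <- cardiomyocyte_network()
  tab <- tiny_table(seed = 8, fold = 1.6, cv = 0.1)
  dists <- fba_cohort(net, tab, tissue = "maternal_heart",
                      reference_group = "sham", v_max = 10)
  expect_length(dists, 10)
  for (d in dists)
    expect_lt(max(abs(stoich_matrix(net) %*% d$flux)), 1e-9)
  groups <- setNames(tab$group, tab$sample_id)
  ana <- analyze_flux_distributions(tag_readouts(dists, net), groups)
  expect_equal(dim(ana$scores)[1], 10)
  expect_gt(silhouette_width(ana$scores[, 1], ana$groups), 0)
  ## identical fluxes coincide in PCA space and at zero distance
  same <- dists[c(1, 1, 2, 2)]
  for (i in seq_along(same)) same[[i]]$sample_id <- paste0("s", i)
  g2 <- setNames(c("a", "a", "b", "b"), paste0("s", 1:4))
  ana2 <- analyze_flux_distributions(same, g2)
  expect_equal(ana2$scores[1, ], ana2$scores[2, ], tolerance = 1e-8)
  ## full reconstruction: scores %*% t(loadings) = standardized matrix
  X <- do.call(rbind, lapply(dists, `[[`, "flux"))
  keep <- apply(X, 2, sd) > 0
  Xs <- scale(X[, keep])
  recon <- ana$scores %*% t(ana$loadings)
  expect_equal(recon, Xs, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(analyze_flux_distributions(dists[1:2], groups), "3")
})

test_that("subsystem enrichment matches the combinatorial oracle", {
  net <- enrichment_toy_network()
  ## selection = an entire small subsystem -> smallest p for it
  s2 <- reaction_ids(net)[subsystems(net) == "s2"]
  enr <- subsystem_enrichment(s2, net)
  expect_equal(enr$subsystem[1], "s2")
  expect_true(all(enr$p_adj >= enr$p - 1e-15))
  ## overlap/expected match direct combinatorics
  sel <- reaction_ids(net)[c(1, 2, 5, 9, 13)]
  enr2 <- subsystem_enrichment(sel, net)
  for (i in seq_len(nrow(enr2))) {
    K <- enr2$size[i]; k <- enr2$overlap[i]
    expect_equal(enr2$expected[i], 5 * K / 20)
    expect_equal(enr2$p[i],
                 sum(dhyper(k:min(K, 5), K, 20 - K, 5)), tolerance = 1e-12)
  }
  expect_error(subsystem_enrichment(character(0), net), "empty")
  expect_error(subsystem_enrichment("NOPE", net), "NOPE")
})
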