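## deterministic random table: n samples, independent standard normals
rand_table <- function(seed, n = 10, p = 8) {
  set.seed(seed)
  mets <- sprintf("m%02d", seq_len(p))
  tab <- data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                    tissue = "placenta",
                    group = rep(c("sham", "rupp"), length.out = n),
                    wet_weight_g = 0.1)
  for (m in mets) tab[[m]] <- rnorm(n)
  tab
}

test_that("perfect and inverted correlations are retained", {
  tab <- rand_table(1)
  tab$m02 <- 2 * tab$m01          # r = +1
  tab$m03 <- -tab$m01             # r = -1 (absolute value retained)
  net <- build_coreg_network(tab, c("m01", "m02", "m03"), threshold = 0.7)
  key <- paste(net$edges$met_a, net$edges$met_b, sep = "~")
  expect_setequal(key, c("m01~m02", "m01~m03", "m02~m03"))
  expect_equal(abs(net$edges$r), rep(1, 3))
  expect_error(build_coreg_network(tab, "m01"), "at least 2")
})

test_that("edge set equals the brute-force Pearson filter", {
  for (seed in 1:6) {
    tab <- rand_table(seed)
    mets <- sprintf("m%02d", 1:8)
    for (thr in c(0.3, 0.7)) {
      net <- build_coreg_network(tab, mets, threshold = thr)
      key <- sort(paste(net$edges$met_a, net$edges$met_b, sep = "~"))
      expect_identical(key, oracle_edge_set(as.matrix(tab[mets]), thr))
    }
  }
})

test_that("threshold pruning is monotone and order-invariant", {
  tab <- rand_table(42)
  mets <- sprintf("m%02d", 1:8)
  n_lo <- nrow(build_coreg_network(tab, mets, 0.2)$edges)
  n_hi <- nrow(build_coreg_network(tab, mets, 0.6)$edges)
  expect_lte(n_hi, n_lo)
  ## permuting samples and metabolite order leaves the edge set alone
  net1 <- build_coreg_network(tab, mets, 0.3)
  tab2 <- tab[sample(nrow(tab)), ]
  net2 <- build_coreg_network(tab2, rev(mets), 0.3)
  k1 <- sort(apply(cbind(net1$edges$met_a, net1$edges$met_b), 1,
                   function(z) paste(sort(z), collapse = "~")))
  k2 <- sort(apply(cbind(net2$edges$met_a, net2$edges$met_b), 1,
                   function(z) paste(sort(z), collapse = "~")))
  expect_identical(k1, k2)
})

test_that("eigenvector centrality matches structure and the dense oracle", {
  ## star K_{1,4}: centre dominates
  star <- structure(list(
    nodes = data.frame(metabolite = c("c", "l1", "l2", "l3", "l4"),
                       class = "x", centrality = NA),
    edges = data.frame(met_a = "c", met_b = c("l1", "l2", "l3", "l4"),
                       r = 1),
    isolated = character(0), threshold = 0.7), class = "coreg_network")
  sc <- eigenvector_centrality(star)
  expect_equal(unname(sc["c"]), 1)
  expect_true(all(sc[c("l1", "l2", "l3", "l4")] < 1))
  ## complete graph: symmetry forces equal scores
  cg <- structure(list(
    nodes = data.frame(metabolite = letters[1:4], class = "x",
                       centrality = NA),
    edges = data.frame(met_a = c("a", "a", "a", "b", "b", "c"),
                       met_b = c("b", "c", "d", "c", "d", "d"), r = 0.8),
    isolated = character(0), threshold = 0.7), class = "coreg_network")
  expect_equal(unname(eigenvector_centrality(cg)), rep(1, 4))
  ## arbitrary weighted graphs match the eigendecomposition oracle
  for (seed in 1:5) {
    tab <- rand_table(seed, n = 6)
    net <- build_coreg_network(tab, sprintf("m%02d", 1:8), 0.3)
    if (nrow(net$nodes) < 2) next
    got <- eigenvector_centrality(net)
    want <- oracle_centrality(net$nodes$metabolite, net$edges)
    expect_equal(got[net$nodes$metabolite], want, tolerance = 1e-8)
  }
  ## uniform rescaling of weights leaves scores unchanged
  net <- build_coreg_network(rand_table(3, n = 6), sprintf("m%02d", 1:8),
                             0.3)
  net2 <- net
  net2$edges$r <- net2$edges$r * 0.5
  expect_equal(eigenvector_centrality(net),
               eigenvector_centrality(net2), tolerance = 1e-8)
  empty <- structure(list(nodes = data.frame(metabolite = character(0)),
                          edges = data.frame(met_a = character(0),
                                             met_b = character(0),
                                             r = numeric(0)),
                          isolated = character(0), threshold = 0.7),
                     class = "coreg_network")
  expect_error(eigenvector_centrality(empty), "empty")
})

test_that("GraphML export round-trips", {
  tab <- rand_table(7)
  tab$m02 <- tab$m01 + 0.05 * rnorm(10)
  tab$m04 <- -tab$m03 + 0.05 * rnorm(10)
  net <- build_coreg_network(tab, sprintf("m%02d", 1:8), 0.7)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_coreg_graphml(net, path)
  back <- read_coreg_graphml(path)
  expect_setequal(back$nodes$metabolite, net$nodes$metabolite)
  o <- match(net$nodes$metabolite, back$nodes$metabolite)
  expect_equal(back$nodes$centrality[o], net$nodes$centrality)
  expect_equal(back$nodes$class[o], net$nodes$class)
  k <- function(e) sort(apply(cbind(e$met_a, e$met_b, round(e$r, 10)), 1,
                              paste, collapse = "~"))
  expect_identical(k(back$edges), k(net$edges))
  ## empty-edge network still writes valid GraphML
  lonely <- build_coreg_network(rand_table(8), c("m01", "m02"), 0.9999)
  p2 <- withr::local_tempfile(fileext = ".graphml")
  write_coreg_graphml(lonely, p2)
  expect_true(igraph::is_igraph(igraph::read_graph(p2,
                                                   format = "graphml")))
})
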