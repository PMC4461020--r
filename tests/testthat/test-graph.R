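test_that("graphs are built, validated and duplicate records merged", {
  g <- md_graph("m1", "d1", weight = 20)
  expect_equal(length(g$mirnas), 1L)
  expect_equal(length(g$diseases), 1L)
  expect_equal(g$edges$weight, 20L)

  empty <- md_graph(character(0), character(0))
  expect_equal(length(md_nodes(empty)), 0L)
  expect_equal(md_edge_count(empty), 0L)

  # duplicates pool distinct citations; weight = distinct-pmid count
  g2 <- md_graph(c("m1", "m1"), c("d1", "d1"),
                 weight = c(2, 1), pubmed_ids = c("111;222", "222"))
  expect_equal(nrow(g2$edges), 1L)
  expect_equal(g2$edges$weight, 2L)
  expect_setequal(g2$edges$pubmed_ids[[1L]], c("111", "222"))

  # citation-free duplicates pool by summing
  g3 <- md_graph(c("m1", "m1"), c("d1", "d1"), weight = c(20, 5))
  expect_equal(g3$edges$weight, 25L)

  expect_error(md_graph(c("m1", "d1"), c("d1", "m2"), weight = 1),
               "both miRNA and disease")
  expect_error(md_graph("m1", "d1", weight = 0), ">= 1")
  expect_error(md_graph("m1", "d1", weight = 1.5), "integer")
  expect_error(md_graph("m1", "", weight = 1), "empty identifier")
})

test_that("identifiers are matched case-insensitively, stored as first seen", {
  g <- md_graph(c("hsa-miR-21", " HSA-MIR-21 "), c("Melanoma", "melanoma"),
                weight = c(3, 4))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$weight, 7L)
  expect_equal(g$mirnas, "hsa-miR-21")
  expect_equal(g$diseases, "Melanoma")
})

test_that("weight disagreement with citations resolves to the citation count", {
  expect_warning(g <- md_graph("m1", "d1", weight = 5, pubmed_ids = "9;8"),
                 "citation count")
  expect_equal(g$edges$weight, 2L)
})

test_that("density follows the simple-graph formula and its invariants", {
  # two nodes joined by one edge: the complete graph on 2 nodes
  expect_equal(graph_density(md_graph("m1", "d1", weight = 1)), 1)
  # edgeless graph on 4 nodes
  g0 <- er_bipartite(2, 2, 0, seed = 1)
  expect_equal(graph_density(g0), 0)
  expect_error(graph_density(md_graph(character(0), character(0))),
               "undefined")
  # the worked example: 7 nodes, 5 edges
  expect_equal(graph_density(worked_example()), 2 * 5 / (7 * 6))

  # projecting a star miRNA yields the complete graph on its diseases
  for (n in 2:6) {
    star <- md_graph(rep("hub", n), paste0("d", seq_len(n)), weight = 1)
    expect_equal(graph_density(project_diseases(star)), 1)
  }

  # invariance under relabeling
  g <- er_bipartite(5, 5, 0.5, seed = 11)
  relab <- md_graph(paste0("X", g$edges$mirna), paste0("Y", g$edges$disease),
                    weight = g$edges$weight)
  expect_equal(graph_density(g),
               2 * md_edge_count(relab) /
                 (length(md_nodes(g)) * (length(md_nodes(g)) - 1)))
})

test_that("degree summaries tabulate all nodes and respect handshake identity", {
  star <- md_graph(rep("m1", 5), paste0("d", 1:5), weight = 1)
  ds <- degree_summary(star)
  expect_equal(ds$degree_histogram, c("1" = 5L, "5" = 1L))

  cyc <- md_graph(c("m1", "m2", "m2", "m1"), c("d1", "d1", "d2", "d2"),
                  weight = 1)
  expect_equal(degree_summary(cyc)$degree_histogram, c("2" = 4L))

  for (seed in 1:5) {
    g <- er_bipartite(6, 7, 0.3, seed = seed)
    h <- degree_summary(g)$degree_histogram
    expect_equal(sum(h), length(md_nodes(g)))
    expect_equal(sum(as.integer(names(h)) * h), 2L * md_edge_count(g))
  }
  expect_error(degree_summary(md_graph(character(0), character(0))), "empty")
})

test_that("power-law fit on a preferential-attachment graph is positive", {
  g <- scale_free_bipartite(500, 500, 2, seed = 97)
  ds <- degree_summary(g, fit_powerlaw = TRUE)
  expect_gt(ds$powerlaw_exponent_estimate, 0)
  deg <- as.integer(names(ds$degree_histogram))
  maxdeg <- max(deg)
  meddeg <- stats::median(rep(deg, ds$degree_histogram))
  expect_gte(maxdeg, 5 * meddeg)
})

test_that("disease projection matches common-neighbor counting", {
  # single miRNA star projects to a triangle with unit counts
  tri <- project_diseases(md_graph(rep("m1", 3), c("d1", "d2", "d3"),
                                   weight = 1))
  expect_equal(nrow(tri$edges), 3L)
  expect_true(all(tri$edges$shared_mirnas == 1L))

  # disjoint edges: isolated disease nodes, no projection edges
  disj <- project_diseases(md_graph(c("m1", "m2"), c("d1", "d2"), weight = 1))
  expect_equal(length(disj$diseases), 2L)
  expect_equal(nrow(disj$edges), 0L)

  # two miRNAs sharing two diseases: one edge of count 2
  two <- project_diseases(md_graph(c("m1", "m1", "m2", "m2"),
                                   c("d1", "d2", "d1", "d2"), weight = 1))
  expect_equal(two$edges,
               data.frame(d1 = "d1", d2 = "d2", shared_mirnas = 2L,
                          stringsAsFactors = FALSE))

  # soundness + completeness against the brute-force oracle
  for (seed in 1:25) {
    g <- er_bipartite(sample(2:6, 1), sample(2:6, 1), 0.4, seed = 400 + seed)
    p <- project_diseases(g)
    o <- oracle_projection(g)
    got <- p$edges[order(p$edges$d1, p$edges$d2, method = "radix"), ]
    rownames(got) <- NULL
    names(o) <- c("d1", "d2", "shared_mirnas")
    expect_equal(got, o)
  }
})

test_that("shortest paths are minimal, alternating and deterministic", {
  pathg <- md_graph(c("m1", "m1"), c("d1", "d2"), weight = 1)
  expect_equal(shortest_path(pathg, "d1", "d2"), c("d1", "m1", "d2"))

  disc <- md_graph(c("m1", "m2"), c("d1", "d2"), weight = 1)
  expect_null(shortest_path(disc, "d1", "d2"))

  # two tied 2-hop routes around the square: m1 < m2 wins
  cyc <- md_graph(c("m1", "m2", "m2", "m1"), c("d1", "d1", "d2", "d2"),
                  weight = 1)
  expect_equal(shortest_path(cyc, "d1", "d2"), c("d1", "m1", "d2"))

  expect_error(shortest_path(pathg, "nope", "d1"), "unknown node")
  expect_equal(shortest_path(pathg, "d1", "d1"), "d1")

  # never longer than exhaustive search on small graphs
  for (seed in 1:10) {
    g <- er_bipartite(4, 4, 0.4, seed = 500 + seed)
    nodes <- md_nodes(g)
    pick <- sample(nodes, 2)
    p <- shortest_path(g, pick[[1]], pick[[2]])
    best <- oracle_shortest_length(g, pick[[1]], pick[[2]])
    if (is.null(p)) {
      expect_true(is.infinite(best))
    } else {
      expect_equal(length(p) - 1L, best)
    }
  }
})
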