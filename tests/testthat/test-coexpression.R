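test_that("correlations and their p-values match independent oracles", {
  x <- 1:6
  expect_equal(cor(x, 2 * x), 1)
  expect_equal(cor(x, rev(x)), -1)
  expect_equal(cor(x, c(1, 2, 3, 4, 5, 7)),
               bf_pearson(x, c(1, 2, 3, 4, 5, 7)), tolerance = 1e-12)
  expect_equal(round(cor(x, c(1, 2, 3, 4, 5, 7)), 5), 0.98974)

  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(8)
    expect_equal(cor(a, b), bf_pearson(a, b), tolerance = 1e-12)
    # cor.test as the independent route for the p-value
    expect_equal(correlation_pvalue(cor(a, b), 8),
                 cor.test(a, b)$p.value, tolerance = 1e-10)
  }
  expect_equal(correlation_pvalue(0, 6), 1)
  expect_equal(correlation_pvalue(0.95, 6), 0.0036875, tolerance = 1e-4)
  expect_equal(correlation_pvalue(-0.7, 10), correlation_pvalue(0.7, 10))
  expect_equal(correlation_pvalue(1, 5), 0)
  expect_error(correlation_pvalue(0.5, 2), "n >= 3")
})

test_that("network construction filters, stays bipartite and is monotone", {
  st <- test_study()
  d <- de_by_biotype(st, "tolerant")
  net <- build_network(d$lnc, d$mrna, d$fpkm, st$design, "tolerant")
  expect_s3_class(net, "coexp_network")
  expect_true(all(abs(net$edges$r) >= 0.95))
  expect_true(all(net$edges$p < 0.05))
  # bipartite: lncRNA side and mRNA side never mix
  expect_true(all(grepl("^LNC", net$edges$lncrna_id)))
  expect_true(all(grepl("^GENE", net$edges$mrna_id)))
  # every node appears in >= 1 edge
  expect_setequal(net$lncrna, unique(net$edges$lncrna_id))
  expect_setequal(net$mrna, unique(net$edges$mrna_id))
  # raising r_min never adds edges
  stricter <- build_network(d$lnc, d$mrna, d$fpkm, st$design, "tolerant",
                            r_min = 0.99)
  expect_lte(nrow(stricter$edges), nrow(net$edges))
  expect_true(all(pair_key(stricter$edges) %in% pair_key(net$edges)))
  # permuting samples consistently leaves the edge set unchanged
  perm <- sample(colnames(d$fpkm))
  net2 <- build_network(d$lnc, d$mrna, d$fpkm[, perm], st$design, "tolerant")
  expect_equal(net2$edges, net$edges)
  # no DE lncRNAs -> empty network
  none <- d$lnc; none$call <- "not_de"
  expect_equal(nrow(build_network(none, d$mrna, d$fpkm, st$design,
                                  "tolerant")$edges), 0)
})

test_that("trend classification follows the two DE calls", {
  expect_equal(classify_trend("up", "up"), "same")
  expect_equal(classify_trend("down", "down"), "same")
  expect_equal(classify_trend("up", "down"), "opposite")
  expect_error(classify_trend("up", "not_de"), "up or down")

  st <- test_study()
  d <- de_by_biotype(st, "tolerant")
  net <- build_network(d$lnc, d$mrna, d$fpkm, st$design, "tolerant")
  calls <- setNames(d$all$call, d$all$feature_id)
  same <- calls[net$edges$lncrna_id] == calls[net$edges$mrna_id]
  expect_equal(net$edges$trend, unname(ifelse(same, "same", "opposite")))
  # planted modules are same-direction, so opposite-trend planted edges rare
  planted <- pair_key(planted_module_pairs(st$truth, "tolerant"))
  on_planted <- net$edges[pair_key(net$edges) %in% planted, ]
  expect_lt(mean(on_planted$trend == "opposite"), 0.05)
})

test_that("degree summaries count nodes, edges and the hub", {
  edges <- data.frame(lncrna_id = c("l1", "l1", "l2"),
                      mrna_id = c("m1", "m2", "m1"),
                      r = c(0.99, 0.98, 0.97), p = c(0.001, 0.002, 0.003),
                      trend = "same")
  net <- lncoexp:::new_network(edges, "tolerant", 6)
  s <- degree_summary(net)
  expect_equal(s$n_nodes, 4)
  expect_equal(s$n_edges, 3)
  expect_equal(s$lncrna_degree_max, 2)
  expect_equal(s$mrna_degree_max, 2)
  expect_equal(s$hub, "l1")   # ties to m1 broken lexicographically
  # handshake identity on a generated network
  st <- test_study()
  d <- de_by_biotype(st, "tolerant")
  g <- build_network(d$lnc, d$mrna, d$fpkm, st$design, "tolerant")
  dl <- table(g$edges$lncrna_id); dm <- table(g$edges$mrna_id)
  expect_equal(sum(dl), nrow(g$edges))
  expect_equal(sum(dm), nrow(g$edges))
  empty <- lncoexp:::new_network(lncoexp:::empty_edges(), "t", 6)
  es <- degree_summary(empty)
  expect_equal(es$n_edges, 0)
  expect_true(is.na(es$hub))
})

test_that("term subnetworks keep exactly the incident edges", {
  edges <- data.frame(lncrna_id = c("l1", "l1", "l2", "l3"),
                      mrna_id = c("m1", "m2", "m1", "m3"),
                      r = 0.99, p = 0.001, trend = "same")
  net <- lncoexp:::new_network(edges, "tolerant", 6)
  tm <- data.frame(feature_id = c("m1", "m2", "m9"),
                   term_id = c("T1", "T1", "T2"))
  sub <- subnetwork_by_term(net, tm, "T1")
  expect_setequal(pair_key(sub$edges),
                  c("l1 m1", "l1 m2", "l2 m1"))
  expect_setequal(sub$lncrna, c("l1", "l2"))
  all_tm <- data.frame(feature_id = c("m1", "m2", "m3"), term_id = "ALL")
  expect_equal(subnetwork_by_term(net, all_tm, "ALL")$edges, net$edges)
  expect_equal(nrow(subnetwork_by_term(net, tm, "T2")$edges), 0)
  expect_error(subnetwork_by_term(net, tm, "T99"), "unknown term")
})

test_that("network exports are valid and round-trip through igraph", {
  edges <- data.frame(lncrna_id = c("l1", "l2"), mrna_id = c("m1", "m1"),
                      r = c(0.97, -0.96), p = c(0.001, 0.002),
                      trend = c("same", "opposite"))
  net <- lncoexp:::new_network(edges, "tolerant", 6)
  sif <- export_network(net, "sif")
  expect_equal(sif, c("l1\tcoexp\tm1", "l2\tcoexp\tm1"))
  one <- lncoexp:::new_network(edges[1, ], "t", 6)
  expect_length(export_network(one, "sif"), 1)

  gml <- export_network(net, "graphml")
  doc <- xml2::read_xml(paste(gml, collapse = "\n"))  # well-formed XML
  expect_equal(xml2::xml_name(doc), "graphml")

  path <- tempfile(fileext = ".graphml")
  export_network(net, "graphml", path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::vertex_attr(g, "type"),
                  c("lncRNA", "lncRNA", "mRNA"))
  expect_equal(sort(igraph::edge_attr(g, "r")), sort(edges$r),
               tolerance = 1e-12)
  expect_setequal(igraph::edge_attr(g, "trend"), edges$trend)
})
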