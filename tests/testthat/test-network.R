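make_catalog <- function() {
  data.frame(variant_id = c("rs1", "rs1", "rs2", "rs3"),
             fu_id = c("CL1:TF1", "CL2:TF2-drug", "CL1:TF1", "CL3:TF3"),
             stringsAsFactors = FALSE)
}

test_that("dummy nodes keep multi-FU annotations unambiguous", {
  net <- build_network(make_catalog())
  g <- net$graph
  kinds <- igraph::V(g)$kind
  expect_equal(sum(kinds == "association"), 4)  # one per catalog row
  # every dummy touches exactly one variant
  for (d in igraph::V(g)[kinds == "association"]) {
    nb <- igraph::neighbors(g, d)
    expect_equal(sum(nb$kind == "variant"), 1)
    expect_gte(length(nb), 2)
  }
  # no direct variant-feature edge: all routed through dummies
  ed <- network_edges(net)
  expect_false(any(ed$source_kind == "variant" &
                     ed$target_kind == "chromatin_feature"))
  # the two-FU dSNP cannot be misread as TF1 in CL2: no dummy of rs1
  # connects to both TF1 and CL2
  rs1_dummies <- igraph::V(g)[kinds == "association" &
                                startsWith(igraph::V(g)$label, "rs1@")]
  for (d in rs1_dummies) {
    nb <- igraph::neighbors(g, d)
    labs <- nb$label[nb$kind %in% c("chromatin_feature", "cell_line")]
    expect_false(setequal(intersect(labs, c("TF1", "CL2")), c("TF1", "CL2")))
  }
  # treatment node only where the FU has one
  expect_true("drug" %in% igraph::V(g)$label[kinds == "treatment"])
  expect_equal(sum(kinds == "treatment"), 1)
})

test_that("the catalog round-trips losslessly through the dummy nodes", {
  cat0 <- make_catalog()
  net <- build_network(cat0)
  back <- network_catalog(net)
  expect_equal(back, cat0[order(cat0$variant_id, cat0$fu_id), ],
               ignore_attr = TRUE)
  # empty QTL inputs leave only the dSNP/FU structure
  expect_setequal(unique(network_edges(net)$edge_kind),
                  c("dsnp_association", "has_feature", "in_cell_line",
                    "under_treatment"))
})

test_that("node and edge counts of a crafted fixture match hand enumeration", {
  cat0 <- data.frame(variant_id = c("rs1", "rs2", "rs3"),
                     fu_id = c("CL1:TF1", "CL1:TF1", "CL2:TF2"))
  eqtl <- data.frame(variant_id = "rs1", trait_id = "geneA", significant = TRUE)
  meqtl <- data.frame(variant_id = c("rs1", "rs2"),
                      trait_id = c("cpg1", "cpg2"),
                      significant = c(TRUE, FALSE))
  eqtm <- data.frame(cpg_id = "cpg1", gene_id = "geneA")
  net <- build_network(cat0, eqtl = eqtl, meqtl = meqtl, eqtm = eqtm)
  # nodes: 3 variants + 3 dummies + 2 TFs + 2 cell lines + 1 gene + 1 cpg = 12
  expect_equal(igraph::vcount(net$graph), 12)
  # edges: 3 variant-dummy + 3 dummy-TF + 3 dummy-CL + 1 eqtl + 1 meqtl
  # (significant only) + 1 eqtm = 12
  expect_equal(igraph::ecount(net$graph), 12)
})

test_that("three-way interactions equal the brute-force triple loop", {
  cat0 <- data.frame(variant_id = "rs1", fu_id = "CL1:TF1")
  eqtl <- data.frame(variant_id = "rs1", trait_id = "geneA")
  meqtl <- data.frame(variant_id = "rs1", trait_id = "cpg1")
  eqtm <- data.frame(cpg_id = "cpg1", gene_id = "geneA")
  net <- build_network(cat0, eqtl = eqtl, meqtl = meqtl, eqtm = eqtm)
  tri <- three_way_interactions(net)
  expect_equal(tri, data.frame(variant_id = "rs1", cpg_id = "cpg1",
                               gene_id = "geneA"), ignore_attr = TRUE)
  # removing the eQTM breaks the triangle
  net2 <- build_network(cat0, eqtl = eqtl, meqtl = meqtl)
  expect_equal(nrow(three_way_interactions(net2)), 0)
  # random 10-variant fixture against an independent triple loop
  set.seed(131)
  vs <- paste0("rs", 1:10); gs <- paste0("g", 1:4); cs <- paste0("c", 1:4)
  eq <- unique(data.frame(variant_id = sample(vs, 12, TRUE),
                          trait_id = sample(gs, 12, TRUE)))
  mq <- unique(data.frame(variant_id = sample(vs, 12, TRUE),
                          trait_id = sample(cs, 12, TRUE)))
  em <- unique(data.frame(cpg_id = sample(cs, 8, TRUE),
                          gene_id = sample(gs, 8, TRUE)))
  catx <- data.frame(variant_id = vs, fu_id = "CL1:TF1")
  netx <- build_network(catx, eqtl = eq, meqtl = mq, eqtm = em)
  trix <- three_way_interactions(netx)
  brute <- list()
  for (v in vs) for (c in cs) for (g in gs) {
    if (any(eq$variant_id == v & eq$trait_id == g) &&
        any(mq$variant_id == v & mq$trait_id == c) &&
        any(em$cpg_id == c & em$gene_id == g))
      brute[[length(brute) + 1]] <- paste(v, c, g)
  }
  expect_setequal(paste(trix$variant_id, trix$cpg_id, trix$gene_id),
                  unlist(brute))
  # every reported triangle re-verifies against the raw edge lists
  for (i in seq_len(nrow(trix))) {
    expect_true(any(eq$variant_id == trix$variant_id[i] &
                      eq$trait_id == trix$gene_id[i]))
    expect_true(any(mq$variant_id == trix$variant_id[i] &
                      mq$trait_id == trix$cpg_id[i]))
    expect_true(any(em$cpg_id == trix$cpg_id[i] &
                      em$gene_id == trix$gene_id[i]))
  }
})

test_that("the graph exports to GraphML and an edge-list TSV", {
  net <- build_network(make_catalog())
  dir <- withr::local_tempdir()
  write_network_graphml(net, file.path(dir, "net.graphml"))
  expect_true(file.size(file.path(dir, "net.graphml")) > 0)
  g2 <- igraph::read_graph(file.path(dir, "net.graphml"), format = "graphml")
  expect_equal(igraph::vcount(g2), igraph::vcount(net$graph))
  write_network_edges(net, file.path(dir, "edges.tsv"))
  ed <- read.table(file.path(dir, "edges.tsv"), header = TRUE, sep = "\t")
  expect_setequal(names(ed), c("source_kind", "source_id", "edge_kind",
                               "target_kind", "target_id"))
  expect_equal(nrow(ed), igraph::ecount(net$graph))
})

test_that("unknown FU references are rejected", {
  cat0 <- data.frame(variant_id = "rs1", fu_id = "CL1:TF1")
  fc <- data.frame(fu_id = "CL9:TF9", cell_line = "CL9", feature = "TF9",
                   treatment = NA)
  expect_error(build_network(cat0, fu_catalogue = fc), "unknown FUs")
})
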