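# Dummy-node QTL integration graph. Node ids are "kind:label" so labels are
# unique per kind; a dummy ("association") node ties one variant to the
# components of one FU, which keeps multi-FU dSNPs unambiguous: connecting
# feature and cell line directly to the variant would confuse, e.g.,
# TF1:CL1 + TF2:CL2 with TF1:CL2.

node_id <- function(kind, label) paste(kind, label, sep = "|")

#' Build the dummy-node QTL integration network
#'
#' One dummy node per dSNP-catalog row links its variant to the FU's
#' components (chromatin feature, cell line, optional treatment, optional
#' tissue group). FDR-significant QTL records add direct edges: variant-gene
#' (eQTL), variant-CpG (meQTL), and CpG-gene (eQTM).
#'
#' @param catalog `fuwas` catalog (columns `variant_id`, `fu_id`).
#' @param fu_catalogue optional data frame `fu_id`, `cell_line`, `feature`,
#'   `treatment`, `tissue_group`; by default FU ids are parsed with
#'   [parse_fu_id()].
#' @param eqtl,meqtl optional [qtl_scan()] results (only rows with
#'   `significant == TRUE` are used; a missing `significant` column means
#'   all rows).
#' @param eqtm optional data frame `cpg_id`, `gene_id`.
#' @return object of class `qtl_network` wrapping an igraph graph whose
#'   vertices carry `kind` and `label` attributes and whose edges carry a
#'   `kind` attribute.
#' @export
build_network <- function(catalog, fu_catalogue = NULL, eqtl = NULL,
                          meqtl = NULL, eqtm = NULL) {
  stopifnot(is.data.frame(catalog),
            all(c("variant_id", "fu_id") %in% names(catalog)))
  if (!nrow(catalog)) fu_stop("empty dSNP catalog")
  fc <- if (is.null(fu_catalogue)) parse_fu_id(unique(catalog$fu_id)) else fu_catalogue
  if (!"tissue_group" %in% names(fc)) fc$tissue_group <- NA_character_
  unknown <- setdiff(catalog$fu_id, fc$fu_id)
  if (length(unknown)) fu_stop("catalog references unknown FUs: %s",
                               paste(head(unknown, 3L), collapse = ", "))
  nodes <- list(); edges <- list()
  add_node <- function(kind, label) {
    id <- node_id(kind, label)
    nodes[[id]] <<- list(kind = kind, label = label)
    id
  }
  add_edge <- function(from, to, kind) {
    edges[[length(edges) + 1L]] <<- list(from = from, to = to, kind = kind)
  }
  sig_rows <- function(tab) {
    if (is.null(tab)) return(NULL)
    if ("significant" %in% names(tab)) tab[tab$significant, , drop = FALSE] else tab
  }
  for (i in seq_len(nrow(catalog))) {
    v <- catalog$variant_id[i]; fu <- catalog$fu_id[i]
    comp <- fc[fc$fu_id == fu, ][1L, ]
    dummy <- add_node("association", paste(v, fu, sep = "@"))
    add_edge(add_node("variant", v), dummy, "dsnp_association")
    add_edge(dummy, add_node("chromatin_feature", comp$feature), "has_feature")
    add_edge(dummy, add_node("cell_line", comp$cell_line), "in_cell_line")
    if (!is.na(comp$treatment))
      add_edge(dummy, add_node("treatment", comp$treatment), "under_treatment")
    if (!is.na(comp$tissue_group))
      add_edge(dummy, add_node("tissue_group", comp$tissue_group), "in_tissue_group")
  }
  eq <- sig_rows(eqtl)
  if (!is.null(eq)) for (i in seq_len(nrow(eq)))
    add_edge(add_node("variant", eq$variant_id[i]),
             add_node("gene", eq$trait_id[i]), "eqtl")
  mq <- sig_rows(meqtl)
  if (!is.null(mq)) for (i in seq_len(nrow(mq)))
    add_edge(add_node("variant", mq$variant_id[i]),
             add_node("cpg", mq$trait_id[i]), "meqtl")
  if (!is.null(eqtm)) {
    stopifnot(all(c("cpg_id", "gene_id") %in% names(eqtm)))
    for (i in seq_len(nrow(eqtm)))
      add_edge(add_node("cpg", eqtm$cpg_id[i]),
               add_node("gene", eqtm$gene_id[i]), "eqtm")
  }
  vdf <- data.frame(name = names(nodes),
                    kind = vapply(nodes, `[[`, "", "kind"),
                    label = vapply(nodes, `[[`, "", "label"),
                    stringsAsFactors = FALSE)
  edf <- data.frame(from = vapply(edges, `[[`, "", "from"),
                    to = vapply(edges, `[[`, "", "to"),
                    kind = vapply(edges, `[[`, "", "kind"),
                    stringsAsFactors = FALSE)
  edf <- unique(edf)
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
  structure(list(graph = g, catalog = catalog[, c("variant_id", "fu_id")]),
            class = "qtl_network")
}

#' @export
print.qtl_network <- function(x, ...) {
  g <- x$graph
  kinds <- table(igraph::V(g)$kind)
  cat(sprintf("qtl_network: %d nodes, %d edges\n",
              igraph::vcount(g), igraph::ecount(g)))
  print(kinds)
  invisible(x)
}

#' Edge list of a QTL network
#' @param network a `qtl_network`.
#' @return data frame `source_kind`, `source_id`, `edge_kind`,
#'   `target_kind`, `target_id`.
#' @export
network_edges <- function(network) {
  g <- network$graph
  e <- igraph::as_data_frame(g, what = "edges")
  kind_of <- setNames(igraph::V(g)$kind, igraph::V(g)$name)
  label_of <- setNames(igraph::V(g)$label, igraph::V(g)$name)
  data.frame(source_kind = unname(kind_of[e$from]),
             source_id = unname(label_of[e$from]),
             edge_kind = e$kind,
             target_kind = unname(kind_of[e$to]),
             target_id = unname(label_of[e$to]),
             stringsAsFactors = FALSE)
}

#' Recover (variant, FU) pairs from the dummy nodes
#'
#' The round-trip guarantee: every dummy node encodes exactly one catalog
#' row.
#'
#' @param network a `qtl_network`.
#' @return data frame `variant_id`, `fu_id`.
#' @export
network_catalog <- function(network) {
  g <- network$graph
  dummies <- igraph::V(g)[igraph::V(g)$kind == "association"]
  rows <- lapply(dummies$label, function(lab) {
    parts <- strsplit(lab, "@", fixed = TRUE)[[1]]
    data.frame(variant_id = parts[1], fu_id = parts[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$variant_id, out$fu_id), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Extract three-way QTL interactions
#'
#' Enumerates all (variant, CpG, gene) triangles in which the variant has an
#' eQTL edge to the gene, a meQTL edge to the CpG, and the CpG has an eQTM
#' edge to the gene — i.e. variants with joint epigenetic and transcriptomic
#' effects. Output is lexicographically ordered.
#'
#' @param network a `qtl_network`.
#' @return data frame `variant_id`, `cpg_id`, `gene_id`.
#' @export
three_way_interactions <- function(network) {
  ed <- network_edges(network)
  # an undirected igraph may store edge endpoints in either order, so
  # orient each edge by node kind instead of by from/to position
  oriented <- function(edge_kind, kind_a, name_a, kind_b, name_b) {
    e <- ed[ed$edge_kind == edge_kind, , drop = FALSE]
    a <- ifelse(e$source_kind == kind_a, e$source_id, e$target_id)
    b <- ifelse(e$source_kind == kind_a, e$target_id, e$source_id)
    setNames(data.frame(a, b, stringsAsFactors = FALSE), c(name_a, name_b))
  }
  eqtl <- oriented("eqtl", "variant", "variant_id", "gene", "gene_id")
  meqtl <- oriented("meqtl", "variant", "variant_id", "cpg", "cpg_id")
  eqtm <- oriented("eqtm", "cpg", "cpg_id", "gene", "gene_id")
  empty <- data.frame(variant_id = character(0), cpg_id = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE)
  if (!nrow(eqtl) || !nrow(meqtl) || !nrow(eqtm)) return(empty)
  tri <- merge(merge(eqtl, meqtl, by = "variant_id"), eqtm,
               by = c("cpg_id", "gene_id"))
  if (!nrow(tri)) return(empty)
  tri <- unique(tri[, c("variant_id", "cpg_id", "gene_id")])
  tri <- tri[order(tri$variant_id, tri$cpg_id, tri$gene_id), , drop = FALSE]
  rownames(tri) <- NULL
  tri
}

#' Write a QTL network as GraphML
#' @param network a `qtl_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}

#' Write the network edge list as TSV
#' @param network a `qtl_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(network, path) {
  write.table(network_edges(network), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
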