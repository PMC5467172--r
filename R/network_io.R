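degradation_path <- function(path) {
  ext <- tools::file_ext(path)
  base <- tools::file_path_sans_ext(path)
  paste0(base, "_degradation.", if (nzchar(ext)) ext else "tsv")
}

TABULAR_COLS <- c("organism_id", "organism_name", "organism_kind", "genus",
                  "compound_id", "compound_name", "compound_kind", "mode")

#' Read a bipartite transport network from disk
#'
#' Two on-disk dialects are supported. The *tabular* dialect is a
#' tab-separated file with one link per row and columns `organism_id`,
#' `organism_name`, `organism_kind`, `genus`, `compound_id`, `compound_name`,
#' `compound_kind`, `mode`; isolated nodes are carried as rows with mode
#' `"none"` and the absent side blank. The degradation map lives in a
#' companion file `<stem>_degradation.<ext>` with columns `macromolecule_id`,
#' `product_id` (absent companion = empty map). The *graphml* dialect is a
#' typed GraphML graph with node attributes `node_type`
#' (`organism`/`compound`), `kind`, `label` and `genus`, edge attribute
#' `mode`, and degradation-map entries encoded as macromolecule-to-product
#' edges with mode `"degradation_product"`.
#'
#' @param path file to read.
#' @param format `"tabular"` or `"graphml"`.
#' @return A validated [gut_network()]; node and link counts are reported
#'   via a message.
#' @export
load_network <- function(path, format = c("tabular", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  net <- switch(format,
                tabular = load_network_tabular(path),
                graphml = load_network_graphml(path))
  gm_msg(sprintf("loaded network: %d organisms, %d compounds, %d links",
                 nrow(net$organisms), nrow(net$compounds), nrow(net$links)))
  net
}

load_network_tabular <- function(path) {
  tab <- tryCatch(
    read.delim(path, colClasses = "character", na.strings = NULL),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  missing <- setdiff(TABULAR_COLS, names(tab))
  if (length(missing)) {
    stop("tabular network file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  has_org <- nzchar(tab$organism_id)
  has_cmp <- nzchar(tab$compound_id)
  organisms <- unique(data.frame(id = tab$organism_id[has_org],
                                 name = tab$organism_name[has_org],
                                 kind = tab$organism_kind[has_org],
                                 genus = tab$genus[has_org],
                                 stringsAsFactors = FALSE))
  compounds <- unique(data.frame(id = tab$compound_id[has_cmp],
                                 name = tab$compound_name[has_cmp],
                                 kind = tab$compound_kind[has_cmp],
                                 stringsAsFactors = FALSE))
  is_link <- has_org & has_cmp & tab$mode %in% LINK_MODES
  links <- data.frame(organism_id = tab$organism_id[is_link],
                      compound_id = tab$compound_id[is_link],
                      mode = tab$mode[is_link], stringsAsFactors = FALSE)
  dpath <- degradation_path(path)
  degradation <- if (file.exists(dpath)) {
    read.delim(dpath, colClasses = "character", na.strings = NULL)
  } else {
    empty_degradation()
  }
  gut_network(organisms, compounds, links, degradation)
}

#' Write a bipartite transport network to disk
#'
#' Inverse of [load_network()]: `load_network(write_network(net, path))`
#' reproduces the network exactly in either dialect. The tabular dialect
#' additionally writes the companion `<stem>_degradation.<ext>` file whenever
#' the degradation map is non-empty.
#'
#' @param network a validated `gut_network`.
#' @param path output file.
#' @param format `"tabular"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("tabular", "graphml")) {
  format <- match.arg(format)
  validate_network(network)
  switch(format,
         tabular = write_network_tabular(network, path),
         graphml = write_network_graphml(network, path))
  invisible(path)
}

write_network_tabular <- function(network, path) {
  org <- network$organisms; cmp <- network$compounds; lnk <- network$links
  rows <- if (nrow(lnk)) {
    oi <- match(lnk$organism_id, org$id); ci <- match(lnk$compound_id, cmp$id)
    data.frame(organism_id = lnk$organism_id, organism_name = org$name[oi],
               organism_kind = org$kind[oi], genus = org$genus[oi],
               compound_id = lnk$compound_id, compound_name = cmp$name[ci],
               compound_kind = cmp$kind[ci], mode = lnk$mode,
               stringsAsFactors = FALSE)
  } else {
    setNames(as.data.frame(matrix(character(), ncol = 8)), TABULAR_COLS)
  }
  iso_org <- setdiff(org$id, lnk$organism_id)
  if (length(iso_org)) {
    oi <- match(iso_org, org$id)
    rows <- rbind(rows, data.frame(
      organism_id = iso_org, organism_name = org$name[oi],
      organism_kind = org$kind[oi], genus = org$genus[oi],
      compound_id = "", compound_name = "", compound_kind = "", mode = "none",
      stringsAsFactors = FALSE))
  }
  iso_cmp <- setdiff(cmp$id, c(lnk$compound_id, network$degradation$product_id,
                               network$degradation$macromolecule_id))
  if (length(iso_cmp)) {
    ci <- match(iso_cmp, cmp$id)
    rows <- rbind(rows, data.frame(
      organism_id = "", organism_name = "", organism_kind = "", genus = "",
      compound_id = iso_cmp, compound_name = cmp$name[ci],
      compound_kind = cmp$kind[ci], mode = "none", stringsAsFactors = FALSE))
  }
  # compounds appearing only in the degradation map still need node rows
  dmap_only <- setdiff(c(network$degradation$product_id,
                         network$degradation$macromolecule_id),
                       c(lnk$compound_id, iso_cmp))
  if (length(dmap_only)) {
    ci <- match(dmap_only, cmp$id)
    rows <- rbind(rows, data.frame(
      organism_id = "", organism_name = "", organism_kind = "", genus = "",
      compound_id = dmap_only, compound_name = cmp$name[ci],
      compound_kind = cmp$kind[ci], mode = "none", stringsAsFactors = FALSE))
  }
  ok <- tryCatch({
    write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write network to ", path, call. = FALSE)
  if (nrow(network$degradation)) {
    write.table(network$degradation, degradation_path(path), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  path
}

network_igraph <- function(network) {
  org <- network$organisms; cmp <- network$compounds
  nodes <- data.frame(
    name = c(org$id, cmp$id),
    node_type = c(rep("organism", nrow(org)), rep("compound", nrow(cmp))),
    kind = c(org$kind, cmp$kind),
    label = c(org$name, cmp$name),
    genus = c(org$genus, rep("", nrow(cmp))),
    stringsAsFactors = FALSE)
  edges <- rbind(
    data.frame(from = network$links$organism_id,
               to = network$links$compound_id,
               mode = network$links$mode, stringsAsFactors = FALSE),
    data.frame(from = network$degradation$macromolecule_id,
               to = network$degradation$product_id,
               mode = rep("degradation_product", nrow(network$degradation)),
               stringsAsFactors = FALSE))
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}

write_network_graphml <- function(network, path) {
  ok <- tryCatch({
    igraph::write_graph(network_igraph(network), path, format = "graphml")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write network to ", path, call. = FALSE)
  path
}

load_network_graphml <- function(path) {
  g <- tryCatch(igraph::read_graph(path, format = "graphml"),
                error = function(e) stop("failed to parse ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  va <- igraph::vertex_attr(g)
  needed <- c("name", "node_type", "kind", "label", "genus")
  missing <- setdiff(needed, names(va))
  if (length(missing)) {
    stop("graphml file lacks node attribute(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  is_org <- va$node_type == "organism"
  organisms <- data.frame(id = va$name[is_org], name = va$label[is_org],
                          kind = va$kind[is_org], genus = va$genus[is_org],
                          stringsAsFactors = FALSE)
  compounds <- data.frame(id = va$name[!is_org], name = va$label[!is_org],
                          kind = va$kind[!is_org], stringsAsFactors = FALSE)
  el <- igraph::as_data_frame(g, what = "edges")
  is_dmap <- el$mode == "degradation_product"
  links <- data.frame(organism_id = el$from[!is_dmap],
                      compound_id = el$to[!is_dmap],
                      mode = el$mode[!is_dmap], stringsAsFactors = FALSE)
  degradation <- data.frame(macromolecule_id = el$from[is_dmap],
                            product_id = el$to[is_dmap],
                            stringsAsFactors = FALSE)
  gut_network(organisms, compounds, links, degradation)
}
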