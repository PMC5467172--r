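#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm coef median optimize p.adjust rgeom rlnorm rpois runif
#'   setNames wilcox.test cor density quantile sd
#' @importFrom utils read.delim write.table head combn
NULL

ORGANISM_KINDS <- c("bacterium", "archaeon", "host_cell")
COMPOUND_KINDS <- c("small_molecule", "macromolecule")
LINK_MODES <- c("import", "export", "degrade")

gm_msg <- function(...) {
  if (isTRUE(getOption("gutmin.verbose", TRUE))) message(...)
}

empty_links <- function() {
  data.frame(organism_id = character(), compound_id = character(),
             mode = character(), stringsAsFactors = FALSE)
}

empty_degradation <- function() {
  data.frame(macromolecule_id = character(), product_id = character(),
             stringsAsFactors = FALSE)
}

#' Bipartite organism-compound transport network
#'
#' Constructs and validates the central data structure of the package: a
#' bipartite network whose one node set is gut organisms (bacteria, archaea,
#' and host cell types) and whose other node set is chemical compounds
#' (small-molecule metabolites and macromolecules). Directed links record
#' that an organism imports or exports a small molecule, or degrades a
#' macromolecule; an accompanying degradation map lists the small-molecule
#' breakdown products of each macromolecule, which become available to the
#' whole community as public goods.
#'
#' Duplicate `(organism, compound, mode)` link triples (for example from
#' strain-level records already unified to species) are silently
#' deduplicated, with the number removed reported via a message.
#'
#' @param organisms data.frame with columns `id`, `name`, `kind`
#'   (`"bacterium"`, `"archaeon"` or `"host_cell"`) and `genus` (empty string
#'   for host cells).
#' @param compounds data.frame with columns `id`, `name`, `kind`
#'   (`"small_molecule"` or `"macromolecule"`).
#' @param links data.frame with columns `organism_id`, `compound_id`, `mode`
#'   (`"import"`, `"export"` or `"degrade"`); `degrade` links may only point
#'   at macromolecules.
#' @param degradation data.frame with columns `macromolecule_id`,
#'   `product_id` mapping each macromolecule to its small-molecule
#'   degradation products.
#' @return An object of class `gut_network`: a list with the four validated
#'   data frames.
#' @examples
#' net <- gut_network(
#'   organisms = data.frame(id = c("A", "B"), name = c("A", "B"),
#'                          kind = "bacterium", genus = c("gA", "gB")),
#'   compounds = data.frame(id = "ac", name = "acetate",
#'                          kind = "small_molecule"),
#'   links = data.frame(organism_id = c("A", "B"), compound_id = "ac",
#'                      mode = c("export", "import")))
#' role_sets(net, "ac")
#' @export
gut_network <- function(organisms, compounds, links = NULL,
                        degradation = NULL) {
  organisms <- as.data.frame(organisms, stringsAsFactors = FALSE)
  compounds <- as.data.frame(compounds, stringsAsFactors = FALSE)
  if (is.null(organisms$genus)) organisms$genus <- ""
  if (is.null(links) || nrow(as.data.frame(links)) == 0) links <- empty_links()
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  if (is.null(degradation) || nrow(as.data.frame(degradation)) == 0) {
    degradation <- empty_degradation()
  }
  degradation <- as.data.frame(degradation, stringsAsFactors = FALSE)

  for (col in c("id", "name", "kind", "genus")) {
    organisms[[col]] <- as.character(organisms[[col]])
  }
  for (col in c("id", "name", "kind")) {
    compounds[[col]] <- as.character(compounds[[col]])
  }
  if (nrow(links)) for (col in names(links)) links[[col]] <- as.character(links[[col]])
  if (nrow(degradation)) {
    for (col in names(degradation)) degradation[[col]] <- as.character(degradation[[col]])
  }

  key <- paste(links$organism_id, links$compound_id, links$mode)
  dup <- duplicated(key)
  if (any(dup)) {
    gm_msg(sprintf("deduplicated %d repeated link(s)", sum(dup)))
    links <- links[!dup, , drop = FALSE]
  }
  dupd <- duplicated(degradation)
  if (any(dupd)) degradation <- degradation[!dupd, , drop = FALSE]

  net <- structure(list(organisms = organisms, compounds = compounds,
                        links = links, degradation = degradation),
                   class = "gut_network")
  validate_network(net)
  net
}

#' Validate a bipartite transport network
#'
#' Checks referential integrity and the structural invariants of a
#' [gut_network()]: unique ids, admissible `kind`/`mode` values, genus
#' labelling consistent with organism kind, degrade links restricted to
#' macromolecules, and a degradation map whose keys are macromolecules and
#' whose products are existing small molecules.
#'
#' @param network a `gut_network`.
#' @return The network, invisibly; errors describe all offending records.
#' @export
validate_network <- function(network) {
  org <- network$organisms; cmp <- network$compounds
  lnk <- network$links; dgr <- network$degradation
  problems <- character()
  add <- function(p) problems <<- c(problems, p)

  if (anyDuplicated(org$id)) add("duplicated organism ids")
  if (anyDuplicated(cmp$id)) add("duplicated compound ids")
  bad <- setdiff(unique(org$kind), ORGANISM_KINDS)
  if (length(bad)) add(paste("unknown organism kind:", paste(bad, collapse = ", ")))
  bad <- setdiff(unique(cmp$kind), COMPOUND_KINDS)
  if (length(bad)) add(paste("unknown compound kind:", paste(bad, collapse = ", ")))
  host <- org$kind == "host_cell"
  if (any(org$genus[host] != "")) add("host cells must have empty genus")
  if (any(org$genus[!host] == "")) {
    add(paste("missing genus for:",
              paste(org$id[!host & org$genus == ""], collapse = ", ")))
  }
  if (nrow(lnk)) {
    bad <- setdiff(unique(lnk$mode), LINK_MODES)
    if (length(bad)) add(paste("unknown link mode:", paste(bad, collapse = ", ")))
    dang <- setdiff(lnk$organism_id, org$id)
    if (length(dang)) add(paste("links reference unknown organisms:",
                                paste(dang, collapse = ", ")))
    dang <- setdiff(lnk$compound_id, cmp$id)
    if (length(dang)) add(paste("links reference unknown compounds:",
                                paste(dang, collapse = ", ")))
    macro <- cmp$id[cmp$kind == "macromolecule"]
    degr <- lnk$mode == "degrade"
    bad <- lnk$compound_id[degr & !(lnk$compound_id %in% macro)]
    if (length(bad)) add(paste("degrade links on non-macromolecules:",
                               paste(unique(bad), collapse = ", ")))
    small <- cmp$id[cmp$kind == "small_molecule"]
    bad <- lnk$compound_id[!degr & !(lnk$compound_id %in% small)]
    if (length(bad)) add(paste("import/export links on macromolecules:",
                               paste(unique(bad), collapse = ", ")))
  }
  if (nrow(dgr)) {
    macro <- cmp$id[cmp$kind == "macromolecule"]
    small <- cmp$id[cmp$kind == "small_molecule"]
    bad <- setdiff(dgr$macromolecule_id, macro)
    if (length(bad)) add(paste("degradation-map keys are not macromolecules:",
                               paste(bad, collapse = ", ")))
    bad <- setdiff(dgr$product_id, small)
    if (length(bad)) add(paste("degradation products are not known small molecules:",
                               paste(bad, collapse = ", ")))
  }
  if (length(problems)) {
    stop("invalid gut_network:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(network)
}

#' @export
print.gut_network <- function(x, ...) {
  cat(sprintf(
    "gut_network: %d organisms (%d host cells), %d compounds (%d macromolecules), %d links\n",
    nrow(x$organisms), sum(x$organisms$kind == "host_cell"),
    nrow(x$compounds), sum(x$compounds$kind == "macromolecule"),
    nrow(x$links)))
  invisible(x)
}

check_compound <- function(network, compound_id) {
  if (length(compound_id) != 1 || !compound_id %in% network$compounds$id) {
    stop("unknown compound: ", compound_id, call. = FALSE)
  }
}

check_organism <- function(network, organism_id) {
  if (length(organism_id) != 1 || !organism_id %in% network$organisms$id) {
    stop("unknown organism: ", organism_id, call. = FALSE)
  }
}

#' Importers, exporters and degraders of a compound
#'
#' @param network a `gut_network`.
#' @param compound_id a compound id present in the network.
#' @return A list with sorted character vectors `importers`, `exporters` and
#'   `degraders` (the latter always empty for small molecules).
#' @export
role_sets <- function(network, compound_id) {
  check_compound(network, compound_id)
  lnk <- network$links[network$links$compound_id == compound_id, , drop = FALSE]
  list(importers = sort(unique(lnk$organism_id[lnk$mode == "import"])),
       exporters = sort(unique(lnk$organism_id[lnk$mode == "export"])),
       degraders = sort(unique(lnk$organism_id[lnk$mode == "degrade"])))
}

#' Effective export set of an organism
#'
#' Small molecules an organism releases into the shared environment: the
#' union of its directly exported small molecules and the degradation
#' products of every macromolecule it degrades (degradation products are
#' treated as indirect export products of all degraders).
#'
#' @param network a `gut_network`.
#' @param organism_id an organism id present in the network.
#' @return Sorted character vector of small-molecule compound ids.
#' @export
effective_exports <- function(network, organism_id) {
  check_organism(network, organism_id)
  lnk <- network$links[network$links$organism_id == organism_id, , drop = FALSE]
  direct <- lnk$compound_id[lnk$mode == "export"]
  small <- network$compounds$id[network$compounds$kind == "small_molecule"]
  direct <- intersect(direct, small)
  degraded <- lnk$compound_id[lnk$mode == "degrade"]
  products <- network$degradation$product_id[
    network$degradation$macromolecule_id %in% degraded]
  sort(unique(c(direct, products)))
}
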