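#' Configuration for metabolic influence network construction
#'
#' @param alpha positive saturation constant added to the abundance-weighted
#'   consumer total of every metabolite; on the relative-abundance scale the
#'   default 1 means a metabolite's per-capita share saturates when total
#'   consumer abundance is comparable to 1.
#' @param abundance_basis which per-species abundance enters the influence
#'   weights: mean over all cohort samples (`"pooled_mean"`, default), or the
#'   control-only / T2D-only means.
#' @param edge_filter `"phenotype_consistent"` keeps an edge i -> j only when
#'   the sign of i's abundance change times the sign of the influence weight
#'   equals the sign of j's abundance change, i.e. the influence accounts for
#'   the observed abundance shift; `"none"` keeps all non-zero edges.
#' @param weight_normalization normalization constant used downstream when
#'   propagating influence along paths: mean (`"mean_abs"`) or maximum
#'   (`"max_abs"`) absolute edge weight.
#' @param degrader_competition treat degraders of a macromolecule as
#'   competing consumers of the macromolecule itself (default TRUE).
#' @return a `min_config` list.
#' @export
min_config <- function(alpha = 1,
                       abundance_basis = c("pooled_mean", "control_mean",
                                           "t2d_mean"),
                       edge_filter = c("phenotype_consistent", "none"),
                       weight_normalization = c("mean_abs", "max_abs"),
                       degrader_competition = TRUE) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0) {
    stop("alpha must be a positive number", call. = FALSE)
  }
  structure(list(alpha = alpha,
                 abundance_basis = match.arg(abundance_basis),
                 edge_filter = match.arg(edge_filter),
                 weight_normalization = match.arg(weight_normalization),
                 degrader_competition = degrader_competition),
            class = "min_config")
}

# Production / consumption incidence over a species universe.
# Production = effective exports (direct small-molecule exports plus
# degradation products); consumption = imports, plus the degraded
# macromolecule itself when degrader_competition is on.
transport_incidence <- function(network, species, degrader_competition = TRUE) {
  compounds <- network$compounds$id
  Gp <- matrix(0, length(species), length(compounds),
               dimnames = list(species, compounds))
  Gc <- Gp
  lnk <- network$links[network$links$organism_id %in% species, , drop = FALSE]
  imp <- lnk[lnk$mode == "import", , drop = FALSE]
  Gc[cbind(imp$organism_id, imp$compound_id)] <- 1
  exp_ <- lnk[lnk$mode == "export", , drop = FALSE]
  small <- network$compounds$id[network$compounds$kind == "small_molecule"]
  exp_ <- exp_[exp_$compound_id %in% small, , drop = FALSE]
  Gp[cbind(exp_$organism_id, exp_$compound_id)] <- 1
  deg <- lnk[lnk$mode == "degrade", , drop = FALSE]
  if (nrow(deg)) {
    dm <- merge(deg, network$degradation,
                by.x = "compound_id", by.y = "macromolecule_id")
    if (nrow(dm)) Gp[cbind(dm$organism_id, dm$product_id)] <- 1
    if (degrader_competition) Gc[cbind(deg$organism_id, deg$compound_id)] <- 1
  }
  list(Gp = Gp, Gc = Gc)
}

# Per-compound source terms: A[l, k] = Gp[l,k]/C_k - Gc[l,k] * P_k / C_k^2
influence_terms <- function(inc, n, alpha) {
  n <- n[rownames(inc$Gp)]
  P <- as.numeric(n %*% inc$Gp)
  C <- alpha + as.numeric(n %*% inc$Gc)
  A <- sweep(inc$Gp, 2, C, "/") - sweep(inc$Gc, 2, P / C^2, "*")
  list(A = A, P = P, C = C)
}

#' Pairwise metabolic influence between two species
#'
#' Quantifies the net effect of species `i`'s abundance on species `j`'s
#' growth, `W_ij`, as the sensitivity of `j`'s growth to `n_i` under a
#' shared-resource growth model: `j`'s growth rate is the sum over imported
#' metabolites `k` of the per-capita share `P_k / C_k`, where
#' `P_k = sum_l n_l g_lk^p` is abundance-weighted production (direct export
#' plus macromolecule degradation products) and `C_k = alpha + sum_l n_l
#' g_lk^c` is abundance-weighted consumption plus the saturation constant
#' `alpha`. Differentiating with respect to `n_i` gives
#' `W_ij = sum_{k in K_j} [ g_ik^p / C_k - g_ik^c P_k / C_k^2 ]`:
#' cross-feeding (production of what `j` consumes) contributes positively,
#' co-consumption (competition) negatively.
#'
#' @param network a `gut_network`.
#' @param i,j distinct species ids.
#' @param abundances named non-negative abundance vector; the names define
#'   the species universe over which production and consumption totals are
#'   accumulated.
#' @param alpha positive saturation constant.
#' @param degrader_competition see [min_config()].
#' @return scalar `W_ij`; per-metabolite contributions in
#'   `attr(, "terms")` (non-zero terms, named by compound id).
#' @export
species_influence <- function(network, i, j, abundances, alpha = 1,
                              degrader_competition = TRUE) {
  check_organism(network, i); check_organism(network, j)
  if (i == j) stop("self-influence is undefined (i == j)", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (any(abundances < 0)) stop("abundances must be >= 0", call. = FALSE)
  universe <- union(names(abundances), c(i, j))
  n <- setNames(numeric(length(universe)), universe)
  n[names(abundances)] <- abundances
  inc <- transport_incidence(network, universe, degrader_competition)
  tm <- influence_terms(inc, n, alpha)
  terms <- tm$A[i, ] * inc$Gc[j, ]
  # competition for a degraded macromolecule acts through consumption shares
  # of its products; the macromolecule node itself is not an importable
  # nutrient of j unless j imports it, which the incidence already encodes
  w <- sum(terms)
  attr(w, "terms") <- terms[terms != 0]
  w
}

#' Metabolic influence of one entity group on another
#'
#' Aggregates species-level influences to group entities: the influence of
#' group `G` on group `Gamma` is the sum over source species `l` in `G` and
#' target species `q` in `Gamma` of `W_lq`, each weighted by species `q`'s
#' share of `Gamma`'s total abundance. Species shared by both groups are
#' excluded from the source side to avoid self-influence.
#'
#' @param network a `gut_network`.
#' @param source_members,target_members character vectors of species ids.
#' @param abundances named abundance vector (defines the species universe).
#' @param alpha positive saturation constant.
#' @param degrader_competition see [min_config()].
#' @return scalar `W_G,Gamma` with per-metabolite contributions in
#'   `attr(, "terms")`.
#' @export
group_influence <- function(network, source_members, target_members,
                            abundances, alpha = 1,
                            degrader_competition = TRUE) {
  n_t <- abundances[target_members]
  if (anyNA(n_t)) stop("target members lack abundances", call. = FALSE)
  tot <- sum(n_t)
  if (tot == 0) {
    stop("target group has zero total abundance; weights undefined",
         call. = FALSE)
  }
  src <- setdiff(source_members, target_members)
  if (!length(src)) {
    w <- 0
    attr(w, "terms") <- numeric()
    return(w)
  }
  universe <- union(names(abundances), c(src, target_members))
  n <- setNames(numeric(length(universe)), universe)
  n[names(abundances)] <- abundances
  inc <- transport_incidence(network, universe, degrader_competition)
  tm <- influence_terms(inc, n, alpha)
  srcsum <- colSums(tm$A[src, , drop = FALSE])
  cons <- as.numeric((n_t / tot) %*% inc$Gc[target_members, , drop = FALSE])
  terms <- srcsum * cons
  names(terms) <- colnames(inc$Gc)
  w <- sum(terms)
  attr(w, "terms") <- terms[terms != 0]
  w
}

basis_abundances <- function(abundance, groups, basis) {
  rows <- switch(basis,
                 pooled_mean = c(groups$control, groups$t2d),
                 control_mean = groups$control,
                 t2d_mean = groups$t2d)
  colMeans(abundance[rows, , drop = FALSE])
}

#' Build a context-specific metabolic influence network
#'
#' Computes the pairwise metabolic influence `W_ij` between every ordered
#' pair of differentially abundant entities and assembles the directed,
#' weighted metabolic influence network (MIN). Under the default
#' phenotype-consistent filter, an edge i -> j is kept only when the observed
#' abundance changes explain each other through the influence: an entity more
#' abundant in T2D with positive influence on j is consistent with j also
#' being more abundant in T2D, and so on
#' (`sign(dn_i) * sign(W_ij) == sign(dn_j)`).
#'
#' @param de a `diff_entities` table; only rows flagged `significant` become
#'   MIN nodes.
#' @param network a `gut_network`.
#' @param abundance samples x species matrix.
#' @param groups list with sample ids `control` and `t2d`.
#' @param config a [min_config()].
#' @return An object of class `min`: list with `nodes` (entity table with
#'   direction and relative change), `edges` (`source`, `target`, `weight`),
#'   `contributions` (per-edge named vectors of per-metabolite terms,
#'   summing to the edge weight), `members`, `abundances`, and `config`.
#' @export
build_min <- function(de, network, abundance, groups, config = min_config()) {
  nodes <- de[de$significant, , drop = FALSE]
  if (nrow(nodes) < 2) stop("need >= 2 significant entities", call. = FALSE)
  members <- entity_members(de)[nodes$entity_id]

  species <- intersect(colnames(abundance),
                       network$organisms$id[network$organisms$kind != "host_cell"])
  n <- basis_abundances(abundance, groups, config$abundance_basis)[species]
  mem_u <- lapply(members, intersect, species)
  usable <- lengths(mem_u) > 0
  if (any(!usable)) {
    gm_msg(sprintf("dropped %d entities with no member in the abundance table",
                   sum(!usable)))
    nodes <- nodes[usable, , drop = FALSE]
    mem_u <- mem_u[usable]
  }
  ids <- nodes$entity_id
  inc <- transport_incidence(network, species, config$degrader_competition)
  tm <- influence_terms(inc, n, config$alpha)

  SA <- t(vapply(mem_u, function(m) colSums(tm$A[m, , drop = FALSE]),
                 numeric(ncol(tm$A))))
  CV <- t(vapply(mem_u, function(m) {
    nt <- n[m]
    if (sum(nt) == 0) stop("entity with zero total abundance", call. = FALSE)
    as.numeric((nt / sum(nt)) %*% inc$Gc[m, , drop = FALSE])
  }, numeric(ncol(inc$Gc))))

  rc <- setNames(nodes$rel_change, ids)
  edges <- list(); contributions <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j) next
      shared <- intersect(mem_u[[i]], mem_u[[j]])
      srcsum <- if (length(shared)) {
        src <- setdiff(mem_u[[i]], shared)
        if (!length(src)) next
        colSums(tm$A[src, , drop = FALSE])
      } else {
        SA[i, ]
      }
      terms <- srcsum * CV[j, ]
      w <- sum(terms)
      if (w == 0) next
      if (config$edge_filter == "phenotype_consistent" &&
          sign(rc[i]) * sign(w) != sign(rc[j])) next
      key <- paste0(ids[i], "->", ids[j])
      edges[[key]] <- data.frame(source = ids[i], target = ids[j], weight = w,
                                 stringsAsFactors = FALSE)
      contributions[[key]] <- terms[terms != 0]
    }
  }
  edges <- if (length(edges)) do.call(rbind, c(edges, make.row.names = FALSE))
           else data.frame(source = character(), target = character(),
                           weight = numeric(), stringsAsFactors = FALSE)
  structure(list(nodes = data.frame(entity_id = ids, kind = nodes$kind,
                                    label = nodes$label,
                                    direction = nodes$direction,
                                    rel_change = nodes$rel_change,
                                    stringsAsFactors = FALSE),
                 edges = edges, contributions = contributions,
                 members = mem_u, abundances = n, config = config),
            class = "min")
}

#' @export
print.min <- function(x, ...) {
  cat(sprintf("metabolic influence network: %d entities, %d directed edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Construct a MIN directly from node/edge tables (fixtures, small studies).
#' Assemble a MIN from explicit node and edge tables
#'
#' Low-level constructor used by the fixture generators and for hand-built
#' influence networks. `nodes` needs columns `entity_id` and `rel_change`
#' (`kind`, `label`, `direction` are filled with defaults when absent);
#' `edges` needs `source`, `target`, `weight`.
#'
#' @param nodes,edges data.frames as described above.
#' @param members optional named list of member species per entity.
#' @param config a [min_config()].
#' @return a `min` object.
#' @export
make_min <- function(nodes, edges, members = NULL, config = min_config()) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (is.null(nodes$kind)) nodes$kind <- "species"
  if (is.null(nodes$label)) nodes$label <- nodes$entity_id
  if (is.null(nodes$direction)) {
    nodes$direction <- ifelse(nodes$rel_change >= 0, "abundant_in_T2D",
                              "abundant_in_control")
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    bad <- setdiff(c(edges$source, edges$target), nodes$entity_id)
    if (length(bad)) stop("edges reference unknown entities: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (any(edges$source == edges$target)) stop("self-loops are not allowed",
                                                call. = FALSE)
    if (any(edges$weight == 0)) stop("zero-weight edges are not stored",
                                     call. = FALSE)
  }
  if (is.null(members)) members <- setNames(as.list(nodes$entity_id),
                                            nodes$entity_id)
  structure(list(nodes = nodes, edges = edges, contributions = list(),
                 members = members, abundances = NULL, config = config),
            class = "min")
}

#' Candidate microbe-host metabolic interactions
#'
#' Identifies entities of the MIN likely to matter for the host, in two
#' steps. First, differential metabolic cliques whose defining compound is
#' imported, exported or degraded by a host cell are selected; such cliques
#' proxy compounds enriched in one phenotype that the host directly touches.
#' Second, every MIN entity that shares both the phenotype direction and the
#' metabolic capability (consumption, production including degradation
#' products, or degradation of that compound) with a selected clique is
#' linked to the host cell.
#'
#' @param de a `diff_entities` table (cliques are taken from its significant
#'   rows).
#' @param network a `gut_network` containing host-cell organisms.
#' @param min the corresponding `min`.
#' @return data.frame with columns `entity_id`, `host_id`, `compound_id`,
#'   `direction`, `host_mode`, `entity_capability` (0 rows when no candidate
#'   exists).
#' @export
host_interaction_candidates <- function(de, network, min) {
  empty <- data.frame(entity_id = character(), host_id = character(),
                      compound_id = character(), direction = character(),
                      host_mode = character(), entity_capability = character(),
                      stringsAsFactors = FALSE)
  hosts <- network$organisms$id[network$organisms$kind == "host_cell"]
  if (!length(hosts)) return(empty)
  hlnk <- network$links[network$links$organism_id %in% hosts, , drop = FALSE]
  cliques <- de[de$significant & de$kind == "clique", , drop = FALSE]
  if (!nrow(cliques)) return(empty)
  # defining compound of a clique entity id "clique:<compound>:<mode>"
  parts <- strsplit(sub("^clique:", "", cliques$entity_id), ":", fixed = TRUE)
  cliques$compound_id <- vapply(parts, `[`, "", 1)
  sel <- cliques[cliques$compound_id %in% hlnk$compound_id, , drop = FALSE]
  if (!nrow(sel)) return(empty)

  members <- min$members
  out <- list()
  for (r in seq_len(nrow(sel))) {
    cid <- sel$compound_id[r]; dir <- sel$direction[r]
    hrows <- hlnk[hlnk$compound_id == cid, , drop = FALSE]
    cand <- min$nodes[min$nodes$direction == dir, , drop = FALSE]
    for (e in cand$entity_id) {
      mem <- members[[e]]
      elnk <- network$links[network$links$organism_id %in% mem &
                              network$links$compound_id == cid, , drop = FALSE]
      caps <- character()
      if (any(elnk$mode == "import")) caps <- c(caps, "consumption")
      if (any(elnk$mode == "degrade")) caps <- c(caps, "degradation")
      produces <- any(vapply(mem, function(s)
        cid %in% effective_exports(network, s), TRUE))
      if (produces) caps <- c(caps, "production")
      if (!length(caps)) next
      for (h in seq_len(nrow(hrows))) {
        out[[length(out) + 1]] <- data.frame(
          entity_id = e, host_id = hrows$organism_id[h], compound_id = cid,
          direction = dir, host_mode = hrows$mode[h],
          entity_capability = paste(caps, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  unique(do.call(rbind, c(out, make.row.names = FALSE)))
}
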