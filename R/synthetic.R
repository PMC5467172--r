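#' Specification for the synthetic-data generators
#'
#' Defines the study conditions emulated by the generators: a bipartite
#' transport network whose species import/export degrees are approximately
#' exponential (geometric draws with rates `r_imp`, `r_exp`) and whose
#' compound popularity is heavy-tailed (sampling weights proportional to
#' `rank^-heavy_tail_exponent`), and a two-group cohort of relative
#' abundances with planted differential species (log-normal noise,
#' multiplicative fold changes in the T2D group, closure to sum 1).
#'
#' Defaults mirror the reference study conditions: import/export degree
#' rates 0.2 and 0.4, a cohort of 21 control and 11 T2D samples, log-normal
#' noise sigma 0.5, and ten planted species at fold change 2.
#'
#' @param n_species,n_compounds,n_macromolecules network sizes
#'   (`n_compounds` counts small molecules only).
#' @param r_imp,r_exp exponential rates of the species import/export degree
#'   distributions, in (0, 1).
#' @param heavy_tail_exponent exponent of the compound popularity weights.
#' @param n_control,n_t2d cohort sample sizes.
#' @param n_planted number of planted differential species used when
#'   `planted_effects` is NULL.
#' @param fold_change fold change of the default planted species in T2D.
#' @param noise_sigma log-normal standard deviation of baseline abundances.
#' @param planted_effects optional list of `list(species = <ids>, fold =
#'   <positive number>)` blueprints overriding the default planting.
#' @param seed integer master seed; every generator stage derives its own
#'   stream from it.
#' @return a `generator_spec` list.
#' @export
generator_spec <- function(n_species = 100, n_compounds = 60,
                           n_macromolecules = 5, r_imp = 0.2, r_exp = 0.4,
                           heavy_tail_exponent = 1.5, n_control = 21,
                           n_t2d = 11, n_planted = 10, fold_change = 2,
                           noise_sigma = 0.5, planted_effects = NULL,
                           seed = 1) {
  stopifnot(n_species >= 1, n_compounds >= 1, n_macromolecules >= 0,
            n_control >= 1, n_t2d >= 1, noise_sigma > 0, fold_change > 0)
  if (r_imp <= 0 || r_imp >= 1 || r_exp <= 0 || r_exp >= 1) {
    stop("degree rates must lie in (0, 1)", call. = FALSE)
  }
  if (n_macromolecules > 0 && n_compounds < 4) {
    stop("need >= 4 small molecules to draw degradation products",
         call. = FALSE)
  }
  structure(list(n_species = n_species, n_compounds = n_compounds,
                 n_macromolecules = n_macromolecules, r_imp = r_imp,
                 r_exp = r_exp, heavy_tail_exponent = heavy_tail_exponent,
                 n_control = n_control, n_t2d = n_t2d, n_planted = n_planted,
                 fold_change = fold_change, noise_sigma = noise_sigma,
                 planted_effects = planted_effects, seed = as.integer(seed)),
            class = "generator_spec")
}

# Per-stage seed: master seed times a small prime plus a stage counter,
# kept below 2^31 so independent stages are independently reproducible.
stage_seed <- function(seed, stage) {
  (as.double(seed) * 101 + stage) %% 2147483647
}

#' Generate a synthetic bipartite transport network
#'
#' Species import and export degrees are geometric draws with rates `r_imp`
#' and `r_exp` (so the degree distribution is exponential,
#' `P(k) ~ exp(-r k)`); the partner compounds are sampled with heavy-tailed
#' popularity weights so that compound degrees are much broader than species
#' degrees. Each macromolecule receives 2-4 small-molecule degradation
#' products and 1-3 degrader species. Genus labels are assigned so that
#' multi-member genera exist.
#'
#' @param spec a [generator_spec()].
#' @return list with `network` (a validated `gut_network`) and `truth`
#'   (import/export degrees, compound weights, degrader assignments).
#' @export
generate_network <- function(spec) {
  set.seed(stage_seed(spec$seed, 1))
  ns <- spec$n_species; nc <- spec$n_compounds; nm <- spec$n_macromolecules
  sp_ids <- sprintf("sp%04d", seq_len(ns))
  sm_ids <- sprintf("c%04d", seq_len(nc))
  mm_ids <- if (nm > 0) sprintf("mm%02d", seq_len(nm)) else character()

  n_genera <- max(2, round(ns / 4))
  genus <- sprintf("g%03d", sample.int(n_genera, ns, replace = TRUE))
  organisms <- data.frame(id = sp_ids, name = sp_ids,
                          kind = ifelse(runif(ns) < 0.1, "archaeon",
                                        "bacterium"),
                          genus = genus, stringsAsFactors = FALSE)
  compounds <- data.frame(
    id = c(sm_ids, mm_ids), name = c(sm_ids, mm_ids),
    kind = c(rep("small_molecule", nc), rep("macromolecule", nm)),
    stringsAsFactors = FALSE)

  weights <- seq_len(nc)^(-spec$heavy_tail_exponent)
  d_imp <- pmin(rgeom(ns, 1 - exp(-spec$r_imp)), nc)
  d_exp <- pmin(rgeom(ns, 1 - exp(-spec$r_exp)), nc)
  draw <- function(d) if (d == 0) character() else
    sm_ids[sample.int(nc, d, prob = weights)]
  links <- list()
  for (i in seq_len(ns)) {
    imp <- draw(d_imp[i]); exp_ <- draw(d_exp[i])
    if (length(imp)) links[[length(links) + 1]] <-
      data.frame(organism_id = sp_ids[i], compound_id = imp, mode = "import",
                 stringsAsFactors = FALSE)
    if (length(exp_)) links[[length(links) + 1]] <-
      data.frame(organism_id = sp_ids[i], compound_id = exp_, mode = "export",
                 stringsAsFactors = FALSE)
  }
  degradation <- empty_degradation()
  degraders <- list()
  if (nm > 0) {
    for (m in mm_ids) {
      products <- sm_ids[sample.int(nc, sample(2:4, 1))]
      degradation <- rbind(degradation,
                           data.frame(macromolecule_id = m,
                                      product_id = products,
                                      stringsAsFactors = FALSE))
      degs <- sp_ids[sample.int(ns, sample(1:3, 1))]
      degraders[[m]] <- degs
      links[[length(links) + 1]] <-
        data.frame(organism_id = degs, compound_id = m, mode = "degrade",
                   stringsAsFactors = FALSE)
    }
  }
  links <- if (length(links)) do.call(rbind, c(links, make.row.names = FALSE))
           else empty_links()
  net <- gut_network(organisms, compounds, links, degradation)
  list(network = net,
       truth = list(import_degrees = setNames(d_imp, sp_ids),
                    export_degrees = setNames(d_exp, sp_ids),
                    compound_weights = setNames(weights, sm_ids),
                    degraders = degraders))
}

#' Generate a synthetic two-group cohort
#'
#' Baseline abundances are log-normal with `sdlog = noise_sigma`; planted
#' species are multiplied by their fold change in the T2D samples; every
#' sample is then closed (divided by its total) so abundances are relative.
#' Metadata places all samples in one configurable stratum (male, mid-age,
#' normal weight, metformin-untreated by default).
#'
#' @param spec a [generator_spec()].
#' @param network the companion synthetic network (planted species must
#'   exist in it).
#' @return list with `abundance` (samples x species matrix), `metadata`,
#'   `groups` (sample ids per phenotype) and `truth` (planted species, fold
#'   changes and expected directions).
#' @export
generate_cohort <- function(spec, network) {
  set.seed(stage_seed(spec$seed, 2))
  species <- network$organisms$id[network$organisms$kind != "host_cell"]
  planted <- spec$planted_effects
  if (is.null(planted)) {
    n_pl <- min(spec$n_planted, length(species))
    planted <- list(list(species = sort(sample(species, n_pl)),
                         fold = spec$fold_change))
  }
  bad <- setdiff(unlist(lapply(planted, `[[`, "species")), species)
  if (length(bad)) {
    stop("planted species not in network: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n_tot <- spec$n_control + spec$n_t2d
  samples <- c(sprintf("ctrl%03d", seq_len(spec$n_control)),
               sprintf("t2d%03d", seq_len(spec$n_t2d)))
  phenotype <- c(rep("control", spec$n_control), rep("T2D", spec$n_t2d))
  ab <- matrix(rlnorm(n_tot * length(species), 0, spec$noise_sigma),
               nrow = n_tot, dimnames = list(samples, species))
  t2d_rows <- phenotype == "T2D"
  for (pe in planted) {
    ab[t2d_rows, pe$species] <- ab[t2d_rows, pe$species] * pe$fold
  }
  ab <- ab / rowSums(ab)
  metadata <- data.frame(sample_id = samples, phenotype = phenotype,
                         gender = "male",
                         age = round(runif(n_tot, 45, 64.9), 1),
                         bmi = round(runif(n_tot, 18.5, 24.9), 1),
                         metformin = "untreated", stringsAsFactors = FALSE)
  truth <- list(planted = planted,
                planted_species = unique(unlist(lapply(planted, `[[`,
                                                       "species"))),
                directions = setNames(
                  unlist(lapply(planted, function(pe)
                    rep(if (pe$fold > 1) "abundant_in_T2D"
                        else "abundant_in_control", length(pe$species)))),
                  unlist(lapply(planted, `[[`, "species"))))
  list(abundance = ab, metadata = metadata,
       groups = list(control = samples[!t2d_rows], t2d = samples[t2d_rows]),
       truth = truth)
}

#' Find a clean cross-feeding pair in a network
#'
#' Deterministically selects a producer/consumer species pair suitable for
#' planting an end-to-end cross-feeding signal: the producer exports a small
#' molecule the consumer imports, and the two import disjoint compound sets,
#' so the pairwise metabolic influence of producer on consumer is strictly
#' positive (cross-feeding with no competing consumption).
#'
#' @param network a `gut_network`.
#' @return character vector `c(producer, consumer)`, or `NULL` when the
#'   network contains no such pair.
#' @export
find_cross_feeding_pair <- function(network) {
  lnk <- network$links
  species <- network$organisms$id[network$organisms$kind != "host_cell"]
  imports <- split(lnk$compound_id[lnk$mode == "import"],
                   factor(lnk$organism_id[lnk$mode == "import"],
                          levels = species))
  for (k in sort(unique(lnk$compound_id[lnk$mode == "export"]))) {
    exporters <- sort(intersect(lnk$organism_id[lnk$mode == "export" &
                                                  lnk$compound_id == k],
                                species))
    importers <- sort(intersect(lnk$organism_id[lnk$mode == "import" &
                                                  lnk$compound_id == k],
                                species))
    for (e in exporters) {
      for (co in setdiff(importers, e)) {
        if (!length(intersect(imports[[e]], imports[[co]]))) {
          return(c(e, co))
        }
      }
    }
  }
  NULL
}

#' Hand-parameterized MIN fixtures with known influence structure
#'
#' Small influence networks whose community-influence values are known
#' analytically, for testing and demonstration:
#' \describe{
#'   \item{chain}{A -> B -> C with unit weights and relative change 1.}
#'   \item{star}{a hub with `m` unit-weight out-edges to leaves.}
#'   \item{diamond}{two equal-length directed paths A -> B -> D and
#'     A -> C -> D with distinct weights.}
#'   \item{bimodal_phi}{80 peripheral nodes with Poisson(2) out-degree and 5
#'     hub nodes with 25 out-edges each, all edge weights 0.7; under max_abs
#'     normalization and a fixed threshold of 0.5 only direct edges count, so
#'     Phi equals out-degree and the Phi distribution is bimodal. The planted
#'     hub ids are stored in `attr(, "truth")`.}
#' }
#'
#' @param kind fixture name.
#' @param m number of leaves for the star fixture.
#' @param seed seed for the bimodal fixture.
#' @return a `min` object.
#' @export
generate_min_fixture <- function(kind = c("chain", "star", "diamond",
                                          "bimodal_phi"),
                                 m = 5, seed = 1) {
  kind <- match.arg(kind)
  node <- function(ids) data.frame(entity_id = ids, rel_change = 1,
                                   stringsAsFactors = FALSE)
  if (kind == "chain") {
    return(make_min(node(c("A", "B", "C")),
                    data.frame(source = c("A", "B"), target = c("B", "C"),
                               weight = 1)))
  }
  if (kind == "star") {
    leaves <- sprintf("L%02d", seq_len(m))
    return(make_min(node(c("hub", leaves)),
                    data.frame(source = "hub", target = leaves, weight = 1)))
  }
  if (kind == "diamond") {
    return(make_min(node(c("A", "B", "C", "D")),
                    data.frame(source = c("A", "A", "B", "C"),
                               target = c("B", "C", "D", "D"),
                               weight = c(0.8, 0.6, 0.5, 0.4))))
  }
  # bimodal_phi: regular edges carry weight 0.7 and a dedicated anchor edge
  # carries the maximum weight 1, so under max_abs normalization a direct
  # regular edge propagates 0.7 (above a 0.5 threshold) while any two-hop
  # product is at most 0.49 (below it); Phi then equals out-degree and its
  # distribution is bimodal by construction.
  set.seed(stage_seed(seed, 3))
  n_low <- 80; n_hub <- 5; hub_deg <- 25
  low <- sprintf("low%03d", seq_len(n_low))
  hubs <- sprintf("hub%02d", seq_len(n_hub))
  edges <- list(anchor = data.frame(source = "anchor1", target = "anchor2",
                                    weight = 1, stringsAsFactors = FALSE))
  for (h in hubs) {
    edges[[h]] <- data.frame(source = h, target = sample(low, hub_deg),
                             weight = 0.7, stringsAsFactors = FALSE)
  }
  for (l in low) {
    d <- min(rpois(1, 2), n_low - 1)
    if (d == 0) next
    edges[[l]] <- data.frame(source = l,
                             target = sample(setdiff(low, l), d),
                             weight = 0.7, stringsAsFactors = FALSE)
  }
  out <- make_min(node(c(hubs, low, "anchor1", "anchor2")),
                  do.call(rbind, c(edges, make.row.names = FALSE)))
  attr(out, "truth") <- list(hubs = hubs)
  out
}
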