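#' Configuration for community-influence analysis
#'
#' @param theta_phi non-negative influence threshold used when
#'   `theta_mode = "fixed"`.
#' @param theta_mode `"permutation_q95"` (default) sets the threshold to the
#'   95th percentile of `|Phi_ij|` over edge-weight-permuted null networks;
#'   `"fixed"` uses `theta_phi` as given.
#' @param normalization normalization of edge weights before path products:
#'   divide by the mean (`"mean_abs"`) or maximum (`"max_abs"`) absolute edge
#'   weight of the MIN.
#' @param permutations number of weight permutations for the null threshold
#'   (>= 100 when `theta_mode = "permutation_q95"`).
#' @param seed seed for the permutation stream.
#' @return an `influence_config` list.
#' @export
influence_config <- function(theta_phi = 0.5,
                             theta_mode = c("permutation_q95", "fixed"),
                             normalization = c("mean_abs", "max_abs"),
                             permutations = 1000, seed = 1) {
  theta_mode <- match.arg(theta_mode)
  if (!is.numeric(theta_phi) || theta_phi < 0) {
    stop("theta_phi must be >= 0", call. = FALSE)
  }
  if (theta_mode == "permutation_q95" && permutations < 100) {
    stop("need >= 100 permutations for the null threshold", call. = FALSE)
  }
  structure(list(theta_phi = theta_phi, theta_mode = theta_mode,
                 normalization = match.arg(normalization),
                 permutations = permutations, seed = seed),
            class = "influence_config")
}

min_igraph <- function(min) {
  igraph::graph_from_data_frame(min$edges, directed = TRUE,
                                vertices = min$nodes$entity_id)
}

weight_norm_constant <- function(weights, normalization) {
  if (!length(weights)) return(1)
  switch(normalization,
         mean_abs = mean(abs(weights)),
         max_abs = max(abs(weights)))
}

# Phi matrix: phi[i, j] = (dn_i/n_i) * mean over shortest directed paths
# i -> j of the product of normalized edge weights; 0 when unreachable.
phi_pair_matrix <- function(min, config, weights = min$edges$weight) {
  ids <- min$nodes$entity_id
  m <- length(ids)
  phi <- matrix(0, m, m, dimnames = list(ids, ids))
  if (!nrow(min$edges)) return(phi)
  g <- min_igraph(min)
  wnorm <- weights / weight_norm_constant(weights, config$normalization)
  wkey <- setNames(wnorm, paste0(min$edges$source, "->", min$edges$target))
  rc <- setNames(min$nodes$rel_change, ids)
  for (i in ids) {
    sp <- suppressWarnings(
      igraph::all_shortest_paths(g, from = i, mode = "out",
                                 weights = NA))$vpaths
    if (!length(sp)) next
    prods <- vapply(sp, function(p) {
      v <- names(p)
      if (length(v) < 2) return(NA_real_)
      prod(wkey[paste0(v[-length(v)], "->", v[-1])])
    }, 0)
    ends <- vapply(sp, function(p) names(p)[length(p)], "")
    ok <- !is.na(prods)
    if (!any(ok)) next
    mean_by_end <- tapply(prods[ok], ends[ok], mean)
    phi[i, names(mean_by_end)] <- rc[i] * as.numeric(mean_by_end)
  }
  phi
}

#' Shortest-path metabolic influence between two entities
#'
#' Entity `i`'s influence on entity `j` along the MIN, `Phi_ij`: for each
#' shortest directed path from `i` to `j` (unit edge length), the path
#' influence is `i`'s relative abundance change times the product of
#' normalized edge weights along the path; `Phi_ij` is the average over all
#' shortest paths, and 0 when `j` is unreachable from `i`.
#'
#' @param min a `min` object (edges already phenotype-filtered).
#' @param i,j distinct entity ids in the MIN.
#' @param config an [influence_config()].
#' @return scalar `Phi_ij`.
#' @export
pair_influence <- function(min, i, j, config = influence_config()) {
  ids <- min$nodes$entity_id
  if (!i %in% ids) stop("unknown entity: ", i, call. = FALSE)
  if (!j %in% ids) stop("unknown entity: ", j, call. = FALSE)
  if (i == j) stop("pair influence needs i != j", call. = FALSE)
  phi_pair_matrix(min, config)[i, j]
}

#' Community metabolic influence and network influencers
#'
#' The community metabolic influence of entity `i` is the number of entities
#' `j` receiving an above-threshold influence from `i`:
#' `Phi_i = sum_j H(|Phi_ij| - theta)`, with `H` the Heaviside step function.
#' The threshold is either fixed or set to the 95th percentile of `|Phi_ij|`
#' over null networks obtained by permuting the edge weights on the fixed
#' topology (seeded, reproducible). Influencers are then detected from the
#' `Phi` distribution via [detect_influencers()].
#'
#' @param min a `min` object.
#' @param config an [influence_config()].
#' @return An `influence_result`: list with `phi` (named counts),
#'   `phi_matrix`, `theta`, `influencer` (named logical), `transition`
#'   (transition point of the Phi distribution) and `config`.
#' @export
community_influence <- function(min, config = influence_config()) {
  if (nrow(min$nodes) < 2) stop("MIN needs >= 2 nodes", call. = FALSE)
  phi_mat <- phi_pair_matrix(min, config)
  theta <- if (config$theta_mode == "fixed") {
    config$theta_phi
  } else {
    permutation_theta(min, config)
  }
  above <- abs(phi_mat) >= theta & theta > 0
  if (theta == 0) {
    above <- abs(phi_mat) > 0
    diag(above) <- FALSE
  }
  diag(above) <- FALSE
  phi <- rowSums(above)
  det <- detect_influencers(phi)
  structure(list(phi = phi, phi_matrix = phi_mat, theta = theta,
                 influencer = det$influencer, transition = det$transition,
                 config = config),
            class = "influence_result")
}

permutation_theta <- function(min, config) {
  if (!nrow(min$edges)) return(0)
  set.seed(config$seed)
  vals <- unlist(lapply(seq_len(config$permutations), function(b) {
    w <- sample(min$edges$weight)
    p <- phi_pair_matrix(min, config, weights = w)
    v <- abs(p[p != 0])
    v
  }))
  if (!length(vals)) return(0)
  unname(quantile(vals, 0.95, type = 7))
}

#' @export
print.influence_result <- function(x, ...) {
  cat(sprintf(
    "community influence: %d entities, theta = %.4g, %d influencer(s), transition at %s\n",
    length(x$phi), x$theta, sum(x$influencer),
    if (is.na(x$transition)) "NA" else format(x$transition)))
  invisible(x)
}

#' Detect network influencers from the Phi distribution
#'
#' Influencers are entities whose community influence lies beyond the
#' transition point of the `Phi` distribution: the first local minimum of
#' the estimated probability distribution of `Phi` after its global mode
#' (the drop-off separating the bulk from the high-influence tail). Because
#' `Phi` values are counts, the distribution is estimated by a unit-width
#' histogram smoothed with a 3-bin moving average, which suppresses spurious
#' single-bin dips in the sparse tail. When the smoothed distribution has no
#' interior minimum (a unimodal distribution), the fallback is the largest
#' relative gap between consecutive sorted unique `Phi` values above the
#' median, and the choice is reported via a message. All-equal `Phi` yields
#' no influencers, with a warning.
#'
#' @param phi named numeric vector of per-entity community influences
#'   (non-negative counts).
#' @return list with `influencer` (named logical), `transition` (numeric or
#'   `NA`) and `rule` (`"density_minimum"`, `"gap"` or `"degenerate"`).
#' @export
detect_influencers <- function(phi) {
  if (length(unique(phi)) == 1) {
    warning("all community influences are equal; no influencers detected")
    return(list(influencer = setNames(rep(FALSE, length(phi)), names(phi)),
                transition = NA_real_, rule = "degenerate"))
  }
  kmax <- max(phi)
  counts <- tabulate(floor(phi) + 1L, nbins = floor(kmax) + 1L)
  padded <- c(0, counts, 0)
  y <- (padded[-c(1, 2)] + padded[-c(1, length(padded))] +
          padded[-((length(padded) - 1):length(padded))]) / 3
  imode <- which.max(y)
  trans <- NA_real_
  if (imode + 2 <= length(y)) {
    for (t in (imode + 1):(length(y) - 1)) {
      if (y[t] < y[t - 1] && y[t] <= y[t + 1] &&
          any(y[(t + 1):length(y)] > y[t])) {
        trans <- t - 1  # bins are 0-based Phi values
        break
      }
    }
  }
  rule <- "density_minimum"
  if (is.na(trans)) {
    u <- sort(unique(phi))
    u <- u[u >= median(phi)]
    if (length(u) < 2) {
      warning("no transition point found; no influencers detected")
      return(list(influencer = setNames(rep(FALSE, length(phi)), names(phi)),
                  transition = NA_real_, rule = "degenerate"))
    }
    gaps <- diff(u) / pmax(abs(u[-length(u)]), 1)
    trans <- u[which.max(gaps) + 1]
    rule <- "gap"
    gm_msg(sprintf("no interior density minimum; gap rule places transition at %g",
                   trans))
  }
  list(influencer = phi >= trans, transition = trans, rule = rule)
}

#' Macromolecule-degrader enrichment among influencers
#'
#' Fraction of macromolecule degraders (entities with at least one member
#' species having a degrade link) among influencers versus non-influencers,
#' and their ratio.
#'
#' @param min a `min` object.
#' @param network a `gut_network`.
#' @param influencer named logical vector (from [community_influence()]).
#' @return list with `influencer_fraction`, `non_influencer_fraction`,
#'   `ratio` (`NA` when undefined) and the underlying counts.
#' @export
degrader_enrichment <- function(min, network, influencer) {
  degraders <- unique(network$links$organism_id[network$links$mode == "degrade"])
  is_deg <- vapply(min$members[min$nodes$entity_id],
                   function(m) any(m %in% degraders), TRUE)
  infl <- influencer[min$nodes$entity_id]
  frac <- function(idx) {
    if (!any(idx)) return(NA_real_)
    mean(is_deg[idx])
  }
  fi <- frac(infl); fn <- frac(!infl)
  ratio <- if (is.na(fi) || is.na(fn) || fn == 0) NA_real_ else fi / fn
  list(influencer_fraction = fi, non_influencer_fraction = fn, ratio = ratio,
       n_influencers = sum(infl), n_non_influencers = sum(!infl),
       n_degraders = sum(is_deg))
}
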