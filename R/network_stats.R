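count_by <- function(ids, universe) {
  out <- setNames(integer(length(universe)), universe)
  if (length(ids)) {
    tb <- table(ids)
    out[names(tb)] <- as.integer(tb)
  }
  out
}

#' Degree statistics of the bipartite transport network
#'
#' Computes, for every microbial species, the number of metabolites it
#' imports and exports, and, for every compound, the number of species
#' importing/exporting it, together with means and medians of each. Organisms
#' without any link count with degree 0. Host cells are excluded from the
#' species-side statistics by default, but still count on the compound side
#' when `include_host = TRUE`.
#'
#' @param network a `gut_network`.
#' @param include_host include host cells in the organism-side statistics.
#' @return An object of class `degree_summary`: named count vectors
#'   `organism_import`, `organism_export`, `compound_importers`,
#'   `compound_exporters`, `compound_degraders` plus a `stats` data.frame of
#'   means and medians.
#' @export
degree_summary <- function(network, include_host = FALSE) {
  org <- network$organisms
  if (!include_host) org <- org[org$kind != "host_cell", , drop = FALSE]
  if (nrow(org) == 0 || nrow(network$compounds) == 0) {
    warning("degree_summary on an empty network")
  }
  lnk <- network$links
  olnk <- lnk[lnk$organism_id %in% org$id, , drop = FALSE]
  res <- list(
    organism_import = count_by(olnk$organism_id[olnk$mode == "import"], org$id),
    organism_export = count_by(olnk$organism_id[olnk$mode == "export"], org$id),
    compound_importers = count_by(olnk$compound_id[olnk$mode == "import"],
                                  network$compounds$id),
    compound_exporters = count_by(olnk$compound_id[olnk$mode == "export"],
                                  network$compounds$id),
    compound_degraders = count_by(olnk$compound_id[olnk$mode == "degrade"],
                                  network$compounds$id))
  res$stats <- data.frame(
    quantity = names(res),
    mean = vapply(res, function(x) mean(as.numeric(x)), 0),
    median = vapply(res, function(x) median(as.numeric(x)), 0),
    row.names = NULL)
  structure(res, class = "degree_summary")
}

#' @export
print.degree_summary <- function(x, ...) {
  cat("degree_summary\n")
  print(x$stats, digits = 3)
  invisible(x)
}

pmf_points <- function(degrees) {
  degrees <- degrees[is.finite(degrees) & degrees >= 1]
  tb <- table(degrees)
  list(k = as.numeric(names(tb)), count = as.numeric(tb),
       p = as.numeric(tb) / length(degrees), n = length(degrees))
}

#' Fit an exponential degree distribution
#'
#' Fits `P(k) ~ exp(-r k)` to a vector of degrees. The primary estimate of
#' the rate `r` comes from a count-weighted least-squares line through the
#' points `(k, log Phat(k))` of the empirical probability mass function
#' (weighting each support point by its observation count suppresses the
#' downward bias otherwise induced by noisy singleton tail frequencies). A
#' maximum-likelihood estimate, from the memoryless (geometric) form of the
#' distribution left-truncated at the smallest observed degree, is reported
#' as a diagnostic. Degrees below 1 are excluded from the fit.
#'
#' @param degrees integer-valued degree vector.
#' @return A `distribution_fit` with elements `family`, `parameter` (`r`),
#'   `mle`, `support`, `r_squared` and `n`.
#' @export
fit_exponential <- function(degrees) {
  pts <- pmf_points(degrees)
  if (length(pts$k) < 3) {
    stop("insufficient data: need >= 3 distinct degree values with positive ",
         "empirical probability", call. = FALSE)
  }
  fit <- lm(log(pts$p) ~ pts$k, weights = pts$count)
  kmin <- min(pts$k)
  m <- sum(pts$k * pts$count) / sum(pts$count)
  r_mle <- log((m - kmin + 1) / (m - kmin))
  structure(list(family = "exponential",
                 parameter = unname(-coef(fit)[2]),
                 mle = r_mle,
                 support = pts$k,
                 r_squared = summary(fit)$r.squared,
                 n = pts$n),
            class = "distribution_fit")
}

hurwitz_zeta <- function(s, kmin) {
  z <- pracma::zeta(s)
  if (kmin > 1) z <- z - sum((seq_len(kmin - 1))^(-s))
  z
}

#' Fit a power-law degree distribution
#'
#' Fits `P(k) ~ k^(-gamma)` for `k >= k_min`. The primary estimate of the
#' exponent comes from a count-weighted least-squares line through
#' `(log k, log Phat(k))` on the empirical pmf; the exact discrete
#' (zeta-distribution) maximum-likelihood estimate is reported as a
#' diagnostic.
#'
#' @param degrees integer-valued degree vector.
#' @param k_min smallest degree included in the fit (default 1).
#' @return A `distribution_fit` with elements `family`, `parameter`
#'   (`gamma`), `mle`, `support`, `r_squared` and `n`.
#' @export
fit_powerlaw <- function(degrees, k_min = 1) {
  degrees <- degrees[is.finite(degrees) & degrees >= k_min]
  pts <- pmf_points(degrees)
  if (length(pts$k) < 3) {
    stop("insufficient data: need >= 3 distinct degree values with positive ",
         "empirical probability", call. = FALSE)
  }
  fit <- lm(log(pts$p) ~ log(pts$k), weights = pts$count)
  slogk <- sum(pts$count * log(pts$k))
  nll <- function(g) pts$n * log(hurwitz_zeta(g, k_min)) + g * slogk
  mle <- optimize(nll, c(1.001, 12))$minimum
  structure(list(family = "power_law",
                 parameter = unname(-coef(fit)[2]),
                 mle = mle,
                 support = pts$k,
                 r_squared = summary(fit)$r.squared,
                 n = pts$n),
            class = "distribution_fit")
}

#' @export
print.distribution_fit <- function(x, ...) {
  cat(sprintf("%s fit: parameter = %.4g (MLE diagnostic %.4g), %d values, R^2 = %.3f\n",
              x$family, x$parameter, x$mle, x$n, x$r_squared))
  invisible(x)
}

#' Rank organisms by transport promiscuity
#'
#' Orders microbial species by total transport degree (imports + exports),
#' descending, ties broken by organism id so the ranking is deterministic.
#'
#' @param network a `gut_network`.
#' @param include_host include host cells in the ranking.
#' @return data.frame with columns `id`, `name`, `imports`, `exports`,
#'   `total`, ordered by decreasing `total`.
#' @export
promiscuity_ranking <- function(network, include_host = FALSE) {
  ds <- degree_summary(network, include_host = include_host)
  ids <- names(ds$organism_import)
  out <- data.frame(
    id = ids,
    name = network$organisms$name[match(ids, network$organisms$id)],
    imports = as.integer(ds$organism_import),
    exports = as.integer(ds$organism_export),
    stringsAsFactors = FALSE)
  out$total <- out$imports + out$exports
  out <- out[order(-out$total, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

jaccard_import_similarity <- function(network, species) {
  imp <- network$links[network$links$mode == "import" &
                         network$links$organism_id %in% species, , drop = FALSE]
  sets <- split(imp$compound_id, factor(imp$organism_id, levels = species))
  n <- length(species)
  J <- matrix(0, n, n, dimnames = list(species, species))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b <= a) next
      u <- length(union(sets[[a]], sets[[b]]))
      J[a, b] <- J[b, a] <- if (u == 0) 0 else
        length(intersect(sets[[a]], sets[[b]])) / u
    }
  }
  diag(J) <- 1
  J
}

#' Nutritional similarity versus co-occurrence
#'
#' Tests whether species with similar nutritional profiles tend to co-occur
#' across samples. For every pair of species present in both the network and
#' the abundance table, nutritional similarity is the Jaccard index of their
#' import sets and co-occurrence is the Spearman correlation of their
#' abundance profiles across samples. The association between the two
#' pairwise measures is summarized by a Spearman correlation, with a
#' one-sided Mantel permutation p-value (species identities permuted) so the
#' pairwise dependence structure is respected.
#'
#' @param network a `gut_network`.
#' @param abundance samples x species relative-abundance matrix (column names
#'   are species ids).
#' @param permutations number of Mantel permutations.
#' @param seed optional seed for the permutation stream.
#' @return list with `rho`, `p_value`, `n_species`, `n_pairs` and a
#'   `degenerate` flag (TRUE when either pairwise vector has zero variance,
#'   in which case `rho` is `NA`).
#' @export
similarity_cooccurrence <- function(network, abundance, permutations = 10000,
                                    seed = NULL) {
  species <- intersect(colnames(abundance), network$organisms$id)
  if (length(species) < 2) {
    stop("insufficient data: < 2 species shared between network and ",
         "abundance table", call. = FALSE)
  }
  J <- jaccard_import_similarity(network, species)
  C <- suppressWarnings(cor(abundance[, species, drop = FALSE],
                            method = "spearman"))
  C[is.na(C)] <- 0
  jl <- J[lower.tri(J)]; cl <- C[lower.tri(C)]
  if (sd(jl) == 0 || sd(cl) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_,
                n_species = length(species), n_pairs = length(jl),
                degenerate = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  mt <- vegan::mantel(stats::as.dist(J), stats::as.dist(C),
                      method = "spearman", permutations = permutations)
  list(rho = unname(mt$statistic), p_value = mt$signif,
       n_species = length(species), n_pairs = length(jl),
       degenerate = FALSE)
}
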