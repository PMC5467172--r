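entity_directions <- function(x) {
  if (inherits(x, "min")) {
    list(table = x$nodes[, c("entity_id", "direction")], members = x$members)
  } else if (inherits(x, "diff_entities")) {
    sig <- x[x$significant, , drop = FALSE]
    list(table = sig[, c("entity_id", "direction")],
         members = entity_members(x)[sig$entity_id])
  } else {
    stop("expected a 'min' or 'diff_entities' object", call. = FALSE)
  }
}

#' Commonly produced metabolites by phenotype direction
#'
#' For each phenotype direction (entities abundant in T2D versus abundant in
#' control), computes the fraction of entities that produce each small
#' molecule. An entity produces a metabolite when at least one member species
#' has it among its effective exports (direct export, or degradation product
#' of a degraded macromolecule when `include_degradation = TRUE`); each entity
#' counts once regardless of how many members produce it.
#'
#' @param x a `min` or `diff_entities` object (significant entities).
#' @param network a `gut_network`.
#' @param include_degradation count degradation products as production.
#' @return A `production_profile` data.frame with columns `direction`,
#'   `compound_id`, `compound_name`, `n_producing`, `n_entities`, `fraction`.
#' @export
production_fractions <- function(x, network, include_degradation = TRUE) {
  ed <- entity_directions(x)
  if (!nrow(ed$table)) stop("no entities with directions", call. = FALSE)
  small <- network$compounds[network$compounds$kind == "small_molecule", ,
                             drop = FALSE]
  produced <- lapply(ed$table$entity_id, function(e) {
    mem <- ed$members[[e]]
    if (include_degradation) {
      unique(unlist(lapply(mem, function(s) effective_exports(network, s))))
    } else {
      lnk <- network$links
      unique(lnk$compound_id[lnk$mode == "export" & lnk$organism_id %in% mem &
                               lnk$compound_id %in% small$id])
    }
  })
  out <- do.call(rbind, lapply(unique(ed$table$direction), function(d) {
    idx <- ed$table$direction == d
    counts <- table(factor(unlist(produced[idx]), levels = small$id))
    data.frame(direction = d, compound_id = small$id,
               compound_name = small$name,
               n_producing = as.integer(counts),
               n_entities = sum(idx),
               fraction = as.numeric(counts) / sum(idx),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("production_profile", "data.frame")
  out
}

#' Top commonly produced metabolites for a direction
#'
#' Ranks metabolites by the fraction of entities producing them, descending,
#' with ties broken by compound id. When the fraction at rank `k` is tied
#' with following metabolites, all tied metabolites are included and the
#' result is flagged (`attr(, "tie_at_k")`).
#'
#' @param profile a [production_fractions()] result.
#' @param direction which phenotype direction to rank.
#' @param k number of metabolites to report (default 5).
#' @return data.frame of the top metabolites, ordered.
#' @export
top_k <- function(profile, direction, k = 5) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  p <- profile[profile$direction == direction, , drop = FALSE]
  p <- p[order(-p$fraction, p$compound_id), , drop = FALSE]
  tie <- FALSE
  kk <- min(k, nrow(p))
  if (kk < nrow(p) && p$fraction[kk] == p$fraction[kk + 1]) {
    tie <- TRUE
    kk <- max(which(p$fraction == p$fraction[kk]))
    gm_msg("tie at rank k; reporting all tied metabolites")
  }
  out <- p[seq_len(kk), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tie_at_k") <- tie
  out
}
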