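AGE_BANDS <- list(young = c(-Inf, 45), mid = c(45, 65), old = c(65, Inf))
BMI_BANDS <- list(underweight = c(-Inf, 18.5), normal = c(18.5, 25),
                  overweight = c(25, Inf))

in_band <- function(x, band) x >= band[1] & x < band[2]

#' Select a demographic stratum of samples
#'
#' Splits sample metadata into phenotype groups within one demographic
#' stratum. Age bands follow the US Census Bureau convention: young
#' (age < 45), mid (45 <= age < 65), old (age >= 65); BMI bands are
#' underweight (BMI < 18.5), normal (18.5 <= BMI < 25) and overweight
#' (BMI >= 25); all intervals are closed on the left. Optionally removes
#' metformin-treated T2D samples, since the drug confounds gut microbiota
#' composition.
#'
#' @param metadata data.frame with columns `sample_id`, `phenotype`
#'   (`"T2D"`/`"control"`), `gender` (`"male"`/`"female"`), `age`, `bmi`,
#'   `metformin` (`"treated"`/`"untreated"`/`"unknown"`).
#' @param gender,age_band,bmi_band stratum selectors (band names as above).
#' @param exclude_metformin_treated drop metformin-treated T2D samples.
#' @return list with character vectors `control` and `t2d` of sample ids.
#' @export
stratify <- function(metadata, gender = "male", age_band = "mid",
                     bmi_band = "normal", exclude_metformin_treated = TRUE) {
  if (!age_band %in% names(AGE_BANDS)) {
    stop("unknown age band: ", age_band, " (expected ",
         paste(names(AGE_BANDS), collapse = "/"), ")", call. = FALSE)
  }
  if (!bmi_band %in% names(BMI_BANDS)) {
    stop("unknown BMI band: ", bmi_band, " (expected ",
         paste(names(BMI_BANDS), collapse = "/"), ")", call. = FALSE)
  }
  if (!gender %in% c("male", "female")) {
    stop("unknown gender: ", gender, call. = FALSE)
  }
  keep <- metadata$gender == gender &
    in_band(metadata$age, AGE_BANDS[[age_band]]) &
    in_band(metadata$bmi, BMI_BANDS[[bmi_band]])
  md <- metadata[keep, , drop = FALSE]
  t2d <- md$phenotype == "T2D"
  if (exclude_metformin_treated) t2d <- t2d & md$metformin != "treated"
  out <- list(control = md$sample_id[md$phenotype == "control"],
              t2d = md$sample_id[t2d])
  if (!length(out$control) || !length(out$t2d)) {
    warning("empty stratum for ", gender, "/", age_band, "/", bmi_band)
  }
  out
}

#' Build microbial entities from a cohort species list
#'
#' A microbial entity is a single species, a genus (all cohort species
#' sharing the genus label), or a metabolic clique: all cohort species that
#' import, export or degrade the same compound. Group entities require at
#' least two cohort members (a singleton group would duplicate its species
#' entity); host cells never form entities.
#'
#' @param network a `gut_network`.
#' @param species character vector of cohort species ids, all present in the
#'   network.
#' @return An `entity_set`: data.frame with columns `entity_id`, `kind`
#'   (`species`/`genus`/`clique`), `label`, `n_members`, and the member
#'   species in `attr(, "members")` (a named list).
#' @export
build_entities <- function(network, species) {
  unknown <- setdiff(species, network$organisms$id)
  if (length(unknown)) {
    stop("species not in network: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  org <- network$organisms
  species <- sort(unique(species[org$kind[match(species, org$id)] != "host_cell"]))
  members <- as.list(species)
  ids <- species
  kinds <- rep("species", length(species))
  labels <- org$name[match(species, org$id)]

  genus <- org$genus[match(species, org$id)]
  for (g in sort(unique(genus))) {
    mem <- species[genus == g]
    if (length(mem) < 2) next
    ids <- c(ids, paste0("genus:", g)); kinds <- c(kinds, "genus")
    labels <- c(labels, g); members <- c(members, list(mem))
  }

  lnk <- network$links[network$links$organism_id %in% species, , drop = FALSE]
  if (nrow(lnk)) {
    key <- paste(lnk$compound_id, lnk$mode, sep = ":")
    for (k in sort(unique(key))) {
      mem <- sort(unique(lnk$organism_id[key == k]))
      if (length(mem) < 2) next
      parts <- strsplit(k, ":", fixed = TRUE)[[1]]
      cname <- network$compounds$name[network$compounds$id == parts[1]]
      ids <- c(ids, paste0("clique:", k)); kinds <- c(kinds, "clique")
      labels <- c(labels, paste(cname, c(import = "importers",
                                         export = "exporters",
                                         degrade = "degraders")[parts[2]]))
      members <- c(members, list(mem))
    }
  }
  out <- data.frame(entity_id = ids, kind = kinds, label = unname(labels),
                    n_members = lengths(members), stringsAsFactors = FALSE)
  attr(out, "members") <- setNames(members, ids)
  class(out) <- c("entity_set", "data.frame")
  out
}

#' Member species of entities
#'
#' @param entities an `entity_set` (or an object carrying one, such as the
#'   result of [differential_entities()]).
#' @return named list of member-species character vectors.
#' @export
entity_members <- function(entities) {
  m <- attr(entities, "members")
  if (is.null(m)) stop("object carries no entity membership", call. = FALSE)
  m
}

#' Per-sample abundance of entities
#'
#' The relative abundance of a group entity in a sample is the sum of the
#' relative abundances of its member species. Member species absent from the
#' table contribute 0 (reported via a message); an entity with no member in
#' the table at all is an error.
#'
#' @param entities an `entity_set`.
#' @param abundance samples x species matrix.
#' @param entity_id optional single entity id; if given, a named vector for
#'   that entity is returned instead of the full matrix.
#' @return samples x entities matrix (or one column as a vector).
#' @export
entity_abundance <- function(entities, abundance, entity_id = NULL) {
  members <- entity_members(entities)
  if (!is.null(entity_id)) {
    if (!entity_id %in% names(members)) {
      stop("unknown entity: ", entity_id, call. = FALSE)
    }
    members <- members[entity_id]
  }
  absent <- setdiff(unique(unlist(members)), colnames(abundance))
  if (length(absent)) {
    gm_msg(sprintf("%d member species absent from abundance table contribute 0",
                   length(absent)))
  }
  out <- vapply(names(members), function(id) {
    mem <- intersect(members[[id]], colnames(abundance))
    if (!length(mem)) {
      stop("entity ", id, " has no member in the abundance table",
           call. = FALSE)
    }
    rowSums(abundance[, mem, drop = FALSE])
  }, numeric(nrow(abundance)))
  if (!is.null(entity_id)) out[, 1] else out
}

wilcox_p <- function(x, y) {
  n <- length(x) + length(y)
  exact <- n <= 12 && !anyDuplicated(c(x, y))
  suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Differentially abundant microbial entities
#'
#' Tests every entity for a relative-abundance difference between the T2D
#' and control groups with a two-sided Wilcoxon rank-sum test (exact
#' enumeration when the combined sample size is at most 12 and there are no
#' ties, otherwise the normal approximation with continuity and tie
#' correction) and controls the false discovery rate over all tested
#' entities with the Benjamini-Hochberg procedure. Entities with zero
#' variance across all samples are excluded (reported via a message). The
#' relative abundance change is `(mean_t2d - mean_control) / mean_control`,
#' clamped to `+/- rel_change_cap` when the control mean is 0.
#'
#' @param entities an `entity_set`.
#' @param abundance samples x species matrix.
#' @param groups list with sample-id vectors `control` and `t2d` (>= 2 each).
#' @param fdr FDR threshold for the `significant` flag (default 0.1).
#' @param rel_change_cap cap for the relative change when the control mean
#'   is 0 (default 10).
#' @return A `diff_entities` data.frame with columns `entity_id`, `kind`,
#'   `label`, `direction`, `p_value`, `q_value`, `mean_control`, `mean_t2d`,
#'   `rel_change`, `significant`; entity membership is carried along in
#'   `attr(, "members")`.
#' @export
differential_entities <- function(entities, abundance, groups, fdr = 0.1,
                                  rel_change_cap = 10) {
  stopifnot(is.list(groups), all(c("control", "t2d") %in% names(groups)))
  if (length(groups$control) < 2 || length(groups$t2d) < 2) {
    stop("need >= 2 samples per group", call. = FALSE)
  }
  ab <- entity_abundance(entities, abundance)
  ctrl <- ab[groups$control, , drop = FALSE]
  t2d <- ab[groups$t2d, , drop = FALSE]
  keep <- apply(rbind(ctrl, t2d), 2, function(v) length(unique(v)) > 1)
  if (any(!keep)) {
    gm_msg(sprintf("excluded %d zero-variance entities", sum(!keep)))
  }
  tested <- colnames(ab)[keep]
  p <- vapply(tested, function(id) wilcox_p(t2d[, id], ctrl[, id]), 0)
  q <- p.adjust(p, method = "BH")
  mc <- colMeans(ctrl[, tested, drop = FALSE])
  mt <- colMeans(t2d[, tested, drop = FALSE])
  rc <- ifelse(mc > 0, (mt - mc) / mc, sign(mt - mc) * rel_change_cap)
  if (any(mc == 0)) gm_msg("relative change clamped for entities absent in control")
  idx <- match(tested, entities$entity_id)
  out <- data.frame(entity_id = tested,
                    kind = entities$kind[idx],
                    label = entities$label[idx],
                    direction = ifelse(mt > mc, "abundant_in_T2D",
                                       "abundant_in_control"),
                    p_value = unname(p), q_value = unname(q),
                    mean_control = unname(mc), mean_t2d = unname(mt),
                    rel_change = unname(rc),
                    significant = unname(q < fdr),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "members") <- entity_members(entities)[tested]
  attr(out, "fdr") <- fdr
  class(out) <- c("diff_entities", "data.frame")
  out
}

#' Prune redundant differential entities
#'
#' Among group entities (genera and cliques) with identical member sets and
#' the same phenotype direction, only the one with the smallest q-value is
#' retained (ties broken by lexicographic entity id). Species entities are
#' always retained. This is a conservative stand-in for fuller
#' representative-entity selection; disable it by not calling this step.
#'
#' @param de a `diff_entities` data.frame.
#' @return the pruned `diff_entities`.
#' @export
prune_entities <- function(de) {
  if (!nrow(de)) stop("no entities to prune", call. = FALSE)
  members <- entity_members(de)
  sig <- paste(vapply(members[de$entity_id],
                      function(m) paste(sort(m), collapse = "|"), ""),
               de$direction)
  de_ord <- de[order(de$q_value, de$entity_id), , drop = FALSE]
  sig_ord <- sig[match(de_ord$entity_id, de$entity_id)]
  drop <- de_ord$kind != "species" & duplicated(sig_ord)
  keep_ids <- de_ord$entity_id[!drop]
  out <- de[de$entity_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "members") <- members[out$entity_id]
  attr(out, "fdr") <- attr(de, "fdr")
  class(out) <- class(de)
  out
}

#' Read sample metadata / abundance tables
#'
#' `read_metadata()` expects a TSV with columns `sample_id`, `phenotype`,
#' `gender`, `age`, `bmi`, `metformin`. `read_abundance()` expects a TSV of
#' species rows x sample columns (first column species id, header row of
#' sample ids) and returns the internal samples x species matrix.
#'
#' @param path file to read.
#' @return data.frame (metadata) or numeric matrix (abundance).
#' @export
read_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "phenotype", "gender", "age", "bmi", "metformin")
  missing <- setdiff(needed, names(md))
  if (length(missing)) {
    stop("metadata lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(md$age <= 0) || any(md$bmi <= 0)) {
    stop("age and bmi must be positive", call. = FALSE)
  }
  md
}

#' @rdname read_metadata
#' @export
read_abundance <- function(path) {
  tab <- read.delim(path, row.names = 1, check.names = FALSE)
  m <- t(as.matrix(tab))
  if (any(m < 0)) stop("negative abundances", call. = FALSE)
  if (any(rowSums(m) > 1 + 1e-6)) {
    stop("per-sample relative abundances exceed 1", call. = FALSE)
  }
  m
}

#' @rdname read_metadata
#' @param abundance samples x species matrix to write.
#' @export
write_abundance <- function(abundance, path) {
  tab <- as.data.frame(t(abundance))
  tab <- cbind(species_id = rownames(tab), tab)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
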