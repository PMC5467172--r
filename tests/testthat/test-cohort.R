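make_metadata <- function() {
  data.frame(
    sample_id = paste0("s", 1:8),
    phenotype = c("control", "control", "T2D", "T2D", "T2D", "control",
                  "T2D", "control"),
    gender = c("male", "male", "male", "male", "male", "female", "male",
               "male"),
    age = c(45, 44.9, 50, 65, 64.9, 50, 50, 50),
    bmi = c(22, 22, 24.9, 22, 25, 22, 18.5, 18.4),
    metformin = c("untreated", "untreated", "untreated", "untreated",
                  "treated", "untreated", "treated", "untreated"),
    stringsAsFactors = FALSE)
}

test_that("stratification applies half-open band boundaries", {
  md <- make_metadata()
  g <- stratify(md, "male", "mid", "normal")
  # s1: age 45 (mid, inclusive), bmi 22 -> control
  # s2: age 44.9 -> young, excluded; s4: age 65 -> old, excluded
  # s5: bmi 25 -> overweight, excluded; s8: bmi 18.4 -> underweight
  expect_equal(g$control, "s1")
  expect_equal(g$t2d, "s3")
  g2 <- stratify(md, "male", "mid", "normal",
                 exclude_metformin_treated = FALSE)
  # s7 (bmi 18.5 -> normal, inclusive) returns once metformin is not excluded
  expect_equal(g2$t2d, c("s3", "s7"))
  expect_warning(
    g3 <- stratify(md, "male", "mid", "underweight",
                   exclude_metformin_treated = TRUE),
    "empty stratum")
  expect_equal(g3$t2d, character(0))  # s8 is the only underweight sample
  expect_error(stratify(md, "male", "middle", "normal"), "unknown age band")
  expect_error(stratify(md, "male", "mid", "skinny"), "unknown BMI band")
  expect_warning(stratify(md, "female", "old", "normal"), "empty stratum")
})

test_that("metformin exclusion only removes treated T2D samples", {
  md <- make_metadata()
  md$metformin[1] <- "treated"  # a control sample; must not be dropped
  g <- stratify(md, "male", "mid", "normal")
  expect_true("s1" %in% g$control)
})

test_that("entities are species, multi-member genera, and metabolic cliques", {
  net <- toy_network()
  ents <- build_entities(net, c("bA", "bB", "bC", "bD"))
  members <- entity_members(ents)
  # 4 species entities; genus Gen1 has 2 members; butyrate exporters {bA,bB};
  # glc importers {bA,bB}; ace importers would need 2 members but only bC
  expect_equal(sum(ents$kind == "species"), 4)
  expect_equal(members[["genus:Gen1"]], c("bA", "bB"))
  expect_equal(members[["clique:but:export"]], c("bA", "bB"))
  expect_equal(members[["clique:glc:import"]], c("bA", "bB"))
  expect_false("clique:ace:import" %in% ents$entity_id)
  expect_false(any(grepl("Gen2|Gen3", ents$entity_id)))  # singleton genera
  expect_false("host1" %in% unlist(members))
  expect_error(build_entities(net, "missing"), "not in network")
})

test_that("synthetic entity counts match combinatorial bookkeeping", {
  gn <- generate_network(generator_spec(seed = 5))
  net <- gn$network
  sp <- net$organisms$id
  ents <- build_entities(net, sp)
  genus_tab <- table(net$organisms$genus)
  clique_tab <- table(paste(net$links$compound_id, net$links$mode))
  expect_equal(nrow(ents),
               length(sp) + sum(genus_tab >= 2) + sum(clique_tab >= 2))
})

test_that("entity abundance is the member sum, matching brute force", {
  net <- toy_network()
  ents <- build_entities(net, c("bA", "bB", "bC", "bD"))
  co <- tiny_cohort(seed = 2, n_species = 4)
  colnames(co$abundance) <- c("bA", "bB", "bC", "bD")
  ab <- quiet(entity_abundance(ents, co$abundance))
  expect_equal(ab[, "bA"], co$abundance[, "bA"])  # singleton = identity
  expect_equal(ab[, "genus:Gen1"],
               co$abundance[, "bA"] + co$abundance[, "bB"])
  one <- quiet(entity_abundance(ents, co$abundance,
                                entity_id = "clique:but:export"))
  expect_equal(one, co$abundance[, "bA"] + co$abundance[, "bB"])
  # random groups vs brute-force summation
  set.seed(9)
  for (rep in 1:10) {
    mem <- sample(colnames(co$abundance), sample(2:4, 1))
    brute <- apply(co$abundance[, mem, drop = FALSE], 1, sum)
    grp <- structure(data.frame(entity_id = "grp", kind = "clique",
                                label = "grp", n_members = length(mem)),
                     members = list(grp = mem),
                     class = c("entity_set", "data.frame"))
    expect_equal(quiet(entity_abundance(grp, co$abundance, "grp")), brute)
  }
  # entity with no member present errors
  ghost <- structure(data.frame(entity_id = "g", kind = "species",
                                label = "g", n_members = 1),
                     members = list(g = "absent_species"),
                     class = c("entity_set", "data.frame"))
  expect_error(quiet(entity_abundance(ghost, co$abundance)), "no member")
})

test_that("small-sample Wilcoxon p-values equal exhaustive enumeration", {
  net <- toy_network()
  ents <- build_entities(net, c("bA", "bB", "bC", "bD"))
  set.seed(31)
  for (rep in 1:5) {
    co <- tiny_cohort(seed = rep + 40, n_species = 4, n1 = 6, n2 = 5)
    colnames(co$abundance) <- c("bA", "bB", "bC", "bD")
    de <- quiet(differential_entities(ents, co$abundance, co$groups))
    for (id in de$entity_id) {
      v <- quiet(entity_abundance(ents, co$abundance, id))
      p_oracle <- oracle_wilcoxon_p(v[co$groups$t2d], v[co$groups$control])
      expect_equal(de$p_value[de$entity_id == id], p_oracle,
                   tolerance = 1e-12, info = id)
    }
  }
})

test_that("identical group distributions yield no discoveries", {
  net <- toy_network()
  ents <- build_entities(net, c("bA", "bB", "bC", "bD"))
  ab <- tiny_cohort(seed = 3, n_species = 4)$abundance
  colnames(ab) <- c("bA", "bB", "bC", "bD")
  # mirror the same sample values in both groups
  ab2 <- rbind(ab, ab)
  rownames(ab2) <- c(paste0("c", 1:11), paste0("t", 1:11))
  groups <- list(control = paste0("c", 1:11), t2d = paste0("t", 1:11))
  de <- quiet(differential_entities(ents, ab2, groups))
  expect_equal(sum(de$significant), 0)
  expect_true(all(de$p_value > 0.9))
})

test_that("q-values dominate p-values and discoveries nest across FDR levels", {
  spec <- generator_spec(seed = 13)
  gn <- generate_network(spec)
  co <- generate_cohort(spec, gn$network)
  ents <- build_entities(gn$network, colnames(co$abundance))
  de_strict <- quiet(differential_entities(ents, co$abundance, co$groups,
                                           fdr = 0.05))
  de_loose <- quiet(differential_entities(ents, co$abundance, co$groups,
                                          fdr = 0.2))
  expect_true(all(de_strict$q_value >= de_strict$p_value))
  expect_true(all(de_strict$entity_id[de_strict$significant] %in%
                    de_loose$entity_id[de_loose$significant]))
  # BH q-values are monotone in sorted p-values
  o <- order(de_strict$p_value)
  expect_true(all(diff(de_strict$q_value[o]) >= -1e-12))
})

test_that("Wilcoxon p is invariant under monotone abundance transforms", {
  spec <- generator_spec(seed = 17, n_species = 20)
  gn <- generate_network(spec)
  co <- generate_cohort(spec, gn$network)
  ents <- build_entities(gn$network, colnames(co$abundance))
  sp_only <- ents[ents$kind == "species", ]
  attr(sp_only, "members") <- entity_members(ents)[sp_only$entity_id]
  class(sp_only) <- class(ents)
  de1 <- quiet(differential_entities(sp_only, co$abundance, co$groups))
  de2 <- quiet(differential_entities(sp_only, sqrt(co$abundance), co$groups))
  expect_equal(de1$p_value, de2$p_value, tolerance = 1e-12)
})

test_that("direction and relative change follow the group means", {
  net <- toy_network()
  ents <- build_entities(net, c("bA", "bB"))
  ab <- matrix(c(0.1, 0.12, 0.11, 0.1, 0.3, 0.31, 0.29, 0.33,
                 0.2, 0.22, 0.21, 0.2, 0.1, 0.11, 0.09, 0.12),
               nrow = 8,
               dimnames = list(c(paste0("c", 1:4), paste0("t", 1:4)),
                               c("bA", "bB")))
  groups <- list(control = paste0("c", 1:4), t2d = paste0("t", 1:4))
  de <- quiet(differential_entities(ents, ab, groups))
  a <- de[de$entity_id == "bA", ]
  expect_equal(a$direction, "abundant_in_T2D")
  expect_equal(a$rel_change,
               (mean(ab[5:8, "bA"]) - mean(ab[1:4, "bA"])) / mean(ab[1:4, "bA"]))
  expect_equal(de$direction[de$entity_id == "bB"], "abundant_in_control")
  expect_lt(de$rel_change[de$entity_id == "bB"], 0)
})

test_that("pruning keeps one entity per identical member set and direction", {
  net <- toy_network()
  ents <- build_entities(net, c("bA", "bB", "bC", "bD"))
  co <- tiny_cohort(seed = 8, n_species = 4)
  colnames(co$abundance) <- c("bA", "bB", "bC", "bD")
  de <- quiet(differential_entities(ents, co$abundance, co$groups))
  # genus:Gen1, clique:but:export and clique:glc:import all have members
  # {bA, bB} and identical abundance vectors, hence identical direction
  pruned <- prune_entities(de)
  dup_ids <- c("genus:Gen1", "clique:but:export", "clique:glc:import")
  expect_equal(sum(pruned$entity_id %in% dup_ids), 1)
  expect_equal(sort(pruned$entity_id[pruned$kind == "species"]),
               sort(de$entity_id[de$kind == "species"]))
  # survivor is the lexicographically first id (all q equal here)
  expect_true("clique:but:export" %in% pruned$entity_id)
  expect_error(prune_entities(de[0, ]), "no entities")
})

test_that("abundance and metadata table I/O round trips", {
  co <- tiny_cohort(seed = 5)
  f <- tempfile(fileext = ".tsv")
  write_abundance(co$abundance, f)
  expect_equal(read_abundance(f), co$abundance)
  md <- make_metadata()
  fm <- tempfile(fileext = ".tsv")
  write.table(md, fm, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_metadata(fm), md)
})
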