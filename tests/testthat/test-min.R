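cross_feed_network <- function() {
  # A exports k; B imports k; X exports k; C and B co-import m
  quiet(gut_network(
    organisms = data.frame(id = c("A", "B", "C", "X"),
                           name = c("A", "B", "C", "X"), kind = "bacterium",
                           genus = c("gA", "gB", "gC", "gX")),
    compounds = data.frame(id = c("k", "m"), name = c("k", "m"),
                           kind = "small_molecule"),
    links = data.frame(
      organism_id = c("A", "B", "X", "B", "C", "X"),
      compound_id = c("k", "k", "k", "m", "m", "m"),
      mode = c("export", "import", "export", "import", "import", "export"))))
}

test_that("species influence matches hand-computed producer/consumer terms", {
  net <- cross_feed_network()
  n <- c(A = 1, B = 1, C = 1, X = 1)
  # B imports k (P_k = n_A + n_X = 2, C_k = 1 + n_B = 2) and m
  # (P_m = n_X = 1, C_m = 1 + n_B + n_C = 3)
  # A produces k only: W_AB = 1 / C_k = 1/2
  expect_equal(as.numeric(species_influence(net, "A", "B", n)), 0.5)
  # B consumes nothing A consumes and produces nothing: W_BA over K_A = {} = 0
  expect_equal(as.numeric(species_influence(net, "B", "A", n)), 0)
  # C co-imports m with B: W_CB = -P_m / C_m^2 = -1/9
  expect_equal(as.numeric(species_influence(net, "C", "B", n)), -1 / 9)
  # disjoint compound sets
  expect_equal(as.numeric(species_influence(net, "C", "A", n)), 0)
  # per-compound terms sum to the total
  w <- species_influence(net, "X", "B", n)
  expect_equal(sum(attr(w, "terms")), as.numeric(w), tolerance = 1e-12)
  expect_error(species_influence(net, "A", "A", n), "i == j")
  expect_error(species_influence(net, "A", "B", n, alpha = 0), "alpha")
  expect_error(species_influence(net, "zz", "B", n), "unknown organism")
})

test_that("species influence equals the finite-difference growth derivative", {
  set.seed(77)
  for (rep in 1:60) {
    sys <- random_system()
    ids <- sys$species
    if (length(ids) < 2) next
    pair <- sample(ids, 2)
    w <- as.numeric(species_influence(sys$network, pair[1], pair[2], sys$n))
    fd <- oracle_fd_influence(sys$network, pair[1], pair[2], sys$n)
    expect_lt(abs(w - fd), 1e-6)
  }
})

test_that("influence sign structure: producers promote, co-consumers inhibit", {
  set.seed(78)
  for (rep in 1:100) {
    sys <- random_system(with_macromolecule = FALSE)
    ids <- sys$species
    if (length(ids) < 2) next
    pair <- sample(ids, 2)
    lnk <- sys$network$links
    i_imp <- lnk$compound_id[lnk$organism_id == pair[1] & lnk$mode == "import"]
    i_exp <- lnk$compound_id[lnk$organism_id == pair[1] & lnk$mode == "export"]
    j_imp <- lnk$compound_id[lnk$organism_id == pair[2] & lnk$mode == "import"]
    w <- as.numeric(species_influence(sys$network, pair[1], pair[2], sys$n))
    if (!length(intersect(i_imp, j_imp))) expect_gte(w, 0)
    if (!length(intersect(i_exp, j_imp))) expect_lte(w, 0)
  }
})

test_that("influence vanishes monotonically as alpha grows", {
  net <- cross_feed_network()
  n <- c(A = 1, B = 1, C = 1, X = 1)
  alphas <- c(0.5, 1, 5, 50, 500)
  for (pair in list(c("A", "B"), c("C", "B"))) {
    w <- vapply(alphas, function(a)
      abs(as.numeric(species_influence(net, pair[1], pair[2], n, alpha = a))),
      0)
    expect_true(all(diff(w) < 0))
    # producer terms decay as 1/alpha, competition terms as 1/alpha^2
    expect_lt(w[length(w)], 0.01)
  }
})

test_that("group influence reduces to species influence and weights targets", {
  net <- cross_feed_network()
  n <- c(A = 1, B = 1, C = 3, X = 1)
  # singleton groups reproduce the species-level value
  expect_equal(as.numeric(group_influence(net, "A", "B", n)),
               as.numeric(species_influence(net, "A", "B", n)))
  # weighted sum: W_{X,{B,C}} with weights n_B/4, n_C/4, brute force
  w_xb <- as.numeric(species_influence(net, "X", "B", n))
  w_xc <- as.numeric(species_influence(net, "X", "C", n))
  expect_equal(as.numeric(group_influence(net, "X", c("B", "C"), n)),
               (1 / 4) * w_xb + (3 / 4) * w_xc, tolerance = 1e-12)
  # shared members are removed from the source side
  expect_equal(as.numeric(group_influence(net, c("A", "B"), "B", n)),
               as.numeric(species_influence(net, "A", "B", n)))
  expect_equal(as.numeric(group_influence(net, "B", c("B", "C"), n)), 0)
  expect_error(group_influence(net, "A", "B", c(A = 1, B = 0, C = 1, X = 1)),
               "zero total abundance")
})

test_that("group influence with singletons reproduces the full W matrix", {
  set.seed(79)
  sys <- random_system(n_species = 5, n_compounds = 4)
  ids <- sys$species
  for (i in ids) {
    for (j in setdiff(ids, i)) {
      expect_equal(as.numeric(group_influence(sys$network, i, j, sys$n)),
                   as.numeric(species_influence(sys$network, i, j, sys$n)),
                   tolerance = 1e-12)
    }
  }
})

min_fixture_inputs <- function(target_dir_flip = FALSE) {
  net <- cross_feed_network()
  samples <- c(paste0("c", 1:6), paste0("t", 1:6))
  groups <- list(control = paste0("c", 1:6), t2d = paste0("t", 1:6))
  set.seed(42)
  ab <- matrix(rlnorm(12 * 4, 0, 0.05), nrow = 12,
               dimnames = list(samples, c("A", "B", "C", "X")))
  # plant: A and B clearly more abundant in T2D (cross-feeding pair)
  ab[groups$t2d, "A"] <- ab[groups$t2d, "A"] * 3
  ab[groups$t2d, "B"] <- ab[groups$t2d, "B"] *
    (if (target_dir_flip) 1 / 3 else 3)
  ab <- ab / rowSums(ab)
  ents <- build_entities(net, c("A", "B", "C", "X"))
  sp_only <- ents[ents$kind == "species", ]
  attr(sp_only, "members") <- entity_members(ents)[sp_only$entity_id]
  class(sp_only) <- class(ents)
  de <- quiet(differential_entities(sp_only, ab, groups, fdr = 0.3))
  list(net = net, ab = ab, groups = groups, de = de)
}

test_that("phenotype-consistent filtering keeps explanatory edges only", {
  fx <- min_fixture_inputs()
  de <- fx$de
  expect_true(all(c("A", "B") %in% de$entity_id[de$significant]))
  mn <- quiet(build_min(de, fx$net, fx$ab, fx$groups))
  # A -> B cross-feeding edge: both abundant in T2D, positive influence
  eAB <- mn$edges[mn$edges$source == "A" & mn$edges$target == "B", ]
  expect_equal(nrow(eAB), 1)
  expect_gt(eAB$weight, 0)

  # same pair but target scarce in T2D: the positive edge is filtered out
  fx2 <- min_fixture_inputs(target_dir_flip = TRUE)
  mn2 <- quiet(build_min(fx2$de, fx2$net, fx2$ab, fx2$groups))
  expect_equal(nrow(mn2$edges[mn2$edges$source == "A" &
                                mn2$edges$target == "B", ]), 0)
  # unfiltered MIN is a superset of the filtered one
  mn2_all <- quiet(build_min(fx2$de, fx2$net, fx2$ab, fx2$groups,
                             min_config(edge_filter = "none")))
  expect_gte(nrow(mn2_all$edges), nrow(mn2$edges))
  key <- function(e) paste(e$source, e$target)
  expect_true(all(key(mn2$edges) %in% key(mn2_all$edges)))
})

test_that("MIN edges store per-compound terms that sum to the weight", {
  fx <- min_fixture_inputs()
  mn <- quiet(build_min(fx$de, fx$net, fx$ab, fx$groups,
                        min_config(edge_filter = "none")))
  expect_gt(nrow(mn$edges), 0)
  for (r in seq_len(nrow(mn$edges))) {
    key <- paste0(mn$edges$source[r], "->", mn$edges$target[r])
    expect_equal(sum(mn$contributions[[key]]), mn$edges$weight[r],
                 tolerance = 1e-9)
  }
  # no self loops; endpoints are nodes
  expect_false(any(mn$edges$source == mn$edges$target))
  expect_true(all(c(mn$edges$source, mn$edges$target) %in%
                    mn$nodes$entity_id))
})

test_that("entities sharing no compounds give an edgeless MIN", {
  net <- quiet(gut_network(
    organisms = data.frame(id = c("A", "B"), name = c("A", "B"),
                           kind = "bacterium", genus = c("gA", "gB")),
    compounds = data.frame(id = c("k1", "k2"), name = c("k1", "k2"),
                           kind = "small_molecule"),
    links = data.frame(organism_id = c("A", "B"),
                       compound_id = c("k1", "k2"), mode = "import")))
  samples <- c(paste0("c", 1:4), paste0("t", 1:4))
  groups <- list(control = paste0("c", 1:4), t2d = paste0("t", 1:4))
  set.seed(1)
  ab <- matrix(rlnorm(16, 0, 0.1), nrow = 8,
               dimnames = list(samples, c("A", "B")))
  ab[5:8, "A"] <- ab[5:8, "A"] * 3
  ab <- ab / rowSums(ab)
  ents <- build_entities(net, c("A", "B"))
  de <- quiet(differential_entities(ents, ab, groups, fdr = 0.5))
  mn <- quiet(build_min(de, net, ab, groups))
  expect_equal(nrow(mn$edges), 0)
})

test_that("host interaction candidates link direction- and capability-matched entities", {
  # butyrate exporters abundant in control + host imports butyrate
  net <- quiet(gut_network(
    organisms = data.frame(
      id = c("A", "B", "C", "D", "host1"),
      name = c("A", "B", "C", "D", "colonocyte"),
      kind = c(rep("bacterium", 4), "host_cell"),
      genus = c("gA", "gB", "gC", "gD", "")),
    compounds = data.frame(id = c("but", "k"), name = c("butyrate", "k"),
                           kind = "small_molecule"),
    links = data.frame(
      organism_id = c("A", "B", "host1", "A", "B", "C", "C", "D"),
      compound_id = c("but", "but", "but", "k", "k", "k", "but", "k"),
      mode = c("export", "export", "import", "import", "import", "import",
               "export", "import"))))
  samples <- c(paste0("c", 1:6), paste0("t", 1:6))
  groups <- list(control = paste0("c", 1:6), t2d = paste0("t", 1:6))
  set.seed(4)
  ab <- matrix(rlnorm(48, 0, 0.05), nrow = 12,
               dimnames = list(samples, c("A", "B", "C", "D")))
  ab[groups$control, c("A", "B", "C")] <- ab[groups$control, c("A", "B", "C")] * 2
  ab <- ab / rowSums(ab)
  ents <- build_entities(net, c("A", "B", "C", "D"))
  de <- quiet(differential_entities(ents, ab, groups, fdr = 0.9))
  mn <- quiet(build_min(de, net, ab, groups, min_config(edge_filter = "none")))
  hl <- host_interaction_candidates(de, net, mn)
  expect_true(nrow(hl) > 0)
  expect_true(all(hl$compound_id == "but"))
  expect_true(all(hl$host_id == "host1"))
  expect_true(all(hl$direction == "abundant_in_control"))
  # butyrate producers A, B (and C, which also exports butyrate) qualify;
  # each candidate must actually have a butyrate capability
  producers <- hl$entity_id[grepl("production", hl$entity_capability)]
  expect_true(all(c("A", "B") %in% hl$entity_id))
  expect_true(all(c("A", "B") %in% producers))

  # a network without host cells yields no candidates
  net_nohost <- cross_feed_network()
  fx <- min_fixture_inputs()
  expect_equal(nrow(host_interaction_candidates(fx$de, net_nohost,
                                                quiet(build_min(fx$de, net_nohost,
                                                                fx$ab, fx$groups)))),
               0)
})
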