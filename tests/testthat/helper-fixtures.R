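# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately written from first principles (loops, explicit
# enumeration) and never call the package functions they check.

quiet <- function(expr) {
  withCallingHandlers(expr, message = function(m) invokeRestart("muffleMessage"))
}

# Small hand-built network: 4 bacteria, 1 host cell, 3 small molecules,
# 1 macromolecule with 2 degradation products.
toy_network <- function() {
  quiet(gut_network(
    organisms = data.frame(
      id = c("bA", "bB", "bC", "bD", "host1"),
      name = c("Alpha", "Beta", "Gamma", "Delta", "colonocyte"),
      kind = c(rep("bacterium", 3), "archaeon", "host_cell"),
      genus = c("Gen1", "Gen1", "Gen2", "Gen3", ""),
      stringsAsFactors = FALSE),
    compounds = data.frame(
      id = c("but", "ace", "glc", "cel"),
      name = c("butyrate", "acetate", "D-glucose", "cellulose"),
      kind = c(rep("small_molecule", 3), "macromolecule"),
      stringsAsFactors = FALSE),
    links = data.frame(
      organism_id = c("bA", "bA", "bB", "bB", "bC", "bC", "bD", "host1"),
      compound_id = c("but", "glc", "but", "glc", "ace", "cel", "ace", "but"),
      mode = c("export", "import", "export", "import", "import", "degrade",
               "export", "import"),
      stringsAsFactors = FALSE),
    degradation = data.frame(
      macromolecule_id = c("cel", "cel"),
      product_id = c("glc", "ace"),
      stringsAsFactors = FALSE)))
}

# Random small bipartite system for influence-oracle checks.
random_system <- function(n_species = NULL, n_compounds = NULL,
                          with_macromolecule = TRUE) {
  ns <- if (is.null(n_species)) sample(2:6, 1) else n_species
  nc <- if (is.null(n_compounds)) sample(2:5, 1) else n_compounds
  sp <- paste0("s", seq_len(ns))
  cm <- paste0("c", seq_len(nc))
  use_macro <- with_macromolecule && nc >= 3 && runif(1) < 0.5
  kind <- rep("small_molecule", nc)
  degradation <- NULL
  links <- expand.grid(organism_id = sp, compound_id = cm,
                       stringsAsFactors = FALSE)
  if (use_macro) {
    kind[nc] <- "macromolecule"
    degradation <- data.frame(macromolecule_id = cm[nc],
                              product_id = sample(cm[-nc], 2))
    links$mode <- ifelse(links$compound_id == cm[nc], "degrade",
                         sample(c("import", "export"), nrow(links),
                                replace = TRUE))
  } else {
    links$mode <- sample(c("import", "export"), nrow(links), replace = TRUE)
  }
  links <- links[runif(nrow(links)) < 0.5, , drop = FALSE]
  net <- quiet(gut_network(
    organisms = data.frame(id = sp, name = sp, kind = "bacterium",
                           genus = paste0("g", seq_len(ns))),
    compounds = data.frame(id = cm, name = cm, kind = kind),
    links = links, degradation = degradation))
  list(network = net, species = sp,
       n = setNames(runif(ns, 0.05, 2), sp))
}

# Independent growth-model oracle: mu_j = sum over metabolites k consumed by
# j of P_k / C_k, with production including degradation products and
# consumption including degraded macromolecules; W_ij by central differences.
oracle_mu <- function(network, j, n, alpha) {
  produces <- function(org, k) {
    lnk <- network$links
    direct <- any(lnk$organism_id == org & lnk$compound_id == k &
                    lnk$mode == "export")
    via_deg <- FALSE
    degraded <- lnk$compound_id[lnk$organism_id == org & lnk$mode == "degrade"]
    for (m in degraded) {
      prods <- network$degradation$product_id[
        network$degradation$macromolecule_id == m]
      if (k %in% prods) via_deg <- TRUE
    }
    direct || via_deg
  }
  consumes <- function(org, k) {
    lnk <- network$links
    any(lnk$organism_id == org & lnk$compound_id == k &
          lnk$mode %in% c("import", "degrade"))
  }
  mu <- 0
  for (k in network$compounds$id) {
    if (!consumes(j, k)) next
    P <- 0; C <- alpha
    for (org in names(n)) {
      if (produces(org, k)) P <- P + n[[org]]
      if (consumes(org, k)) C <- C + n[[org]]
    }
    mu <- mu + P / C
  }
  mu
}

oracle_fd_influence <- function(network, i, j, n, alpha = 1, h = 1e-6) {
  np <- n; np[[i]] <- n[[i]] + h
  nm <- n; nm[[i]] <- n[[i]] - h
  (oracle_mu(network, j, np, alpha) - oracle_mu(network, j, nm, alpha)) / (2 * h)
}

# Exhaustive path oracle: hop distance by hand-rolled BFS, then DFS over all
# simple directed paths of exactly that length, averaging weight products.
oracle_bfs_dist <- function(edges, i, j) {
  dist <- 0
  frontier <- i
  seen <- i
  while (length(frontier)) {
    if (j %in% frontier) return(dist)
    nxt <- setdiff(unique(edges$target[edges$source %in% frontier]), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
    dist <- dist + 1
  }
  Inf
}

oracle_pair_influence <- function(min, i, j, normalization = "mean_abs") {
  edges <- min$edges
  if (!nrow(edges)) return(0)
  d <- oracle_bfs_dist(edges, i, j)
  if (!is.finite(d)) return(0)
  norm <- switch(normalization, mean_abs = mean(abs(edges$weight)),
                 max_abs = max(abs(edges$weight)))
  wkey <- setNames(edges$weight / norm, paste(edges$source, edges$target))
  prods <- numeric()
  dfs <- function(node, visited, prod) {
    if (node == j) {
      prods[length(prods) + 1] <<- prod
      return()
    }
    if (length(visited) - 1 >= d) return()
    for (v in edges$target[edges$source == node]) {
      if (v %in% visited) next
      dfs(v, c(visited, v), prod * wkey[[paste(node, v)]])
    }
  }
  dfs(i, i, 1)
  rc <- min$nodes$rel_change[min$nodes$entity_id == i]
  rc * mean(prods)
}

oracle_phi <- function(min, theta, normalization = "mean_abs") {
  ids <- min$nodes$entity_id
  phi <- setNames(integer(length(ids)), ids)
  for (i in ids) {
    for (j in setdiff(ids, i)) {
      if (abs(oracle_pair_influence(min, i, j, normalization)) >= theta) {
        phi[i] <- phi[i] + 1
      }
    }
  }
  phi
}

# Random MIN with signed weights for oracle equivalence checks.
random_min <- function(n_nodes = NULL, p_edge = 0.25) {
  m <- if (is.null(n_nodes)) sample(4:12, 1) else n_nodes
  ids <- paste0("e", seq_len(m))
  pairs <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pairs <- pairs[runif(nrow(pairs)) < p_edge, , drop = FALSE]
  pairs$weight <- runif(nrow(pairs), -1, 1)
  pairs$weight[pairs$weight == 0] <- 0.1
  nodes <- data.frame(entity_id = ids,
                      rel_change = runif(m, -2, 2), stringsAsFactors = FALSE)
  make_min(nodes, pairs)
}

# Exact two-sided Wilcoxon rank-sum p-value by enumeration of all
# C(n1+n2, n1) group labelings of the pooled sample (midranks for ties).
oracle_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  obs <- sum(r[seq_len(n1)])
  combos <- combn(length(pooled), n1)
  stats <- apply(combos, 2, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(stats <= obs), mean(stats >= obs)))
}

# Two-group cohort abundance fixture without the generator (for unit tests).
tiny_cohort <- function(seed = 1, n_species = 8, n1 = 6, n2 = 5) {
  set.seed(seed)
  sp <- paste0("sp", seq_len(n_species))
  samples <- c(paste0("c", seq_len(n1)), paste0("t", seq_len(n2)))
  ab <- matrix(rlnorm(length(samples) * n_species, 0, 0.5),
               nrow = length(samples), dimnames = list(samples, sp))
  ab <- ab / rowSums(ab)
  list(abundance = ab,
       groups = list(control = samples[seq_len(n1)],
                     t2d = samples[n1 + seq_len(n2)]))
}
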