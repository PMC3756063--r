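# Independent brute-force oracles and fixture builders.  These stay
# deliberately naive: adjacency by exhaustive pixel-pair scan, components
# by repeated neighbourhood sweeps, distances by hand-rolled BFS --
# different code paths from the igraph-based implementation under test.

# connected components of the subgraph induced by `ids`, by label
# propagation until fixpoint
oracle_components <- function(ids, edges) {
  if (!length(ids)) return(list())
  lab <- seq_along(ids)
  names(lab) <- as.character(ids)
  a <- as.character(edges$fiber_a)
  b <- as.character(edges$fiber_b)
  keep <- a %in% names(lab) & b %in% names(lab)
  a <- a[keep]; b <- b[keep]
  repeat {
    changed <- FALSE
    for (k in seq_along(a)) {
      la <- lab[[a[k]]]; lb <- lab[[b[k]]]
      if (la != lb) {
        lab[lab == max(la, lb)] <- min(la, lb)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(ids, lab), sort))
}

# all shortest-path distances from `from` to every fiber, by explicit BFS
oracle_bfs_dist <- function(from, ids, edges) {
  adj <- lapply(setNames(seq_along(ids), as.character(ids)),
                function(i) integer())
  for (k in seq_len(nrow(edges))) {
    a <- as.character(edges$fiber_a[k]); b <- as.character(edges$fiber_b[k])
    adj[[a]] <- c(adj[[a]], edges$fiber_b[k])
    adj[[b]] <- c(adj[[b]], edges$fiber_a[k])
  }
  d <- setNames(rep(Inf, length(ids)), as.character(ids))
  d[[as.character(from)]] <- 0
  frontier <- from
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) {
      for (w in adj[[as.character(v)]]) {
        if (is.infinite(d[[as.character(w)]])) {
          d[[as.character(w)]] <- d[[as.character(v)]] + 1
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  d
}

# isolated revertant fibers by all-pairs BFS
oracle_isolated <- function(graph, min_separation = 2) {
  rf <- sort(graph$fibers$fiber_id[graph$fibers$revertant])
  if (length(rf) <= 1) return(rf)
  ids <- graph$fibers$fiber_id
  iso <- logical(length(rf))
  for (i in seq_along(rf)) {
    d <- oracle_bfs_dist(rf[i], ids, graph$edges)
    others <- d[as.character(setdiff(rf, rf[i]))]
    iso[i] <- all(others >= min_separation + 1)
  }
  rf[iso]
}

# exhaustive pixel-pair adjacency scan of a label map
oracle_labelmap_edges <- function(m, connectivity = 4) {
  nr <- nrow(m); nc <- ncol(m)
  offs <- list(c(0, 1), c(1, 0))
  if (connectivity == 8) offs <- c(offs, list(c(1, 1), c(1, -1)))
  pairs <- character()
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    u <- m[r, cc]
    if (u == 0) next
    for (o in offs) {
      r2 <- r + o[1]; c2 <- cc + o[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      v <- m[r2, c2]
      if (v == 0 || v == u) next
      pairs <- c(pairs, paste(min(u, v), max(u, v)))
    }
  }
  unique(sort(pairs))
}

edge_key <- function(edges) {
  if (!nrow(edges)) return(character())
  sort(paste(pmin(edges$fiber_a, edges$fiber_b),
             pmax(edges$fiber_a, edges$fiber_b)))
}

# random fixtures ------------------------------------------------------

random_section_graph <- function(n, p_edge = 0.08, p_rev = 0.25,
                                 seed = 1, area = 2) {
  set.seed(seed)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p_edge
  edges <- data.frame(fiber_a = pairs[keep, 1], fiber_b = pairs[keep, 2])
  fibers <- data.frame(fiber_id = seq_len(n),
                       x_um = runif(n, 0, 500), y_um = runif(n, 0, 500),
                       csa_um2 = rlnorm(n, log(2000), 0.3),
                       revertant = runif(n) < p_rev)
  section_graph(paste0("rand", seed), fibers, edges, area)
}

random_label_map <- function(seed, max_dim = 32, max_labels = 12) {
  set.seed(seed)
  nr <- sample(2:max_dim, 1); nc <- sample(2:max_dim, 1)
  k <- sample(2:max_labels, 1)
  # labelled blobs: nearest of k random centres, with random background
  cy <- runif(k, 1, nr); cx <- runif(k, 1, nc)
  m <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    m[r, cc] <- which.min((r - cy)^2 + (cc - cx)^2)
  }
  m[matrix(runif(nr * nc) < 0.15, nr, nc)] <- 0L
  m
}

path_section <- function(rev, area = 1) {
  # path graph 1-2-...-n with given revertant flags
  n <- length(rev)
  fibers <- data.frame(fiber_id = 1:n, x_um = seq_len(n) * 50, y_um = 0,
                       csa_um2 = 2000, revertant = rev)
  edges <- if (n > 1) data.frame(fiber_a = 1:(n - 1), fiber_b = 2:n)
           else NULL
  section_graph("path", fibers, edges, area)
}

# direct trait-table simulator for the mixed-model tests: the model the
# fitter assumes, with known truth
simulate_trait_table <- function(n_mice_per_group = 10,
                                 muscles = c("TA", "D"),
                                 n_sections = 3,
                                 group_effects = c(0, 0, 0, 0),
                                 muscle_effects = NULL,
                                 mouse_sd = 1, resid_sd = 1,
                                 grand = 5, seed = 1) {
  set.seed(seed)
  if (is.null(muscle_effects))
    muscle_effects <- setNames(rep(0, length(muscles)), muscles)
  rows <- list()
  for (g in 1:4) for (m in seq_len(n_mice_per_group)) {
    mid <- sprintf("g%dm%02d", g, m)
    u <- rnorm(1, 0, mouse_sd)
    for (mus in muscles) for (s in seq_len(n_sections)) {
      rows[[length(rows) + 1L]] <- data.frame(
        mouse_id = mid, age_group = g, muscle = mus,
        section_id = sprintf("%s_%s_s%d", mid, mus, s),
        trait = "rf_per_mm2",
        value = grand + group_effects[g] + muscle_effects[[mus]] + u +
          rnorm(1, 0, resid_sd),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
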