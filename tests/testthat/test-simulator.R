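test_that("tessellations are deterministic, connected, hex-like", {
  t1 <- make_tessellation(100, seed = 4)
  t2 <- make_tessellation(100, seed = 4)
  expect_identical(t1, t2)
  expect_false(identical(t1, make_tessellation(100, seed = 5)))

  # single fiber: one node, no edges
  t0 <- make_tessellation(1, seed = 1)
  expect_equal(t0$n_fibers, 1)
  expect_equal(nrow(t0$edges), 0)
  expect_error(make_tessellation(0), ">= 1")

  for (s in 1:10) {
    tt <- make_tessellation(100, seed = s)
    deg <- 2 * nrow(tt$edges) / tt$n_fibers
    expect_gt(deg, 4); expect_lt(deg, 7)
    g <- igraph::graph_from_edgelist(as.matrix(tt$edges), directed = FALSE)
    expect_true(igraph::is_connected(g))
  }
  # areas log-normal around the configured mean
  tt <- make_tessellation(500, seed = 9, mean_csa_um2 = 2000)
  expect_equal(mean(tt$fibers$csa_um2), 2000, tolerance = 0.1)
})

test_that("simulate_reversion respects its source terms", {
  tess <- make_tessellation(150, seed = 2)
  off <- sim_config(founder_rate = 0, denovo_rate = 0)
  expect_equal(nrow(simulate_reversion(tess, off, 4, seed = 1)), 0)

  # no expansion: every clone stays a single fiber
  solo <- sim_config(founder_rate = 10, denovo_rate = 1,
                     expansion_prob = 0)
  for (g in c(1, 4)) {
    rev <- simulate_reversion(tess, solo, g, seed = g)
    expect_equal(anyDuplicated(rev$clone_id), 0)
  }

  # heart mode suppresses expansion regardless of expansion_prob
  hot <- sim_config(founder_rate = 10, denovo_rate = 1,
                    expansion_prob = 0.5)
  revh <- simulate_reversion(tess, hot, 4, seed = 3, muscle = "H")
  expect_equal(anyDuplicated(revh$clone_id), 0)
  # heart extents are cardiomyocyte-length
  expect_true(all(revh$z1 - revh$z0 <= 120 + 1e-9))

  # extents live inside the muscle and within the configured support
  cfg <- sim_config()
  rev <- simulate_reversion(tess, cfg, 4, seed = 7)
  expect_true(all(rev$z0 >= 0 & rev$z1 <= cfg$muscle_length_um))
  expect_true(all(rev$z1 > rev$z0))
})

test_that("founder counts are Poisson with the configured mean", {
  tess <- make_tessellation(400, seed = 3)
  cfg <- sim_config(founder_rate = 5, denovo_rate = 0,
                    expansion_prob = 0)
  n <- vapply(1:300, function(s)
    nrow(simulate_reversion(tess, cfg, 1, seed = s)), 0L)
  # mean within a 4-sigma band of Poisson(5)
  expect_equal(mean(n), 5, tolerance = 4 * sqrt(5 / 300) / 5)
  expect_gt(var(n), 5 * 0.6)   # and genuinely dispersed
  expect_lt(var(n), 5 * 1.6)
})

test_that("sections realize extent-interval overlap exactly", {
  tess <- make_tessellation(50, seed = 5)
  cfg <- sim_config(muscle_length_um = 2000)
  # hand-built reversion: one clone spanning 300 um mid-muscle
  rev <- data.frame(fiber_id = c(7L, 8L), clone_id = 1L,
                    z0 = c(850, 860), z1 = c(1150, 1160))
  for (s in 1:10) {
    secs <- sample_sections(tess, rev, cfg, seed = s, n_sections = 10)
    hits <- vapply(secs, function(g) sum(g$fibers$revertant), 0L)
    runs <- which(hits > 0)
    # a 300 um segment crosses 2-3 planes 120 um apart, consecutively
    expect_gte(length(runs), 2)
    expect_lte(length(runs), 3)
    expect_true(all(diff(runs) == 1))
    # overlap oracle: direct interval arithmetic per section
    for (g in secs) {
      zlo <- g$z_position; zhi <- zlo + cfg$section_thickness_um
      want <- rev$fiber_id[rev$z0 <= zhi & rev$z1 >= zlo]
      expect_setequal(g$fibers$fiber_id[g$fibers$revertant], want)
    }
  }
  # a short segment placed between planes can miss every section
  rev_miss <- data.frame(fiber_id = 1L, clone_id = 1L, z0 = 395, z1 = 405)
  secs <- sample_sections(tess, rev_miss, cfg, seed = 2, n_sections = 10)
  zs <- vapply(secs, function(g) g$z_position, 0)
  in_gap <- !any(rev_miss$z0 <= zs + cfg$section_thickness_um &
                 rev_miss$z1 >= zs)
  expect_equal(sum(vapply(secs, function(g) sum(g$fibers$revertant), 0L)) == 0,
               in_gap)

  short <- sim_config(muscle_length_um = 500)
  expect_error(sample_sections(tess, rev, short, n_sections = 10),
               "cannot hold")
})

test_that("random interval overlap matches the brute-force oracle", {
  cfg <- sim_config()
  tess <- make_tessellation(60, seed = 6)
  set.seed(99)
  for (r in 1:15) {
    k <- sample(1:12, 1)
    ctr <- runif(k, 0, cfg$muscle_length_um)
    ext <- runif(k, 50, 600)
    rev <- data.frame(fiber_id = sample(60, k), clone_id = seq_len(k),
                      z0 = pmax(0, ctr - ext / 2),
                      z1 = pmin(cfg$muscle_length_um, ctr + ext / 2))
    secs <- sample_sections(tess, rev, cfg, seed = r)
    for (g in secs) {
      zlo <- g$z_position; zhi <- zlo + cfg$section_thickness_um
      expect_setequal(g$fibers$fiber_id[g$fibers$revertant],
                      rev$fiber_id[rev$z0 <= zhi & rev$z1 >= zlo])
    }
  }
})

test_that("generate_cohort is deterministic and validates its design", {
  cfg <- sim_config(n_fibers = 120)
  des <- cohort_design(2, c("TA", "H"))
  c1 <- generate_cohort(cfg, des, master_seed = 8)
  c2 <- generate_cohort(cfg, des, master_seed = 8)
  expect_identical(c1$design, c2$design)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$sections[[1]]$fibers, c2$sections[[1]]$fibers)
  expect_false(identical(c1$truth,
                         generate_cohort(cfg, des, master_seed = 9)$truth))

  expect_equal(sort(unique(c1$design$age_group)), 1:4)
  expect_equal(sort(unique(c1$design$muscle)), c("H", "TA"))
  per <- table(c1$design$mouse_id, c1$design$muscle)
  expect_true(all(per >= 10 & per <= 12))

  dup <- rbind(des, des[1, ])
  expect_error(generate_cohort(cfg, dup, master_seed = 1), "duplicate")
  bad <- des; bad$age_group[1] <- 3
  expect_error(generate_cohort(cfg, bad, master_seed = 1),
               "two different age groups")
})

test_that("simulator functions leave the caller's RNG stream untouched", {
  set.seed(123); r1 <- runif(1)
  set.seed(123)
  invisible(make_tessellation(50, seed = 1))
  invisible(generate_cohort(sim_config(n_fibers = 60),
                            cohort_design(2, "TA"), master_seed = 1))
  expect_identical(runif(1), r1)
})

test_that("expected RF totals increase with the source rates", {
  tess <- make_tessellation(200, seed = 10)
  total <- function(cfg, seeds = 1:20, group = 3)
    mean(vapply(seeds, function(s)
      nrow(simulate_reversion(tess, cfg, group, seed = s)), 0L))
  base <- sim_config(founder_rate = 2, denovo_rate = 0.5,
                     expansion_prob = 0.02)
  expect_lt(total(base),
            total(sim_config(founder_rate = 8, denovo_rate = 0.5,
                             expansion_prob = 0.02)))
  expect_lt(total(base),
            total(sim_config(founder_rate = 2, denovo_rate = 2.5,
                             expansion_prob = 0.02)))
  expect_lt(total(base),
            total(sim_config(founder_rate = 2, denovo_rate = 0.5,
                             expansion_prob = 0.15)))
})

test_that("clustering percentage grows with elapsed cycles", {
  # expansion on, no de-novo inflow: clustered share rises with age
  cfg <- sim_config(founder_rate = 12, denovo_rate = 0,
                    expansion_prob = 0.05)
  pct_at <- function(group) {
    vals <- c()
    for (s in 1:8) {
      tess <- make_tessellation(300, seed = s)
      rev <- simulate_reversion(tess, cfg, group, seed = 100 + s)
      secs <- sample_sections(tess, rev, cfg, seed = 200 + s)
      for (g in secs) {
        st <- section_traits(g, include_isolated = FALSE,
                             empty_section_policy = "drop")
        vals <- c(vals, st$pct_clustered)
      }
    }
    mean(vals, na.rm = TRUE)
  }
  p1 <- pct_at(1); p4 <- pct_at(4)
  expect_gt(p4, p1)
})

test_that("quantify reproduces the generator's ground truth exactly", {
  cfg <- sim_config(n_fibers = 250)
  coh <- generate_cohort(cfg, cohort_design(2, c("TA", "SOL", "H")),
                         master_seed = 14)
  tt <- trait_table(coh$sections, coh$design)
  wide <- data.table::dcast(data.table::as.data.table(tt),
                            section_id ~ trait, value.var = "value")
  m <- merge(wide, coh$truth, by = "section_id",
             suffixes = c("_q", "_t"))
  expect_equal(nrow(m), nrow(coh$truth))
  for (cl in c("n_rf", "n_singleton", "n_small", "n_medium", "n_large",
               "n_very_large")) {
    expect_identical(as.integer(m[[paste0(cl, "_q")]]),
                     as.integer(m[[paste0(cl, "_t")]]),
                     label = cl)
  }
  # and the explicit size multisets agree with find_clusters
  for (sid in sample(coh$design$section_id, 20)) {
    cs <- find_clusters(coh$sections[[sid]])
    truth_sizes <- coh$truth$cluster_sizes[coh$truth$section_id == sid]
    got <- paste(sort(cs$sizes, decreasing = TRUE), collapse = ",")
    expect_identical(got, truth_sizes, label = sid)
  }
})
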