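test_that("cluster size classes follow the 1/2-4/5-8/9-17/>17 convention", {
  expect_equal(as.character(classify_cluster_size(c(1, 2, 4, 5, 8, 9, 17, 18, 61))),
               c("singleton", "small", "small", "medium", "medium",
                 "large", "large", "very_large", "very_large"))
  expect_error(classify_cluster_size(0), ">= 1")
  expect_error(classify_cluster_size(c(3, -1)), ">= 1")
})

test_that("find_clusters merges adjacent revertants only", {
  # chain of adjacent RFs is one cluster
  g <- path_section(c(TRUE, TRUE, TRUE))
  cs <- find_clusters(g)
  expect_equal(cs$clusters, list(1:3))
  expect_equal(cs$n_rf, 3)

  # a negative fiber between two RFs keeps them apart
  g2 <- path_section(c(TRUE, FALSE, TRUE))
  cs2 <- find_clusters(g2)
  expect_equal(cs2$sizes, c(1L, 1L))
  expect_setequal(unlist(cs2$clusters), c(1, 3))

  # no revertants: empty cluster set
  cs3 <- find_clusters(path_section(c(FALSE, FALSE)))
  expect_equal(cs3$n_rf, 0)
  expect_length(cs3$clusters, 0)
})

test_that("find_clusters agrees with the component oracle on random graphs", {
  for (s in 1:50) {
    g <- random_section_graph(n = sample(5:50, 1), seed = s)
    rf <- g$fibers$fiber_id[g$fibers$revertant]
    got <- find_clusters(g)$clusters
    want <- oracle_components(rf, g$edges)
    key <- function(cl) sort(vapply(cl, function(x)
      paste(x, collapse = ","), ""))
    expect_identical(key(got), key(want), label = paste("seed", s))
  }
})

test_that("count_isolated applies the >=2 intervening fibers rule", {
  # a lone RF has no revertant neighbour: isolated
  expect_equal(count_isolated(path_section(c(FALSE, TRUE, FALSE))), 2L)
  # one intervening fiber is not enough (A-B-C-D-E, RFs A and C)
  g <- path_section(c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_length(count_isolated(g), 0)
  # two intervening fibers qualify both ends (A-B-C-D, RFs A and D)
  g2 <- path_section(c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(count_isolated(g2), c(1L, 4L))
  # adjacent RFs are never isolated
  expect_length(count_isolated(path_section(c(TRUE, TRUE))), 0)
  expect_error(count_isolated(g2, min_separation = 0), "min_separation")
})

test_that("count_isolated matches the all-pairs BFS oracle", {
  for (s in 1:40) {
    g <- random_section_graph(n = sample(5:50, 1), seed = s + 500)
    for (ms in c(1, 2, 3)) {
      expect_identical(count_isolated(g, ms), oracle_isolated(g, ms),
                       label = paste("seed", s, "min_sep", ms))
    }
  }
})

test_that("raising min_separation never adds isolated fibers", {
  for (s in 1:15) {
    g <- random_section_graph(n = 40, seed = s + 900)
    prev <- count_isolated(g, 1)
    for (ms in 2:4) {
      cur <- count_isolated(g, ms)
      expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("section_traits computes the documented quantities", {
  # zero revertants, 3 mm2
  g0 <- section_graph("e", data.frame(fiber_id = 1:2, x_um = 0, y_um = 0,
                                      csa_um2 = 1000, revertant = FALSE),
                      NULL, 3)
  st0 <- section_traits(g0)
  expect_equal(st0$n_rf, 0)
  expect_equal(st0$rf_per_mm2, 0)
  expect_equal(st0$pct_clustered, 0)
  expect_true(is.na(section_traits(g0, empty_section_policy = "drop")$pct_clustered))

  # 5 RFs in 2 mm2
  g5 <- section_graph("f", data.frame(fiber_id = 1:5, x_um = 0, y_um = 0,
                                      csa_um2 = 1000, revertant = TRUE),
                      NULL, 2)
  expect_equal(section_traits(g5)$rf_per_mm2, 2.5)

  # one pair + one singleton: two thirds clustered
  g3 <- path_section(c(TRUE, TRUE, FALSE, TRUE))
  st3 <- section_traits(g3)
  expect_equal(st3$pct_clustered, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(st3$n_singleton, 1)
  expect_equal(st3$n_small, 1)
  expect_equal(st3$max_cluster_size, 2)

  bad <- g3; bad$section_area_mm2 <- 0
  expect_error(section_traits(bad), "section_area_mm2")
})

test_that("cluster sizes always sum to n_rf and pct stays in [0,100]", {
  for (s in 1:30) {
    g <- random_section_graph(n = sample(3:60, 1), seed = s + 2000,
                              p_rev = runif(1, 0, 0.6))
    cs <- find_clusters(g)
    expect_equal(sum(cs$sizes), cs$n_rf)
    st <- section_traits(g)
    expect_gte(st$pct_clustered, 0)
    expect_lte(st$pct_clustered, 100)
    expect_gte(st$rf_per_mm2, 0)
    expect_lte(st$n_isolated, st$n_singleton)
  }
})

test_that("adding one revertant call perturbs counts canonically", {
  for (s in 1:15) {
    g <- random_section_graph(n = 30, seed = s + 3000, p_rev = 0.3)
    neg <- which(!g$fibers$revertant)
    if (!length(neg)) next
    before <- find_clusters(g)
    g$fibers$revertant[sample(neg, 1)] <- TRUE
    after <- find_clusters(g)
    expect_equal(after$n_rf, before$n_rf + 1)
    expect_lte(length(after$clusters), length(before$clusters) + 1)
  }
})

test_that("aggregate_traits averages sections, then mice, then groups", {
  traits <- data.frame(
    mouse_id = "m1", age_group = 1, muscle = "TA",
    section_id = c("s1", "s2"), trait = "rf_per_mm2", value = c(2, 4))
  agg <- aggregate_traits(traits)
  expect_equal(agg$per_mouse$value, 3)
  expect_equal(agg$per_group$mean, 3)
  expect_equal(agg$grand$grand_mean_groups, 3)

  # flat recomputation oracle on a small two-mouse layout
  traits2 <- rbind(traits, data.frame(
    mouse_id = "m2", age_group = 1, muscle = "TA",
    section_id = c("t1", "t2", "t3"), trait = "rf_per_mm2",
    value = c(1, 2, 6)))
  agg2 <- aggregate_traits(traits2)
  expect_equal(agg2$per_group$mean, mean(c(mean(c(2, 4)), mean(c(1, 2, 6)))))
  expect_equal(agg2$grand$grand_mean_sections, mean(c(2, 4, 1, 2, 6)))
  expect_equal(agg2$per_group$sd, sd(c(3, 3)))
})

test_that("reference grand means reproduce the printed low/high densities", {
  ref <- read.csv(system.file("extdata", "mdx_reference_densities.csv",
                              package = "revfiber"))
  d <- grand_mean(ref$mean_rf_per_mm2[ref$muscle == "D"])
  sol <- grand_mean(ref$mean_rf_per_mm2[ref$muscle == "SOL"])
  expect_equal(round(d, 1), 2.4)
  expect_equal(round(sol, 1), 4.4)
  expect_equal(d, 2.385, tolerance = 1e-12)
})

test_that("trait_table joins design keys and reshapes long", {
  g1 <- path_section(c(TRUE, TRUE, FALSE))
  g1$section_id <- "a"
  g2 <- path_section(c(FALSE, FALSE, FALSE))
  g2$section_id <- "b"
  design <- data.frame(section_id = c("a", "b"), mouse_id = "m1",
                       age_group = 2, muscle = "TA")
  tt <- trait_table(list(g1, g2), design)
  expect_setequal(unique(tt$trait),
                  c("n_rf", "rf_per_mm2", "pct_clustered", "n_isolated",
                    "n_singleton", "n_small", "n_medium", "n_large",
                    "n_very_large", "max_cluster_size"))
  expect_equal(nrow(tt), 2 * 10)
  expect_equal(tt$value[tt$section_id == "a" & tt$trait == "n_rf"], 2)
  expect_error(trait_table(list(g1), design[, -2]), "mouse_id")
})
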