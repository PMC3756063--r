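## Per-section revertant-fiber statistics: clusters, size classes,
## isolated fibers, densities, and cohort-level aggregation.

#' Cluster size class labels, in order
#' @format Character vector.
#' @export
SIZE_CLASSES <- c("singleton", "small", "medium", "large", "very_large")

#' Classify a cluster by its size
#'
#' Size classes follow the standard reporting convention for revertant
#' fiber clusters: 1 fiber is a singleton (not a cluster proper), 2-4
#' fibers a small cluster, 5-8 medium, 9-17 large, 18 or more very large.
#'
#' @param size integer vector of cluster cardinalities, each >= 1.
#' @return factor with levels [SIZE_CLASSES].
#' @examples
#' classify_cluster_size(c(1, 4, 5, 17, 18))
#' @export
classify_cluster_size <- function(size) {
  size <- as.integer(size)
  if (any(is.na(size) | size < 1L))
    stop("cluster `size` must be >= 1", call. = FALSE)
  cut(size, breaks = c(0, 1, 4, 8, 17, Inf), labels = SIZE_CLASSES)
}

#' Find revertant-fiber clusters in a section
#'
#' Revertant fibers adjacent to each other belong to a single cluster:
#' clusters are the connected components of the subgraph induced by the
#' revertant fibers on the section adjacency graph.  Every revertant
#' fiber falls in exactly one cluster; singletons are size-1 components.
#'
#' @param graph a \code{section_graph}.
#' @return An object of class \code{cluster_set}: list with
#'   \code{clusters} (list of integer fiber-id vectors), \code{sizes},
#'   \code{size_class} (see [classify_cluster_size()]) and \code{n_rf}.
#' @export
find_clusters <- function(graph) {
  stopifnot(inherits(graph, "section_graph"))
  rf <- graph$fibers$fiber_id[graph$fibers$revertant]
  if (!length(rf)) {
    return(structure(list(clusters = list(), sizes = integer(),
                          size_class = classify_cluster_size(integer(0) + 1L)[0],
                          n_rf = 0L),
                     class = "cluster_set"))
  }
  e <- graph$edges
  keep <- e$fiber_a %in% rf & e$fiber_b %in% rf
  ids <- as.character(rf)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (any(keep))
    g <- igraph::add_edges(
      g, rbind(match(as.character(e$fiber_a[keep]), ids),
               match(as.character(e$fiber_b[keep]), ids)))
  comp <- igraph::components(g)
  clusters <- split(rf, comp$membership)
  clusters <- unname(lapply(clusters, sort))
  sizes <- lengths(clusters)
  o <- order(-sizes, vapply(clusters, min, 0L))
  clusters <- clusters[o]
  sizes <- sizes[o]
  structure(list(clusters = clusters, sizes = as.integer(sizes),
                 size_class = classify_cluster_size(sizes),
                 n_rf = length(rf)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d revertant fibers in %d components\n",
              x$n_rf, length(x$clusters)))
  if (length(x$sizes))
    print(table(x$size_class))
  invisible(x)
}

#' Isolated revertant fibers
#'
#' A revertant fiber is isolated when it is separated from every other
#' revertant fiber by at least \code{min_separation} intervening
#' (dystrophin-negative) fibers, i.e. its shortest-path distance on the
#' full fiber adjacency graph to every other revertant fiber is at least
#' \code{min_separation + 1}.  With the default 2 this is graph distance
#' >= 3, the usual operational definition of a seemingly newly formed
#' fiber rather than a remnant of an existing cluster.  A section whose
#' only revertant fiber has no revertant neighbour at all (including the
#' single-RF section) yields that fiber as isolated; unreachable fibers
#' (disconnected tissue) count as infinitely separated.
#'
#' @param graph a \code{section_graph}.
#' @param min_separation minimum number of intervening negative fibers
#'   (>= 1; default 2).
#' @param full_igraph optional precomputed [igraph] of the whole section
#'   (internal use; avoids rebuilding in tight loops).
#' @return Integer vector of isolated fiber ids (sorted).
#' @export
count_isolated <- function(graph, min_separation = 2, full_igraph = NULL) {
  stopifnot(inherits(graph, "section_graph"))
  if (!is.numeric(min_separation) || min_separation < 1)
    stop("`min_separation` must be >= 1", call. = FALSE)
  rf <- sort(graph$fibers$fiber_id[graph$fibers$revertant])
  if (length(rf) <= 1L)
    return(rf)
  g <- if (is.null(full_igraph)) section_igraph(graph) else full_igraph
  vn <- match(as.character(rf), igraph::V(g)$name)
  d <- igraph::distances(g, v = vn, to = vn)
  diag(d) <- Inf
  nearest <- apply(d, 1L, min)
  rf[nearest >= min_separation + 1]
}

#' Per-section revertant-fiber traits
#'
#' Computes all per-section summary statistics: total revertant fiber
#' count, density per mm2 of section area, percentage of revertant fibers
#' lying in clusters of two or more, the number of isolated fibers (see
#' [count_isolated()]), counts of clusters per size class, and the
#' largest cluster size.
#'
#' \code{pct_clustered} for a section with zero revertant fibers is 0
#' under the default \code{empty_section_policy = "zero"}; \code{"drop"}
#' returns NA so the section is excluded from averages (dropping biases
#' per-muscle means toward RF-rich sections, hence not the default).
#'
#' @param graph a \code{section_graph} with positive area.
#' @param min_separation passed to [count_isolated()].
#' @param empty_section_policy \code{"zero"} or \code{"drop"}.
#' @param include_isolated set \code{FALSE} to skip the isolation
#'   computation (reported as NA); useful in large simulation sweeps
#'   that only consume density and clustering traits.
#' @param full_igraph optional precomputed igraph of the section.
#' @return One-row data frame with columns \code{section_id, n_rf,
#'   rf_per_mm2, pct_clustered, n_isolated, n_singleton, n_small,
#'   n_medium, n_large, n_very_large, max_cluster_size}.
#' @export
section_traits <- function(graph, min_separation = 2,
                           empty_section_policy = "zero",
                           include_isolated = TRUE,
                           full_igraph = NULL) {
  empty_section_policy <- empty_section_policy[1]
  if (!empty_section_policy %in% c("zero", "drop"))
    stop("`empty_section_policy` must be \"zero\" or \"drop\"",
         call. = FALSE)
  stopifnot(inherits(graph, "section_graph"))
  if (is.na(graph$section_area_mm2) || graph$section_area_mm2 <= 0)
    stop("section ", graph$section_id, ": section_area_mm2 must be > 0",
         call. = FALSE)
  cs <- find_clusters(graph)
  n_rf <- cs$n_rf
  class_counts <- table(cs$size_class)
  pct <- if (n_rf > 0) {
    100 * sum(cs$sizes[cs$sizes >= 2L]) / n_rf
  } else if (empty_section_policy == "zero") 0 else NA_real_
  iso <- if (include_isolated)
    length(count_isolated(graph, min_separation,
                          full_igraph = full_igraph))
  else NA_integer_
  # constructed without data.frame() -- this sits in tight cohort loops
  structure(list(
    section_id = graph$section_id,
    n_rf = n_rf,
    rf_per_mm2 = n_rf / graph$section_area_mm2,
    pct_clustered = pct,
    n_isolated = iso,
    n_singleton = as.integer(class_counts[["singleton"]]),
    n_small = as.integer(class_counts[["small"]]),
    n_medium = as.integer(class_counts[["medium"]]),
    n_large = as.integer(class_counts[["large"]]),
    n_very_large = as.integer(class_counts[["very_large"]]),
    max_cluster_size = if (length(cs$sizes)) max(cs$sizes) else 0L),
    class = "data.frame", row.names = 1L)
}

#' Long-format trait table for a collection of sections
#'
#' Runs [section_traits()] on every section and joins the study design,
#' yielding the long table consumed by [aggregate_traits()] and
#' [fit_repeated_measures()].
#'
#' @param sections list of \code{section_graph}s.
#' @param design data frame with one row per section: \code{section_id,
#'   mouse_id, age_group, muscle}.  Every section must appear.
#' @param ... passed to [section_traits()].
#' @return Data frame with columns \code{mouse_id, age_group, muscle,
#'   section_id, trait, value}.
#' @export
trait_table <- function(sections, design, ...) {
  design <- as.data.frame(design)
  need <- c("section_id", "mouse_id", "age_group", "muscle")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("`design` lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  # sections cut from one muscle share the same edge table object; reuse
  # the igraph across them instead of rebuilding per section
  last_edges <- NULL
  last_g <- NULL
  per_sec <- data.table::rbindlist(lapply(sections, function(s) {
    if (is.null(last_g) || !identical(s$edges, last_edges)) {
      last_edges <<- s$edges
      last_g <<- section_igraph(s)
    }
    section_traits(s, ..., full_igraph = last_g)
  }))
  dt <- data.table::as.data.table(design[, need])
  dt <- merge(dt, per_sec, by = "section_id")
  if (nrow(dt) < length(sections))
    warning("some sections missing from `design` were dropped")
  meas <- setdiff(names(dt), need)
  for (cl in meas) dt[[cl]] <- as.numeric(dt[[cl]])
  long <- data.table::melt(
    dt, id.vars = need, variable.name = "trait", value.name = "value",
    variable.factor = FALSE)
  data.table::setcolorder(
    long, c("mouse_id", "age_group", "muscle", "section_id", "trait",
            "value"))
  as.data.frame(long)
}

#' Aggregate per-section traits to mouse, group and grand summaries
#'
#' Per mouse and muscle, each trait is the mean of its 10-12 section
#' values; group-level summaries are the mean and standard deviation of
#' these per-mouse values (the layout of a per-muscle-by-age-group
#' summary grid).  Grand per-muscle means across age groups are reported
#' two ways: \code{grand_mean_groups}, the unweighted mean of the four
#' group means, and \code{grand_mean_sections}, the flat mean over all
#' sections - the two differ when group sizes differ.
#'
#' @param traits long trait table from [trait_table()].
#' @return List with data frames \code{per_mouse} (mouse x muscle x
#'   trait means), \code{per_group} (muscle x age_group x trait: n, mean,
#'   sd) and \code{grand} (muscle x trait: both grand means).  Empty
#'   mouse-muscle cells are omitted with a warning.
#' @export
aggregate_traits <- function(traits) {
  dt <- data.table::as.data.table(traits)
  need <- c("mouse_id", "age_group", "muscle", "trait", "value")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("`traits` lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  n_na <- sum(is.na(dt[["value"]]))
  if (n_na)
    warning(n_na, " NA trait value(s) dropped from aggregation")
  dt <- dt[!is.na(dt[["value"]])]
  per_mouse <- dt[, list(value = mean(value)),
                  by = c("mouse_id", "age_group", "muscle", "trait")]
  per_group <- per_mouse[, list(n_mice = .N, mean = mean(value),
                                sd = sd(value)),
                         by = c("muscle", "age_group", "trait")]
  grand_g <- per_group[, list(grand_mean_groups = mean(mean)),
                       by = c("muscle", "trait")]
  grand_s <- dt[, list(grand_mean_sections = mean(value)),
                by = c("muscle", "trait")]
  grand <- merge(grand_g, grand_s, by = c("muscle", "trait"))
  list(per_mouse = as.data.frame(per_mouse),
       per_group = as.data.frame(per_group[order(muscle, age_group)]),
       grand = as.data.frame(grand))
}

#' Grand mean of per-group means
#'
#' Utility for reproducing a grand density from a row of group means,
#' e.g. the mean over the four age-group means of a muscle.
#'
#' @param group_means numeric vector of per-group means.
#' @return Their unweighted mean.
#' @examples
#' grand_mean(c(0.91, 1.37, 2.9, 4.36))  # 2.385, printed as 2.4
#' @export
grand_mean <- function(group_means) {
  if (!is.numeric(group_means) || !length(group_means))
    stop("`group_means` must be a non-empty numeric vector", call. = FALSE)
  mean(group_means)
}
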