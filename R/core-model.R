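## Core domain types: fiber tables, per-section adjacency graphs, and the
## positivity rule.  A "section graph" is a plain S3 list so it serializes
## to CSV losslessly; heavy graph work converts to igraph on demand.

#' Call a fiber revertant from its membrane stain fraction
#'
#' A fiber counts as revertant only when essentially its whole membrane
#' circumference is dystrophin positive.  A small tolerance absorbs
#' rasterization of the membrane: with the default 0.01, a fiber is called
#' revertant when at least 99\% of its circumference is stained.
#'
#' @param stain_fraction numeric vector in [0, 1]; fraction of the membrane
#'   circumference that is dystrophin positive.  NA yields NA.
#' @param tolerance single numeric in [0, 0.05]; permitted unstained
#'   fraction.
#' @return logical vector: \code{stain_fraction >= 1 - tolerance}.
#' @examples
#' call_revertant(c(1, 0.995, 0.5, 0))
#' @export
call_revertant <- function(stain_fraction, tolerance = 0.01) {
  if (!is.numeric(stain_fraction))
    stop("`stain_fraction` must be numeric", call. = FALSE)
  bad <- !is.na(stain_fraction) &
    (stain_fraction < 0 | stain_fraction > 1)
  if (any(bad))
    stop("`stain_fraction` out of [0, 1]: ",
         paste(utils::head(stain_fraction[bad], 3), collapse = ", "),
         call. = FALSE)
  if (!is.numeric(tolerance) || length(tolerance) != 1L ||
      is.na(tolerance) || tolerance < 0 || tolerance > 0.05)
    stop("`tolerance` must be a single value in [0, 0.05]", call. = FALSE)
  stain_fraction >= 1 - tolerance
}

#' Construct a per-section fiber graph
#'
#' Bundles the fibers of one transverse section with their adjacency edges
#' and the section area.  Fibers are rows of a data frame with columns
#' \code{fiber_id} (positive integer, unique), \code{x_um}, \code{y_um}
#' (centroid, micrometres), \code{csa_um2} (cross-sectional area, > 0),
#' optionally \code{stain_fraction} in [0, 1], and \code{revertant}
#' (logical).  When \code{revertant} is absent it is derived from
#' \code{stain_fraction} via [call_revertant()].
#'
#' @param section_id scalar identifier (coerced to character).
#' @param fibers data frame as described above.
#' @param edges data frame (or 2-column matrix) of unordered adjacent
#'   fiber-id pairs, columns \code{fiber_a}, \code{fiber_b}.  Self edges
#'   and duplicates are rejected by [validate_section()].
#' @param section_area_mm2 section area in mm2, > 0.  May exceed the fiber
#'   union (interstitium).
#' @param z_position position of the section along the muscle axis (um);
#'   optional.
#' @param tolerance passed to [call_revertant()] when deriving calls.
#' @return An object of class \code{section_graph}.
#' @seealso [validate_section()], [graph_from_labelmap()]
#' @export
section_graph <- function(section_id, fibers, edges, section_area_mm2,
                          z_position = NA_real_, tolerance = 0.01) {
  fibers <- as.data.frame(fibers)
  need <- c("fiber_id", "x_um", "y_um", "csa_um2")
  miss <- setdiff(need, names(fibers))
  if (length(miss))
    stop("`fibers` lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"stain_fraction" %in% names(fibers))
    fibers$stain_fraction <- NA_real_
  if (!"revertant" %in% names(fibers)) {
    fibers$revertant <- call_revertant(fibers$stain_fraction, tolerance)
    fibers$revertant[is.na(fibers$revertant)] <- FALSE
  }
  fibers$fiber_id <- as.integer(fibers$fiber_id)
  fibers$revertant <- as.logical(fibers$revertant)
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(fiber_a = integer(), fiber_b = integer())
  } else {
    edges <- as.data.frame(edges)
    if (ncol(edges) < 2L)
      stop("`edges` needs two columns (fiber_a, fiber_b)", call. = FALSE)
    names(edges)[1:2] <- c("fiber_a", "fiber_b")
    edges$fiber_a <- as.integer(edges$fiber_a)
    edges$fiber_b <- as.integer(edges$fiber_b)
    # store unordered pairs canonically (a < b)
    swap <- edges$fiber_a > edges$fiber_b
    tmp <- edges$fiber_a[swap]
    edges$fiber_a[swap] <- edges$fiber_b[swap]
    edges$fiber_b[swap] <- tmp
  }
  structure(
    list(section_id = as.character(section_id)[1],
         fibers = fibers,
         edges = edges[, c("fiber_a", "fiber_b")],
         section_area_mm2 = as.numeric(section_area_mm2)[1],
         z_position = as.numeric(z_position)[1]),
    class = "section_graph")
}

#' @export
print.section_graph <- function(x, ...) {
  cat(sprintf(
    "<section_graph> %s: %d fibers (%d revertant), %d edges, %.3f mm2\n",
    x$section_id, nrow(x$fibers), sum(x$fibers$revertant),
    nrow(x$edges), x$section_area_mm2))
  invisible(x)
}

#' Validate a section graph
#'
#' Reports every invariant violation rather than stopping at the first:
#' duplicate or non-positive fiber ids, non-positive cross-sectional
#' areas, stain fractions outside [0, 1], self edges, duplicate edges,
#' edges referencing absent fibers, and a non-positive section area.
#'
#' @param graph a \code{section_graph}.
#' @return Character vector of violation messages; empty if valid.
#' @export
validate_section <- function(graph) {
  stopifnot(inherits(graph, "section_graph"))
  v <- character()
  f <- graph$fibers
  e <- graph$edges
  dup <- unique(f$fiber_id[duplicated(f$fiber_id)])
  if (length(dup))
    v <- c(v, paste0("duplicate fiber_id: ", paste(dup, collapse = ", ")))
  if (any(is.na(f$fiber_id) | f$fiber_id < 1L))
    v <- c(v, "fiber_id must be >= 1")
  if (any(is.na(f$csa_um2) | f$csa_um2 <= 0))
    v <- c(v, "csa_um2 must be > 0")
  sf <- f$stain_fraction
  if (any(!is.na(sf) & (sf < 0 | sf > 1)))
    v <- c(v, "stain_fraction outside [0, 1]")
  if (nrow(e)) {
    if (any(e$fiber_a == e$fiber_b))
      v <- c(v, "self edge(s) present")
    if (anyDuplicated(e))
      v <- c(v, "duplicate edge(s) present")
    dangling <- setdiff(unique(c(e$fiber_a, e$fiber_b)), f$fiber_id)
    if (length(dangling))
      v <- c(v, paste0("edge references absent fiber id: ",
                       paste(dangling, collapse = ", ")))
  }
  if (is.na(graph$section_area_mm2) || graph$section_area_mm2 <= 0)
    v <- c(v, "section_area_mm2 must be > 0")
  v
}

#' Build a section graph from an integer label map
#'
#' Pixels with the same positive label form one fiber; label 0 is
#' background and never mediates adjacency.  Two fibers are adjacent when
#' at least \code{min_shared_boundary} pixel pairs of theirs touch under
#' the chosen connectivity.  4-connectivity is the default because
#' 8-connectivity also joins fibers touching only at a corner, which
#' overstates membrane contact.
#'
#' Centroids are 0-based pixel indices scaled to micrometres; the section
#' area is the tissue mask (non-zero pixels), which excludes interstitium
#' - if a whole-section area was measured separately, overwrite
#' \code{section_area_mm2} on the result (\code{area_source = "provided"}).
#'
#' @param label_map integer matrix; 0 = background, labels need not be
#'   consecutive.
#' @param pixel_size_um pixel edge length in micrometres, > 0.
#' @param connectivity 4 (edge-sharing) or 8 (edge- or corner-sharing).
#' @param min_shared_boundary minimum number of touching pixel pairs for
#'   an adjacency edge (default 1).
#' @param positivity optional data frame \code{fiber_id, stain_fraction}
#'   and/or \code{revertant} giving per-fiber calls; fibers absent from it
#'   are non-revertant.
#' @param section_id,z_position passed through to [section_graph()].
#' @param area_source \code{"mask"} (default; nonzero-pixel area) or
#'   \code{"provided"}, in which case \code{section_area_mm2} must be given.
#' @param section_area_mm2 externally measured area, used when
#'   \code{area_source = "provided"}.
#' @return A \code{section_graph}.  An all-background map yields an empty
#'   graph whose area 0 is flagged by [validate_section()].
#' @export
graph_from_labelmap <- function(label_map, pixel_size_um, connectivity = 4,
                                min_shared_boundary = 1L,
                                positivity = NULL,
                                section_id = "labelmap",
                                z_position = NA_real_,
                                area_source = c("mask", "provided"),
                                section_area_mm2 = NULL) {
  area_source <- match.arg(area_source)
  m <- as.matrix(label_map)
  storage.mode(m) <- "integer"
  if (any(is.na(m)) || any(m < 0L))
    stop("label map must contain non-negative integers", call. = FALSE)
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be > 0", call. = FALSE)
  if (!connectivity %in% c(4, 8))
    stop("`connectivity` must be 4 or 8", call. = FALSE)

  labs <- sort(unique(m[m > 0L]))
  if (length(labs)) {
    idx <- which(m > 0L, arr.ind = TRUE)
    val <- m[m > 0L]
    # 0-based pixel coordinates: x along columns, y along rows
    px_count <- tabulate(match(val, labs), nbins = length(labs))
    xs <- vapply(split((idx[, 2] - 1), match(val, labs)), mean, 0)
    ys <- vapply(split((idx[, 1] - 1), match(val, labs)), mean, 0)
    fibers <- data.frame(
      fiber_id = labs,
      x_um = as.numeric(xs) * pixel_size_um,
      y_um = as.numeric(ys) * pixel_size_um,
      csa_um2 = px_count * pixel_size_um^2,
      stain_fraction = NA_real_,
      revertant = FALSE)
  } else {
    fibers <- data.frame(fiber_id = integer(), x_um = numeric(),
                         y_um = numeric(), csa_um2 = numeric(),
                         stain_fraction = numeric(), revertant = logical())
  }

  pair_counts <- labelmap_touch_pairs(m, connectivity)
  if (nrow(pair_counts)) {
    keep <- pair_counts$n >= min_shared_boundary
    edges <- pair_counts[keep, c("fiber_a", "fiber_b")]
  } else {
    edges <- data.frame(fiber_a = integer(), fiber_b = integer())
  }

  if (!is.null(positivity) && nrow(fibers)) {
    positivity <- as.data.frame(positivity)
    j <- match(fibers$fiber_id, positivity$fiber_id)
    if ("stain_fraction" %in% names(positivity))
      fibers$stain_fraction <- positivity$stain_fraction[j]
    if ("revertant" %in% names(positivity)) {
      fibers$revertant <- as.logical(positivity$revertant[j])
      fibers$revertant[is.na(fibers$revertant)] <- FALSE
    } else {
      fibers$revertant <- call_revertant(fibers$stain_fraction)
      fibers$revertant[is.na(fibers$revertant)] <- FALSE
    }
  }

  area <- if (area_source == "mask") {
    sum(m > 0L) * pixel_size_um^2 / 1e6
  } else {
    if (is.null(section_area_mm2))
      stop("area_source = \"provided\" needs `section_area_mm2`",
           call. = FALSE)
    section_area_mm2
  }
  section_graph(section_id, fibers, edges, area, z_position)
}

# Count touching pixel pairs between distinct positive labels.  Returns a
# data.frame(fiber_a, fiber_b, n) with a < b.  Vectorized over the four
# (or eight) neighbour shifts.
labelmap_touch_pairs <- function(m, connectivity) {
  nr <- nrow(m); nc <- ncol(m)
  a <- integer(); b <- integer()
  add_pairs <- function(u, v) {
    keep <- u > 0L & v > 0L & u != v
    if (any(keep)) {
      a <<- c(a, pmin(u[keep], v[keep]))
      b <<- c(b, pmax(u[keep], v[keep]))
    }
  }
  if (nc > 1L) add_pairs(m[, -nc, drop = FALSE], m[, -1L, drop = FALSE])
  if (nr > 1L) add_pairs(m[-nr, , drop = FALSE], m[-1L, , drop = FALSE])
  if (connectivity == 8 && nr > 1L && nc > 1L) {
    add_pairs(m[-nr, -nc, drop = FALSE], m[-1L, -1L, drop = FALSE])
    add_pairs(m[-1L, -nc, drop = FALSE], m[-nr, -1L, drop = FALSE])
  }
  if (!length(a))
    return(data.frame(fiber_a = integer(), fiber_b = integer(),
                      n = integer()))
  M <- as.numeric(max(b)) + 1       # b > a, so M bounds both
  if (M * M < 2^53) {               # exact in doubles for 16/24-bit labels
    key <- as.numeric(a) * M + b
    uk <- sort(unique(key))
    n <- tabulate(match(key, uk), nbins = length(uk))
    data.frame(fiber_a = as.integer(uk %/% M),
               fiber_b = as.integer(uk %% M),
               n = n)
  } else {
    dt <- data.table::data.table(fiber_a = a, fiber_b = b)
    as.data.frame(dt[, list(n = .N), by = c("fiber_a", "fiber_b")][
      order(fiber_a, fiber_b)])
  }
}

# internal: igraph view of a section graph (vertex name = fiber_id)
section_igraph <- function(graph) {
  ids <- as.character(graph$fibers$fiber_id)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(graph$edges))
    g <- igraph::add_edges(
      g, rbind(match(as.character(graph$edges$fiber_a), ids),
               match(as.character(graph$edges$fiber_b), ids)))
  g
}
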