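## Synthetic dystrophic-muscle cohorts.  A muscle is a fixed planar fiber
## tessellation extruded along z; revertant clones start from Poisson
## founders, annex adjacent fibers over regeneration cycles, gain de-novo
## founders each cycle, and carry longitudinal extent intervals.  Serial
## transverse sections realize per-section revertant calls by interval
## overlap, reproducing the dependence between neighbouring sections.

#' Simulator configuration
#'
#' All rates and geometry of the clonal-expansion generator.  Defaults
#' describe the reference mdx cohort: four age groups (2, 6, 12, >18
#' months) mapped to \code{cycles_per_group} elapsed regeneration cycles,
#' 10-12 transverse 9 um sections about 120 um apart, revertant segments
#' extending 100-300 um longitudinally with an occasional heavy tail up
#' to 900 um, high between-mouse variability (log-normal multiplier on
#' the reversion rates), and muscle-specific rate multipliers (diaphragm
#' and pectoralis low, TA and soleus high, heart lowest with clonal
#' expansion suppressed).
#'
#' @param n_fibers fibers per muscle cross-section.
#' @param mean_csa_um2 mean fiber cross-sectional area (um2).
#' @param csa_sdlog log-normal sd of fiber areas.
#' @param muscle_length_um modelled longitudinal extent of the sampled
#'   muscle block (um); must exceed the section span.
#' @param founder_rate expected founder clones per muscle at birth
#'   (Poisson mean), baseline before muscle/mouse multipliers.
#' @param denovo_rate expected new founder clones per regeneration cycle
#'   (Poisson mean), baseline.
#' @param expansion_prob per cycle, probability that a clone annexes each
#'   adjacent non-revertant fiber.
#' @param cycles_per_group regeneration cycles elapsed by each age group.
#' @param extent_range longitudinal extent of a revertant segment (um),
#'   uniform over this range with probability \code{1 - extent_tail_prob}.
#' @param extent_tail_prob probability of a long segment, uniform on
#'   (\code{extent_range[2]}, \code{extent_tail_max}].
#' @param extent_tail_max upper cap of the long-segment tail (um).
#' @param extent_jitter_um an annexed fiber inherits its clone's interval
#'   with endpoints jittered by up to this much (um).
#' @param section_spacing_um distance between consecutive sections.
#' @param section_thickness_um section thickness.
#' @param sections_range inclusive range of sections per muscle.
#' @param mouse_sd log-normal sd of the per-mouse multiplier applied to
#'   \code{founder_rate} and \code{denovo_rate}.
#' @param muscle_rates named numeric vector of per-muscle rate
#'   multipliers (names from [MUSCLE_CODES]); defaults mirror the
#'   observed ordering of muscles by revertant-fiber density.
#' @param heart_muscles muscle codes simulated in heart mode: clonal
#'   expansion suppressed and short segments (cardiomyocyte length).
#' @param heart_extent_range segment extent range in heart mode (um).
#' @return Object of class \code{sim_config} (validated list).
#' @export
sim_config <- function(n_fibers = 600,
                       mean_csa_um2 = 2000,
                       csa_sdlog = 0.3,
                       muscle_length_um = 1500,
                       founder_rate = 11,
                       denovo_rate = 2.8,
                       expansion_prob = 0.010,
                       cycles_per_group = c(2, 11, 12, 13),
                       extent_range = c(100, 300),
                       extent_tail_prob = 0.05,
                       extent_tail_max = 900,
                       extent_jitter_um = 50,
                       section_spacing_um = 120,
                       section_thickness_um = 9,
                       sections_range = c(10, 12),
                       mouse_sd = 0.6,
                       muscle_rates = NULL,
                       heart_muscles = "H",
                       heart_extent_range = c(80, 120)) {
  if (is.null(muscle_rates))
    muscle_rates <- c(TA = 1.00, EDL = 0.95, SOL = 1.00, GC = 0.85,
                      PL = 0.95, Q = 0.80, TRIC = 0.80, PT = 0.55,
                      D = 0.55, IC = 0.75, H = 0.45)
  cfg <- list(n_fibers = n_fibers, mean_csa_um2 = mean_csa_um2,
              csa_sdlog = csa_sdlog, muscle_length_um = muscle_length_um,
              founder_rate = founder_rate, denovo_rate = denovo_rate,
              expansion_prob = expansion_prob,
              cycles_per_group = cycles_per_group,
              extent_range = extent_range,
              extent_tail_prob = extent_tail_prob,
              extent_tail_max = extent_tail_max,
              extent_jitter_um = extent_jitter_um,
              section_spacing_um = section_spacing_um,
              section_thickness_um = section_thickness_um,
              sections_range = sections_range,
              mouse_sd = mouse_sd, muscle_rates = muscle_rates,
              heart_muscles = heart_muscles,
              heart_extent_range = heart_extent_range)
  with(cfg, {
    stopifnot(n_fibers >= 1, mean_csa_um2 > 0, csa_sdlog >= 0,
              founder_rate >= 0, denovo_rate >= 0,
              expansion_prob >= 0, expansion_prob <= 1,
              length(cycles_per_group) == 4, all(cycles_per_group >= 0),
              extent_range[1] >= 0, extent_range[2] >= extent_range[1],
              extent_tail_max >= extent_range[2],
              extent_tail_prob >= 0, extent_tail_prob <= 1,
              section_spacing_um > section_thickness_um,
              sections_range[1] >= 1,
              sections_range[2] >= sections_range[1],
              mouse_sd >= 0, all(muscle_rates >= 0))
  })
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_fibers, "fibers/section;",
      "founder rate", x$founder_rate, "; de-novo", x$denovo_rate,
      "/cycle; expansion", x$expansion_prob,
      "; cycles/group", paste(x$cycles_per_group, collapse = "/"), "\n")
  invisible(x)
}

# segment extent sampler (um)
rextent <- function(n, config, heart = FALSE) {
  if (heart) {
    r <- config$heart_extent_range
    return(runif(n, r[1], r[2]))
  }
  tail <- runif(n) < config$extent_tail_prob
  out <- runif(n, config$extent_range[1], config$extent_range[2])
  if (any(tail))
    out[tail] <- runif(sum(tail), config$extent_range[2],
                       config$extent_tail_max)
  out
}

#' Generate a fiber tessellation
#'
#' Seeded point process (jittered triangular lattice) with a
#' nearest-region (discrete Voronoi) partition of the cross-section; the
#' adjacency graph is read off the resulting label map, so fibers are
#' adjacent exactly when their regions share boundary.  Interior fibers
#' have about six neighbours, as in real fiber packings.  Cross-sectional
#' areas are drawn log-normal around \code{mean_csa_um2}; the section
#' area is the tessellated tissue mask, which includes an interstitium
#' allowance (fibers fill ~85\% of it).
#'
#' @param n_fibers number of fibers, >= 1.
#' @param seed RNG seed (determinism contract: same seed, same graph).
#' @param mean_csa_um2,csa_sdlog fiber area distribution.
#' @return Object of class \code{tessellation}: list with \code{fibers}
#'   (fiber_id, x_um, y_um, csa_um2), \code{edges} (fiber_a, fiber_b),
#'   \code{section_area_mm2}, \code{n_fibers}.
#' @export
make_tessellation <- function(n_fibers, seed = 1, mean_csa_um2 = 2000,
                              csa_sdlog = 0.3) {
  if (!is.numeric(n_fibers) || n_fibers < 1)
    stop("`n_fibers` must be >= 1", call. = FALSE)
  n_fibers <- as.integer(n_fibers)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  pitch <- 4                      # lattice pitch in pixels
  cols <- ceiling(sqrt(n_fibers))
  rows <- ceiling(n_fibers / cols)
  rowh <- pitch * sqrt(3) / 2
  # seed points: triangular lattice, odd rows offset, jittered
  ij <- expand.grid(j = seq_len(cols), i = seq_len(rows))
  ij <- ij[order(ij$i, ij$j), ]
  ij <- ij[seq_len(n_fibers), , drop = FALSE]
  sx <- (ij$j - 1) * pitch + ifelse(ij$i %% 2 == 0, pitch / 2, 0) +
    runif(n_fibers, -0.3, 0.3) * pitch
  sy <- (ij$i - 1) * rowh + runif(n_fibers, -0.3, 0.3) * pitch
  width <- cols * pitch
  height <- max(1, ceiling(rows * rowh))

  # nearest-seed assignment: each pixel checks seeds of the 3x3 block of
  # lattice cells around it (enough, given bounded jitter)
  px <- rep(seq_len(width) - 0.5, each = height)
  py <- rep(seq_len(height) - 0.5, times = width)
  ci <- pmin(pmax(round(py / rowh) + 1, 1), rows)
  cj <- pmin(pmax(round(px / pitch) + 1, 1), cols)
  np <- length(px)
  # seed index lookup by (i, j); row-major as constructed above
  seed_at <- matrix(NA_integer_, rows, cols)
  seed_at[cbind(ij$i, ij$j)] <- seq_len(n_fibers)
  dmat <- matrix(Inf, np, 9L)
  candm <- matrix(NA_integer_, np, 9L)
  k <- 0L
  for (di in -1:1) for (dj in -1:1) {
    k <- k + 1L
    ii <- ci + di; jj <- cj + dj
    inside <- ii >= 1L & ii <= rows & jj >= 1L & jj <= cols
    cand <- rep(NA_integer_, np)
    cand[inside] <- seed_at[(jj[inside] - 1L) * rows + ii[inside]]
    d <- (px - sx[cand])^2 + (py - sy[cand])^2
    d[is.na(d)] <- Inf
    dmat[, k] <- d
    candm[, k] <- cand
  }
  kbest <- max.col(-dmat, ties.method = "first")
  best <- candm[(kbest - 1L) * np + seq_len(np)]
  # pixels whose 3x3 candidate block held no seed (clamped border cells)
  # fall back to the global nearest seed -- rare, small n only
  if (anyNA(best)) {
    for (k in which(is.na(best)))
      best[k] <- which.min((px[k] - sx)^2 + (py[k] - sy)^2)
  }
  lab <- matrix(0L, height, width)
  lab[cbind(ceiling(py), ceiling(px))] <- best

  # pixel size chosen so mean fiber area ~= mean_csa / 0.85 fill factor
  px_per_fiber <- sum(lab > 0L) / n_fibers
  pixel_size <- sqrt(mean_csa_um2 / 0.85 / px_per_fiber)
  pairs <- labelmap_touch_pairs(lab, 4)
  edges <- pairs[, c("fiber_a", "fiber_b")]
  cnt <- tabulate(lab[lab > 0L], nbins = n_fibers)
  # centroids from the partition (fall back to the seed point for any
  # fiber whose region got squeezed out), areas log-normal
  xs <- rep(NA_real_, n_fibers); ys <- rep(NA_real_, n_fibers)
  sums <- rowsum(cbind(px, py, 1), best)
  at <- as.integer(rownames(sums))
  xs[at] <- sums[, 1] / sums[, 3]
  ys[at] <- sums[, 2] / sums[, 3]
  xs[is.na(xs)] <- sx[is.na(xs)]
  ys[is.na(ys)] <- sy[is.na(ys)]
  csa <- rlnorm(n_fibers, log(mean_csa_um2) - csa_sdlog^2 / 2, csa_sdlog)
  fibers <- data.frame(
    fiber_id = seq_len(n_fibers),
    x_um = xs * pixel_size,
    y_um = ys * pixel_size,
    csa_um2 = csa)
  structure(list(fibers = fibers, edges = edges,
                 section_area_mm2 = sum(cnt) * pixel_size^2 / 1e6,
                 n_fibers = n_fibers, seed = seed),
            class = "tessellation")
}

#' @export
print.tessellation <- function(x, ...) {
  cat(sprintf("<tessellation> %d fibers, %d edges, %.3f mm2\n",
              x$n_fibers, nrow(x$edges), x$section_area_mm2))
  invisible(x)
}

# RNG state helpers: simulator functions are seeded without disturbing
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}

# adjacency list from an edge table
adjacency_list <- function(n, edges) {
  if (!nrow(edges))
    return(vector("list", n))
  unname(split(c(edges$fiber_b, edges$fiber_a),
               factor(c(edges$fiber_a, edges$fiber_b),
                      levels = seq_len(n))))
}

#' Simulate reversion and clonal expansion in one muscle
#'
#' Founder clones appear at birth (Poisson, rate scaled by the muscle
#' and mouse multipliers) on uniformly chosen fibers, each with a
#' longitudinal extent interval placed uniformly along the muscle.  Each
#' elapsed regeneration cycle every clone annexes each adjacent
#' non-revertant fiber independently with probability
#' \code{expansion_prob} (the annexed fiber inherits the annexing
#' fiber's interval, endpoints jittered), and new de-novo founders are
#' added (Poisson per cycle).  In heart mode expansion is suppressed and
#' extents are cardiomyocyte-length, so clusters beyond chance-adjacent
#' pairs are essentially absent.
#'
#' @param tess a [make_tessellation()] result.
#' @param config a [sim_config()].
#' @param age_group 1-4; selects \code{cycles_per_group}.
#' @param seed RNG seed.
#' @param muscle muscle code; selects the rate multiplier and heart mode.
#' @param mouse_factor per-mouse multiplier on founder and de-novo rates.
#' @return Data frame \code{fiber_id, clone_id, z0, z1} (one row per
#'   revertant fiber; z interval in um, clipped to the muscle length).
#' @export
simulate_reversion <- function(tess, config, age_group, seed = 1,
                               muscle = "TA", mouse_factor = 1) {
  stopifnot(inherits(tess, "tessellation"),
            inherits(config, "sim_config"),
            age_group %in% 1:4)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  heart <- muscle %in% config$heart_muscles
  rate_mult <- if (muscle %in% names(config$muscle_rates))
    config$muscle_rates[[muscle]] else 1
  mu0 <- config$founder_rate * rate_mult * mouse_factor
  lam <- config$denovo_rate * rate_mult * mouse_factor
  p_exp <- if (heart) 0 else config$expansion_prob
  n_cycles <- config$cycles_per_group[age_group]
  L <- config$muscle_length_um
  n <- tess$n_fibers
  adj <- adjacency_list(n, tess$edges)

  clone <- integer(n)            # 0 = not revertant
  z0 <- numeric(n); z1 <- numeric(n)
  next_clone <- 1L
  place_founders <- function(k) {
    free <- which(clone == 0L)
    k <- min(k, length(free))
    if (k < 1L) return(invisible())
    ids <- if (length(free) == 1L) free else sample(free, k)
    ext <- rextent(k, config, heart)
    ctr <- runif(k, 0, L)
    clone[ids] <<- next_clone - 1L + seq_len(k)
    z0[ids] <<- pmax(0, ctr - ext / 2)
    z1[ids] <<- pmin(L, ctr + ext / 2)
    next_clone <<- next_clone + k
  }
  place_founders(rpois(1, mu0))
  for (cyc in seq_len(n_cycles)) {
    if (p_exp > 0) {
      rev_now <- which(clone > 0L)
      if (length(rev_now)) {
        # frontier: (revertant source, non-revertant target) pairs
        src <- rep(rev_now, lengths(adj[rev_now]))
        tgt <- unlist(adj[rev_now], use.names = FALSE)
        open <- clone[tgt] == 0L
        src <- src[open]; tgt <- tgt[open]
        if (length(tgt)) {
          hit <- runif(length(tgt)) < p_exp
          src <- src[hit]; tgt <- tgt[hit]
          if (length(tgt)) {
            # a fiber annexed by several clones goes to a random one
            ord <- sample(length(tgt))
            src <- src[ord]; tgt <- tgt[ord]
            first <- !duplicated(tgt)
            src <- src[first]; tgt <- tgt[first]
            jit <- config$extent_jitter_um
            clone[tgt] <- clone[src]
            z0[tgt] <- pmax(0, z0[src] + runif(length(src), -jit, jit))
            z1[tgt] <- pmin(L, z1[src] + runif(length(src), -jit, jit))
            bad <- z1[tgt] <= z0[tgt]
            if (any(bad)) {         # jitter collapsed the interval
              mid <- (z0[tgt][bad] + z1[tgt][bad]) / 2
              z0[tgt][bad] <- pmax(0, mid - 50)
              z1[tgt][bad] <- pmin(L, mid + 50)
            }
          }
        }
      }
    }
    place_founders(rpois(1, lam))
  }
  rev <- which(clone > 0L)
  data.frame(fiber_id = rev, clone_id = clone[rev],
             z0 = z0[rev], z1 = z1[rev])
}

#' Cut serial transverse sections from a simulated muscle
#'
#' Realizes 10-12 sections (default; \code{sections_range}) of
#' \code{section_thickness_um} at \code{section_spacing_um} intervals,
#' randomly offset within the muscle.  A fiber is revertant in a section
#' iff its extent interval overlaps the section's z-interval; revertant
#' fibers get stain fraction 1, others a sub-threshold random fraction.
#'
#' @param tess a [make_tessellation()] result.
#' @param reversion result of [simulate_reversion()].
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @param section_prefix prefix for section ids.
#' @param n_sections optional fixed section count (else drawn from
#'   \code{sections_range}).
#' @return List of \code{section_graph}s (one per section, shallow-
#'   sharing the tessellation geometry), each with its \code{z_position}.
#' @export
sample_sections <- function(tess, reversion, config, seed = 1,
                            section_prefix = "s", n_sections = NULL) {
  stopifnot(inherits(tess, "tessellation"), inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sp <- config$section_spacing_um
  th <- config$section_thickness_um
  if (is.null(n_sections))
    n_sections <- sample(seq(config$sections_range[1],
                             config$sections_range[2]), 1)
  span <- (n_sections - 1) * sp + th
  L <- config$muscle_length_um
  if (span > L)
    stop("muscle length ", L, " um cannot hold ", n_sections,
         " sections spanning ", span, " um", call. = FALSE)
  z_start <- runif(1, 0, L - span)
  base <- tess$fibers
  n <- nrow(base)
  lapply(seq_len(n_sections), function(j) {
    zlo <- z_start + (j - 1) * sp
    zhi <- zlo + th
    rev_ids <- reversion$fiber_id[reversion$z0 <= zhi &
                                  reversion$z1 >= zlo]
    fibers <- base
    fibers$revertant <- fibers$fiber_id %in% rev_ids
    sf <- round(runif(n, 0, 0.9), 3)
    sf[fibers$revertant] <- 1
    fibers$stain_fraction <- sf
    # tessellation edges are already canonical (a < b): construct
    # directly, skipping the re-canonicalization in section_graph()
    structure(
      list(section_id = sprintf("%s%02d", section_prefix, j),
           fibers = fibers,
           edges = tess$edges,
           section_area_mm2 = tess$section_area_mm2,
           z_position = zlo),
      class = "section_graph")
  })
}

# hand-rolled union-find over the revertant subgraph: the generator's own
# ground truth, independent of the igraph-based quantifier
uf_cluster_sizes <- function(rev_ids, edges) {
  if (!length(rev_ids)) return(integer())
  parent <- seq_along(rev_ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  a <- match(edges$fiber_a, rev_ids)
  b <- match(edges$fiber_b, rev_ids)
  keep <- !is.na(a) & !is.na(b)
  for (k in which(keep)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_along(rev_ids), find, 0L)
  sort(as.integer(table(roots)), decreasing = TRUE)
}

#' Default cohort design
#'
#' @param n_mice_per_group mice per age group (reference design: 10).
#' @param muscles muscle codes to include.
#' @return Data frame \code{mouse_id, age_group, muscle}.
#' @export
cohort_design <- function(n_mice_per_group = 10, muscles = MUSCLE_CODES) {
  mice <- expand.grid(m = seq_len(n_mice_per_group), age_group = 1:4)
  mice$mouse_id <- sprintf("g%dm%02d", mice$age_group, mice$m)
  out <- merge(mice[, c("mouse_id", "age_group")],
               data.frame(muscle = muscles), by = NULL)
  out[order(out$mouse_id, match(out$muscle, MUSCLE_CODES)), ]
}

#' Generate a complete synthetic cohort
#'
#' Simulates every (mouse, muscle) of the design: one tessellation per
#' muscle (fixed along its length), clonal reversion according to the
#' mouse's age group, and serial sections.  Per-mouse log-normal
#' multipliers on the reversion rates induce the high inter-individual
#' variability typical of revertant-fiber counts.  Fully deterministic
#' given \code{master_seed}.
#'
#' @param config a [sim_config()].
#' @param design data frame \code{mouse_id, age_group, muscle} (default
#'   [cohort_design()]); duplicate (mouse, muscle) rows are an error.
#' @param master_seed integer master seed.
#' @return List with \code{sections} (named list of
#'   \code{section_graph}s), \code{design} (one row per section:
#'   section_id, mouse_id, age_group, muscle, section_area_mm2, z_um) and
#'   \code{truth} (per-section ground truth from the generator's own
#'   union-find: section_id, n_rf and cluster sizes as a comma-separated
#'   string, plus size-class counts).
#' @export
generate_cohort <- function(config = sim_config(),
                            design = cohort_design(),
                            master_seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  design <- as.data.frame(design)
  need <- c("mouse_id", "age_group", "muscle")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("`design` lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(design[, c("mouse_id", "muscle")]))
    stop("duplicate (mouse_id, muscle) rows in `design`", call. = FALSE)
  mice <- unique(design[, c("mouse_id", "age_group")])
  if (anyDuplicated(mice$mouse_id))
    stop("a mouse_id appears with two different age groups", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(master_seed, 0L))
  mouse_factor <- setNames(
    rlnorm(nrow(mice), -config$mouse_sd^2 / 2, config$mouse_sd),
    mice$mouse_id)

  sections <- list()
  acc <- list(section_id = character(), mouse_id = character(),
              age_group = integer(), muscle = character(),
              section_area_mm2 = numeric(), z_um = numeric(),
              n_rf = integer(), cluster_sizes = character(),
              n_singleton = integer(), n_small = integer(),
              n_medium = integer(), n_large = integer(),
              n_very_large = integer())
  for (r in seq_len(nrow(design))) {
    mid <- design$mouse_id[r]
    mus <- design$muscle[r]
    grp <- design$age_group[r]
    s_tess <- derive_seed(master_seed, r * 3L + 1L)
    s_rev <- derive_seed(master_seed, r * 3L + 2L)
    s_sec <- derive_seed(master_seed, r * 3L + 3L)
    tess <- make_tessellation(config$n_fibers, seed = s_tess,
                              mean_csa_um2 = config$mean_csa_um2,
                              csa_sdlog = config$csa_sdlog)
    rev <- simulate_reversion(tess, config, grp, seed = s_rev,
                              muscle = mus,
                              mouse_factor = mouse_factor[[mid]])
    prefix <- paste0(mid, "_", mus, "_s")
    secs <- sample_sections(tess, rev, config, seed = s_sec,
                            section_prefix = prefix)
    for (sec in secs) {
      sections[[sec$section_id]] <- sec
      rf <- sec$fibers$fiber_id[sec$fibers$revertant]
      sizes <- uf_cluster_sizes(rf, sec$edges)
      cls <- tabulate(classify_cluster_size(if (length(sizes)) sizes
                                            else 1L), nbins = 5L)
      if (!length(sizes)) cls[] <- 0L
      k <- length(acc$section_id) + 1L
      acc$section_id[k] <- sec$section_id
      acc$mouse_id[k] <- mid
      acc$age_group[k] <- grp
      acc$muscle[k] <- mus
      acc$section_area_mm2[k] <- sec$section_area_mm2
      acc$z_um[k] <- sec$z_position
      acc$n_rf[k] <- length(rf)
      acc$cluster_sizes[k] <- paste(sizes, collapse = ",")
      acc$n_singleton[k] <- cls[1]; acc$n_small[k] <- cls[2]
      acc$n_medium[k] <- cls[3]; acc$n_large[k] <- cls[4]
      acc$n_very_large[k] <- cls[5]
    }
  }
  design_out <- data.frame(
    section_id = acc$section_id, mouse_id = acc$mouse_id,
    age_group = acc$age_group, muscle = acc$muscle,
    section_area_mm2 = acc$section_area_mm2, z_um = acc$z_um,
    stringsAsFactors = FALSE)
  truth <- data.frame(
    section_id = acc$section_id, n_rf = acc$n_rf,
    cluster_sizes = acc$cluster_sizes, n_singleton = acc$n_singleton,
    n_small = acc$n_small, n_medium = acc$n_medium,
    n_large = acc$n_large, n_very_large = acc$n_very_large,
    stringsAsFactors = FALSE)
  list(sections = sections, design = design_out, truth = truth)
}
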