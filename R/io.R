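## CSV readers/writers for the pipeline's interchange formats, summary
## report tables, and the run manifest.
##
## Schemas (comma-separated, UTF-8, mandatory header; numeric fields
## accept both decimal point and decimal comma on input, are always
## written with a decimal point):
##   fibers.csv: section_id,fiber_id,x_um,y_um,csa_um2,stain_fraction,revertant
##   edges.csv:  section_id,fiber_a,fiber_b
##   design.csv: section_id,mouse_id,age_group,muscle,section_area_mm2,z_um

num_col <- function(x, name, file) {
  if (is.numeric(x)) return(as.numeric(x))
  y <- suppressWarnings(as.numeric(gsub(",", ".", as.character(x),
                                        fixed = TRUE)))
  bad <- which(!is.na(x) & x != "" & is.na(y))
  if (length(bad))
    stop(file, ": column '", name, "' not numeric at data row(s) ",
         paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
  y
}

read_schema <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- data.table::fread(path, colClasses = list(character = "section_id"),
                         data.table = FALSE, showProgress = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop(basename(path), ": missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  d
}

#' Read per-section fiber tables into section graphs
#'
#' Reads the fiber, edge and design CSVs (schemas documented in the
#' package README) and assembles one validated [section_graph()] per
#' section.  Malformed inputs fail with messages naming the offending
#' column, section and fiber ids.
#'
#' @param fibers_path,edges_path,design_path CSV paths.
#' @param tolerance positivity tolerance used when a \code{revertant}
#'   column is absent and calls are derived from \code{stain_fraction}.
#' @return List with \code{sections} (named list of
#'   \code{section_graph}s) and \code{design} (data frame, one row per
#'   section).
#' @export
read_fiber_tables <- function(fibers_path, edges_path, design_path,
                              tolerance = 0.01) {
  fib <- read_schema(fibers_path,
                     c("section_id", "fiber_id", "x_um", "y_um", "csa_um2"))
  for (cl in c("fiber_id", "x_um", "y_um", "csa_um2"))
    fib[[cl]] <- num_col(fib[[cl]], cl, basename(fibers_path))
  if ("stain_fraction" %in% names(fib))
    fib$stain_fraction <- num_col(fib$stain_fraction, "stain_fraction",
                                  basename(fibers_path))
  if ("revertant" %in% names(fib))
    fib$revertant <- as.logical(fib$revertant)
  edg <- read_schema(edges_path, c("section_id", "fiber_a", "fiber_b"))
  for (cl in c("fiber_a", "fiber_b"))
    edg[[cl]] <- num_col(edg[[cl]], cl, basename(edges_path))
  des <- read_schema(design_path,
                     c("section_id", "mouse_id", "age_group", "muscle",
                       "section_area_mm2"))
  des$section_area_mm2 <- num_col(des$section_area_mm2,
                                  "section_area_mm2",
                                  basename(design_path))
  des$age_group <- as.integer(des$age_group)
  if (!"z_um" %in% names(des)) des$z_um <- NA_real_
  bad_mus <- setdiff(unique(des$muscle), MUSCLE_CODES)
  if (length(bad_mus))
    warning("non-canonical muscle code(s): ",
            paste(bad_mus, collapse = ", "))
  if (anyDuplicated(des$section_id))
    stop("design.csv: duplicate section_id", call. = FALSE)

  fib_split <- split(fib, fib$section_id)
  edg_split <- split(edg, edg$section_id)
  orphan <- setdiff(names(fib_split), des$section_id)
  if (length(orphan))
    stop("fibers.csv: section(s) absent from design: ",
         paste(utils::head(orphan, 3), collapse = ", "), call. = FALSE)
  sections <- vector("list", nrow(des))
  names(sections) <- des$section_id
  for (i in seq_len(nrow(des))) {
    sid <- des$section_id[i]
    f <- fib_split[[sid]]
    if (is.null(f))
      stop("design.csv: section ", sid, " has no fibers", call. = FALSE)
    e <- edg_split[[sid]]
    if (is.null(e))
      e <- data.frame(fiber_a = integer(), fiber_b = integer())
    g <- section_graph(sid, f[setdiff(names(f), "section_id")],
                       e[c("fiber_a", "fiber_b")],
                       des$section_area_mm2[i], des$z_um[i],
                       tolerance = tolerance)
    viol <- validate_section(g)
    if (length(viol))
      stop("section ", sid, ": ", paste(viol, collapse = "; "),
           call. = FALSE)
    sections[[sid]] <- g
  }
  list(sections = sections, design = des)
}

#' Write a cohort as pipeline interchange CSVs
#'
#' Emits \code{fibers.csv}, \code{edges.csv} and \code{design.csv} for a
#' list of section graphs, the exact inputs [read_fiber_tables()]
#' consumes.
#'
#' @param sections named list of \code{section_graph}s.
#' @param design data frame with one row per section (as produced by
#'   [generate_cohort()]).
#' @param dir output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
write_fiber_tables <- function(sections, design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fib <- data.table::rbindlist(lapply(sections, function(s) {
    cbind(section_id = s$section_id,
          s$fibers[c("fiber_id", "x_um", "y_um", "csa_um2",
                     "stain_fraction", "revertant")])
  }))
  fib$x_um <- round(fib$x_um, 2)
  fib$y_um <- round(fib$y_um, 2)
  fib$csa_um2 <- round(fib$csa_um2, 1)
  edg <- data.table::rbindlist(lapply(sections, function(s) {
    if (!nrow(s$edges))
      return(data.table::data.table(section_id = character(),
                                    fiber_a = integer(),
                                    fiber_b = integer()))
    cbind(section_id = s$section_id, s$edges)
  }))
  paths <- file.path(dir, c("fibers.csv", "edges.csv", "design.csv"))
  data.table::fwrite(fib, paths[1])
  data.table::fwrite(edg, paths[2])
  data.table::fwrite(design, paths[3])
  invisible(paths)
}

#' Read an integer label map from a CSV grid
#'
#' A plain-text stand-in for single-channel label images: one CSV row
#' per image row, no header, non-negative integers, 0 = background.
#'
#' @param path CSV path.
#' @return Integer matrix for [graph_from_labelmap()].
#' @export
read_label_map_csv <- function(path) {
  m <- as.matrix(data.table::fread(path, header = FALSE,
                                   data.table = FALSE))
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

#' Summary report tables
#'
#' Produces the standard summary grids from a long trait table: a
#' muscle-by-age-group grid of \code{mean +/- sd} revertant-fiber
#' densities (one decimal), a muscle-by-age-group grid of the maximum
#' cluster size, per-muscle-per-group trend tables for every trait, and
#' (optionally) the contrast listing.  When \code{dir} is given, each
#' table is written as a CSV.
#'
#' @param traits long trait table (see [trait_table()]).
#' @param contrasts optional data frame from [group_contrasts()].
#' @param dir optional output directory.
#' @return List of data frames: \code{density_grid}, \code{max_cluster_grid},
#'   \code{trends}, and \code{contrasts} when supplied.
#' @export
report_tables <- function(traits, contrasts = NULL, dir = NULL) {
  agg <- aggregate_traits(traits)
  pg <- data.table::as.data.table(agg$per_group)
  mus_lev <- intersect(MUSCLE_CODES, unique(pg$muscle))
  dens <- pg[pg$trait == "rf_per_mm2", ]
  dens$cell <- sprintf("%.1f\u00b1%.1f", dens$mean,
                       ifelse(is.na(dens$sd), 0, dens$sd))
  density_grid <- data.table::dcast(dens, muscle ~ age_group,
                                    value.var = "cell")
  names(density_grid)[-1] <- paste0("GROUP_", names(density_grid)[-1])
  density_grid <- density_grid[order(match(muscle, mus_lev))]

  dt <- data.table::as.data.table(traits)
  mx <- dt[dt$trait == "max_cluster_size",
           list(max = max(value, na.rm = TRUE)),
           by = c("muscle", "age_group")]
  max_cluster_grid <- data.table::dcast(mx, muscle ~ age_group,
                                        value.var = "max")
  names(max_cluster_grid)[-1] <-
    paste0("GROUP_", names(max_cluster_grid)[-1])
  max_cluster_grid <- max_cluster_grid[order(match(muscle, mus_lev))]

  trends <- agg$per_group[order(agg$per_group$trait,
                                match(agg$per_group$muscle, mus_lev),
                                agg$per_group$age_group), ]
  out <- list(density_grid = as.data.frame(density_grid),
              max_cluster_grid = as.data.frame(max_cluster_grid),
              trends = trends)
  if (!is.null(contrasts)) out$contrasts <- contrasts
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out))
      data.table::fwrite(out[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  out
}

#' Write a machine-readable run manifest
#'
#' Records what produced a set of outputs: package version, R version,
#' the seed, the configuration (plus its MD5 hash for quick equality
#' checks) and a timestamp, as JSON.  Together with the seed this makes
#' every pipeline run exactly replayable.
#'
#' @param path output JSON path.
#' @param config list of configuration values (coerced to JSON).
#' @param seed the seed used.
#' @param extra optional named list of additional fields.
#' @return Invisibly, the manifest list.
#' @export
write_run_manifest <- function(path, config, seed, extra = list()) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- c(list(
    package = "revfiber",
    version = as.character(utils::packageVersion("revfiber")),
    r_version = R.version.string,
    seed = seed,
    config = jsonlite::fromJSON(cfg_json),
    config_md5 = unname(tools::md5sum(tmp)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
  unlink(tmp)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
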