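# Readers and writers for the package's file schemas. CSV files are UTF-8,
# comma-separated, header mandatory; lengths in metres, masses in
# kilograms, angles in degrees. Every file written here starts with a
# comment line embedding the package version and a configuration hash, and
# every reader skips '#' comment lines, so write -> read is lossless.

pkg_version <- function() as.character(utils::packageVersion("avimorph"))

config_hash <- function(x) {
  txt <- paste(utils::capture.output(utils::str(x)), collapse = "\n")
  # small polynomial rolling hash; stable across sessions
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_stamped_csv <- function(x, path, config = list()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# avimorph %s config %s", pkg_version(),
                     config_hash(config)), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

read_stamped_csv <- function(path, ...) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}

#' Morphology table column dictionary
#'
#' @return tibble with `column`, `unit` and `description` for the specimen
#'   morphology schema consumed by the builders.
#' @export
morphology_schema <- function() {
  tibble::tribble(
    ~column, ~unit, ~description,
    "species", "-", "species identifier (matches tree tip labels)",
    "specimen_id", "-", "unique specimen identifier",
    "mass_total", "kg", "full body mass",
    "wingspan", "m", "maximum wingspan (tip to tip)",
    "length_body", "m", "body length used to normalize CG positions",
    "mass_head", "kg", "head mass", "length_head", "m", "head length",
    "width_head", "m", "head width",
    "mass_neck", "kg", "neck mass", "length_neck", "m", "neck length",
    "radius_neck", "m", "neck radius",
    "mass_torso", "kg", "torso mass (body without head, neck, tail, wings)",
    "length_torso", "m", "torso length",
    "width_torso", "m", "maximum torso width",
    "height_torso", "m", "maximum torso height",
    "torso_cg_x", "m", "torso balance point x relative to the clavicle reference point (negative caudal)",
    "torso_cg_z", "m", "torso balance point z relative to the clavicle reference point (negative ventral)",
    "mass_legs", "kg", "both legs", "length_leg", "m", "leg length",
    "radius_leg", "m", "leg radius",
    "mass_tail", "kg", "tail (feathers + flesh)",
    "length_tail", "m", "tail length beyond the torso",
    "width_tail_root", "m", "tail width at the root",
    "width_tail_tip", "m", "tail width at the tip",
    "mass_humerus", "kg", "humerus mass (one wing)",
    "length_humerus", "m", "humerus length",
    "mass_radius", "kg", "radius bone mass", "length_radius", "m", "radius bone length",
    "mass_ulna", "kg", "ulna mass", "length_ulna", "m", "ulna length",
    "mass_carpometacarpus", "kg", "carpometacarpus + digit mass",
    "length_carpometacarpus", "m", "carpometacarpus + digit length",
    "mass_radiale", "kg", "radiale (point mass)",
    "mass_ulnare", "kg", "ulnare (point mass)",
    "mass_muscle_brachial", "kg", "brachial muscle group",
    "mass_muscle_antebrachial", "kg", "antebrachial muscle group",
    "mass_muscle_manus", "kg", "manus muscle group",
    "mass_skin", "kg", "skin + propatagium",
    "mass_coverts", "kg", "covert feathers (lumped)",
    "mass_tertiaries", "kg", "tertiary feathers (lumped)",
    "n_primaries", "count", "number of primary feathers",
    "n_secondaries", "count", "number of secondary feathers",
    "estimated_fields", "-", "semicolon-separated names of estimated (not measured) fields"
  )
}

FEATHER_COLUMNS <- c("specimen_id", "feather_id", "type", "mass",
                     "length_calamus", "length_rachis", "radius_calamus",
                     "width_vane_proximal", "width_vane_distal",
                     "length_vane_proximal", "length_vane_distal",
                     "frac_calamus", "frac_rachis_cortex",
                     "frac_rachis_medulla", "frac_vane_proximal",
                     "frac_vane_distal")

check_columns <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Read / write the morphology table
#'
#' @param path CSV path.
#' @return tibble validated against [morphology_schema()].
#' @export
read_morphology <- function(path) {
  df <- read_stamped_csv(path)
  check_columns(df, morphology_schema()$column, "morphology table")
  if (anyDuplicated(df$specimen_id)) stop("duplicate specimen_id", call. = FALSE)
  df$estimated_fields[is.na(df$estimated_fields)] <- ""
  df
}

#' @rdname read_morphology
#' @param morphology tibble to write.
#' @param config optional configuration list folded into the file stamp.
#' @export
write_morphology <- function(morphology, path, config = list()) {
  check_columns(morphology, morphology_schema()$column, "morphology table")
  write_stamped_csv(morphology, path, config)
}

#' Read / write the feather table
#' @param path CSV path.
#' @return validated tibble.
#' @export
read_feathers <- function(path) {
  df <- read_stamped_csv(path)
  check_columns(df, FEATHER_COLUMNS, "feather table")
  df
}

#' @rdname read_feathers
#' @param feathers tibble to write.
#' @param config optional configuration list folded into the file stamp.
#' @export
write_feathers <- function(feathers, path, config = list()) {
  check_columns(feathers, FEATHER_COLUMNS, "feather table")
  write_stamped_csv(feathers, path, config)
}

#' Read / write marker traces
#' @param path CSV path with columns frame, marker, x, y, z.
#' @return tibble.
#' @export
read_markers <- function(path) {
  check_columns(read_stamped_csv(path), c("frame", "marker", "x", "y", "z"),
                "marker table")
}

#' @rdname read_markers
#' @param markers tibble to write.
#' @param config optional configuration list folded into the file stamp.
#' @export
write_markers <- function(markers, path, config = list()) {
  write_stamped_csv(markers, path, config)
}

#' Read / write species trait tables
#' @param path CSV path with columns species, trait, value.
#' @return tibble.
#' @export
read_traits <- function(path) {
  check_columns(read_stamped_csv(path), c("species", "trait", "value"),
                "trait table")
}

#' @rdname read_traits
#' @param traits tibble to write.
#' @param config optional configuration list folded into the file stamp.
#' @export
write_traits <- function(traits, path, config = list()) {
  write_stamped_csv(traits, path, config)
}

#' Read an ultrametric phylogeny from Newick
#'
#' @param path Newick file.
#' @param tips optional tip set to prune to (error if any tip is absent).
#' @param require_ultrametric check ultrametricity (needed for OU fits).
#' @param tol relative ultrametricity tolerance.
#' @return `phylo` object.
#' @export
read_tree <- function(path, tips = NULL, require_ultrametric = TRUE,
                      tol = 1e-6) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path, call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (!is.null(tips)) {
    absent <- setdiff(tips, tree$tip.label)
    if (length(absent)) {
      stop("requested tip(s) absent from tree: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    tree <- ape::keep.tip(tree, tips)
  }
  check_tree(tree, require_ultrametric = require_ultrametric, tol = tol)
  tree
}

#' Write / read ROM hulls as JSON
#' @param hulls named list of [rom_hull()] objects.
#' @param path JSON path.
#' @export
write_hulls <- function(hulls, path) {
  obj <- list(package = "avimorph", version = pkg_version(),
              config = config_hash(hulls),
              hulls = purrr::map(hulls, function(h) {
                list(elbow = h$elbow, wrist = h$wrist)
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hulls
#' @return named list of [rom_hull()] objects.
#' @export
read_hulls <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  purrr::map(obj$hulls, function(h) {
    rom_hull(tibble::tibble(elbow = as.numeric(h$elbow),
                            wrist = as.numeric(h$wrist)))
  })
}

#' Read / write a run configuration (YAML)
#'
#' Validates the presence and types of the pipeline settings before any
#' computation: paths, grid step, neutral-point exponent, neck state, seeds,
#' simulation sizes and per-trait null slopes.
#'
#' @param path YAML file.
#' @return named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_run_config()
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  stopifnot(cfg$grid_step > 0, cfg$np_exponent > 0,
            cfg$neck %in% c("extended", "furled"),
            cfg$n_sim >= 1, cfg$n_boot >= 1)
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @export
default_run_config <- function() {
  list(grid_step = 1, np_exponent = 0.8, neck = "extended", seed = 1,
       n_sim = 5000, n_boot = 5000,
       null_slopes = list(x_cg_norm = 0, z_cg_norm = 0, y_cg_wing_norm = 0,
                          log_Ixx = 5 / 3, log_Iyy = 5 / 3, log_Izz = 5 / 3))
}

#' @rdname read_run_config
#' @param config list to write.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
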