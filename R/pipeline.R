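# Cohort-level pipeline: sweep every specimen's ROM, summarize extrema, and
# build the species-mean trait tables consumed by the evolutionary analyses.

log_stage <- function(stage, ...) {
  message(sprintf("[avimorph] %s | %s", stage,
                  paste(sprintf("%s=%s", names(list(...)), unlist(list(...))),
                        collapse = " ")))
}

#' Sweep every specimen in a cohort
#'
#' @param morphology morphology tibble (one row per specimen).
#' @param feathers feather tibble (all specimens).
#' @param hulls named list of [rom_hull()]s keyed by `specimen_id`.
#' @param grid_step grid spacing (degrees).
#' @param ... passed to [sweep_rom()].
#' @return named list of `avi_sweep` tibbles.
#' @export
cohort_sweep <- function(morphology, feathers, hulls, grid_step = 1, ...) {
  out <- purrr::map(seq_len(nrow(morphology)), function(i) {
    id <- morphology$specimen_id[i]
    hull <- hulls[[id]]
    if (is.null(hull)) stop("no ROM hull for specimen ", id, call. = FALSE)
    sw <- sweep_rom(morphology[i, ],
                    feathers[feathers$specimen_id == id, , drop = FALSE],
                    hull, grid_step = grid_step, ...)
    log_stage("sweep", specimen = id, configs = nrow(sw))
    sw
  })
  names(out) <- morphology$specimen_id
  out
}

#' Per-specimen summary table for a cohort
#'
#' One row per specimen: ROM extrema ([specimen_extremes()]) joined with the
#' specimen identifiers and the quantities the sensitivity bootstrap needs
#' (torso length and torso+tail mass fraction).
#'
#' @param sweeps named list from [cohort_sweep()].
#' @param morphology the morphology tibble used for the sweeps.
#' @return tibble, one row per specimen.
#' @export
specimen_summary_table <- function(sweeps, morphology) {
  rows <- purrr::imap(sweeps, function(sw, id) {
    m <- morphology[morphology$specimen_id == id, ]
    ex <- specimen_extremes(sw)
    ex$specimen_id <- id
    ex$species <- m$species
    ex$mass_total <- m$mass_total
    ex$length_body <- m$length_body
    ex$length_torso <- m$length_torso
    ex$mass_frac_tt <- (m$mass_torso + m$mass_tail) / m$mass_total
    ex$x_cg_aft_frac <- ex$x_cg_aft_mean / m$length_body
    ex$wingspan <- m$wingspan
    ex
  })
  dplyr::bind_rows(rows)
}

#' Species-mean trait table
#'
#' Species means of the per-specimen traits used in the evolutionary
#' analyses: maximum and minimum static margin, aft CG fraction, absolute
#' agility extrema and log body mass.
#'
#' @param specimen_summary output of [specimen_summary_table()].
#' @return tibble, one row per species.
#' @export
species_trait_table <- function(specimen_summary) {
  dplyr::summarise(
    dplyr::group_by(specimen_summary, .data$species),
    sm_max = mean(.data$sm_max),
    sm_min = mean(.data$sm_min),
    x_cg_aft_frac = mean(.data$x_cg_aft_frac),
    abs_agility_max = mean(.data$abs_agility_max),
    abs_agility_min = mean(.data$abs_agility_min),
    log_mass = log(mean(.data$mass_total)),
    n_specimens = dplyr::n(),
    .groups = "drop"
  )
}

#' Named trait vector for the phylogenetic fits
#'
#' @param species_traits output of [species_trait_table()].
#' @param trait column name.
#' @return named numeric vector keyed by species.
#' @export
trait_vector <- function(species_traits, trait) {
  stats::setNames(species_traits[[trait]], species_traits$species)
}
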