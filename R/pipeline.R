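#' Scaled-down hydration sweep of the hotspot simulation
#'
#' Runs the package's standard scaled-down study: a 2 mm disk domain with
#' 200 founder cells simulated for 8 hours at 10 s steps, across a set of
#' matric potentials and replicate seeds, and post-processes each run into
#' the demographic summaries (final population, realized mean generation
#' time, dominant/rare lineage classification and the rare lineages' summed
#' biomass share).  The replicate network is rebuilt per seed so both the
#' pore geometry and the agent dynamics vary across replicates.
#'
#' @param psi_values Matric potentials to sweep (kPa).
#' @param seeds Replicate seeds.
#' @param disk_radius_mm Domain radius (mm).
#' @param n_inoculum Founder cells per run.
#' @param t_end_s Simulated horizon (s).
#' @param n_hetero_regions Heterogeneity regions in the scaled domain.
#' @param dt_s Time step (s).
#' @param ... Further arguments to \code{\link{sim_config}}.
#' @return data.frame with one row per (psi, seed): \code{psi}, \code{seed},
#'   \code{n_final}, \code{total_biomass_fg}, \code{n_events},
#'   \code{mean_generation_time_h}, \code{fraction_dominant},
#'   \code{rare_biomass_fraction}, \code{n_zero_success}.
#' @examples
#' \donttest{
#' sweep <- run_hotspot_sweep(psi_values = c(-3, -7), seeds = 1,
#'                            disk_radius_mm = 0.5, n_inoculum = 50,
#'                            t_end_s = 3600)
#' }
#' @export
run_hotspot_sweep <- function(psi_values = c(0, -3, -7), seeds = 1:3,
                              disk_radius_mm = 2, n_inoculum = 200,
                              t_end_s = 8 * 3600, n_hetero_regions = 2,
                              dt_s = 10, ...) {
  rows <- list()
  for (seed in seeds) {
    net <- build_pore_network(disk_radius_mm, seed = seed,
                              n_hetero_regions = n_hetero_regions)
    for (psi in psi_values) {
      cfg <- sim_config(psi = psi, n_inoculum = n_inoculum,
                        t_end_s = t_end_s, dt_s = dt_s, seed = seed, ...)
      sim <- simulate_hotspot(cfg, net)
      fin <- sim$snapshots[[length(sim$snapshots)]]
      lt <- lineage_table(sim$events, fin, sim$inoculum_lineages)
      cl <- classify_dominant_rare(lt)
      gt <- sim$events$generation_time_s / 3600
      rows[[length(rows) + 1L]] <- data.frame(
        psi = psi, seed = seed, n_final = nrow(fin),
        total_biomass_fg = sum(fin$biomass_fg),
        n_events = nrow(sim$events),
        mean_generation_time_h = if (length(gt)) mean(gt) else NA_real_,
        fraction_dominant = cl$fraction_dominant,
        rare_biomass_fraction = cl$rare_biomass_fraction,
        n_zero_success = sum(lt$reproductive_success == 0))
    }
  }
  do.call(rbind, rows)
}

#' Majority verdict over replicate seeds
#'
#' For a per-seed logical comparison, the verdict that holds for more than
#' half the seeds.
#'
#' @param x Logical vector, one entry per seed.
#' @return Single logical.
#' @export
majority <- function(x) sum(x) > length(x) / 2
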