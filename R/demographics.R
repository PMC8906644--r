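#' Extrapolate a cell's generation time from its current state
#'
#' For a cell that has not yet divided, the most likely generation time under
#' present local conditions is its current age plus the time still needed to
#' assimilate the biomass gap to division at its localized net growth rate:
#' \eqn{\hat\tau = age + \ln(m_{div}/m) / (\mu - m_{maint})}.  Cells at or
#' below maintenance can never close the gap; they receive the censoring cap
#' and are flagged.
#'
#' @param age Current age (h), vectorized.
#' @param biomass Current biomass (fg), in \code{[m_birth, m_division]}.
#' @param mu_local Localized specific growth rate (1/h).
#' @param p A \code{\link{growth_params}}.
#' @param cap Censoring value (h) returned when net growth is non-positive;
#'   the package convention is ten times the simulated horizon.
#' @return data.frame with \code{tau_hat_h} and \code{censored}.
#' @examples
#' p <- growth_params(maintenance_m = 0)
#' extrapolate_generation_time(0, p$m_birth, 1, p)  # ln 2 hours
#' @export
extrapolate_generation_time <- function(age, biomass, mu_local,
                                        p = growth_params(), cap = 7200) {
  stopifnot(all(age >= 0), all(mu_local >= 0))
  if (any(biomass > p$m_division * (1 + 1e-9)))
    stop("invariant violation: biomass exceeds the division threshold")
  net <- mu_local - p$maintenance_m
  growing <- net > 0
  tau <- ifelse(growing,
                age + log(p$m_division / pmax(biomass, 1e-300)) / ifelse(growing, net, 1),
                cap)
  data.frame(tau_hat_h = tau, censored = !growing)
}

#' Generation-time sample from a simulation
#'
#' Combines realized generation times (from the division-event log) with
#' extrapolated ones for the cells alive at the final snapshot, in hours.
#'
#' @param sim A \code{hotspot_sim}, or a list with \code{events} and a final
#'   snapshot data.frame under \code{snapshots}.
#' @param extrapolate Include extrapolated values for live cells.
#' @param cap Censoring cap (h); default ten times the simulated horizon.
#' @return data.frame with \code{value_h} and \code{status} in
#'   \code{realized | extrapolated | censored}.
#' @export
generation_time_sample <- function(sim, extrapolate = TRUE, cap = NULL) {
  ev <- sim$events
  out <- data.frame(value_h = ev$generation_time_s / 3600,
                    status = rep("realized", nrow(ev)))
  if (extrapolate) {
    fin <- sim$snapshots[[length(sim$snapshots)]]
    p <- sim$config$growth
    if (is.null(cap)) cap <- 10 * sim$config$t_end_s / 3600
    ex <- extrapolate_generation_time(fin$age_s / 3600, fin$biomass_fg,
                                      fin$mu_per_h, p, cap = cap)
    out <- rbind(out, data.frame(value_h = ex$tau_hat_h,
                                 status = ifelse(ex$censored, "censored",
                                                 "extrapolated")))
  }
  out[out$value_h > 0, , drop = FALSE]
}

#' Empirical CDF of generation times
#'
#' Thin wrapper around \code{stats::ecdf} that validates the sample; the
#' result is the usual right-continuous step function with F(max) = 1.
#'
#' @param values Positive generation times (any unit).
#' @return An \code{ecdf} function.
#' @export
generation_time_ecdf <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("empty generation-time sample")
  stats::ecdf(values)
}

#' Per-lineage summary table
#'
#' One row per inoculated barcode: reproductive success (the maximum
#' generation reached by any cell of the lineage during the run), final cell
#' count and biomass fraction, mean cell age and mean realized generation
#' time.  Lineages that never divided have reproductive success 0 and an
#' \code{NA} mean generation time.
#'
#' @param events Division-event data.frame (\code{lineage_id},
#'   \code{generation}, \code{generation_time_s}).
#' @param final_snapshot Final population snapshot data.frame.
#' @param inoculum_lineages All founder lineage ids (so extinct-from-records
#'   lineages still appear); defaults to the lineages present in the
#'   snapshot.
#' @return data.frame of class \code{lineage_table}.
#' @export
lineage_table <- function(events, final_snapshot,
                          inoculum_lineages = NULL) {
  if (is.null(inoculum_lineages))
    inoculum_lineages <- sort(unique(final_snapshot$lineage_id))
  if (!all(final_snapshot$lineage_id %in% inoculum_lineages))
    stop("orphan lineage id in snapshot: not part of the inoculum registry")
  if (nrow(events) > 0 && !all(events$lineage_id %in% inoculum_lineages))
    stop("orphan lineage id in event log: not part of the inoculum registry")
  lin <- inoculum_lineages
  f <- factor(final_snapshot$lineage_id, levels = lin)
  n_cells <- as.integer(table(f))
  biomass <- as.numeric(rowsum(final_snapshot$biomass_fg, f, reorder = FALSE))
  biomass[is.na(biomass)] <- 0
  total_b <- sum(final_snapshot$biomass_fg)
  mean_age <- as.numeric(tapply(final_snapshot$age_s / 3600, f, mean))
  # reproductive success: max generation reached (snapshot or event log)
  rs_snap <- as.numeric(tapply(final_snapshot$generation, f, max))
  rs_snap[is.na(rs_snap)] <- 0
  rs_ev <- rep(0, length(lin))
  mean_gt <- rep(NA_real_, length(lin))
  if (nrow(events) > 0) {
    fe <- factor(events$lineage_id, levels = lin)
    ev_max <- tapply(events$generation, fe, max)
    rs_ev[!is.na(ev_max)] <- ev_max[!is.na(ev_max)]
    gt <- tapply(events$generation_time_s / 3600, fe, mean)
    mean_gt[!is.na(gt)] <- gt[!is.na(gt)]
  }
  out <- data.frame(lineage_id = lin,
                    reproductive_success = as.integer(pmax(rs_snap, rs_ev)),
                    n_cells_final = n_cells,
                    biomass_fraction_final = biomass / total_b,
                    mean_age_h = mean_age,
                    mean_generation_time_h = mean_gt)
  class(out) <- c("lineage_table", "data.frame")
  out
}

#' Minimum cross-entropy threshold
#'
#' Li's minimum cross-entropy thresholding, originally formulated for image
#' segmentation, applied to a one-dimensional sample: for every candidate
#' cut \code{t} (midpoints between sorted unique values) the objective
#' \eqn{\eta(t) = -\sum_{x<t} x\ln\mu_{low}(t) - \sum_{x\ge t} x\ln\mu_{high}(t)}
#' is evaluated exhaustively (the sample is one value per lineage, so the
#' scan is cheap and oracle-grade) and the minimizing cut returned.  Ties
#' break to the lower threshold.  A class whose members are all zero
#' contributes nothing to the objective, so zero-inflated samples (lineages
#' that never divided) are handled without shifting.
#'
#' @param values Non-negative reals with at least two distinct values.
#' @return The threshold (numeric scalar); values \code{>= threshold} form
#'   the upper class.
#' @examples
#' min_cross_entropy_threshold(c(1, 1, 1, 100, 100))
#' @export
min_cross_entropy_threshold <- function(values) {
  stopifnot(all(values >= 0), all(is.finite(values)))
  u <- sort(unique(values))
  if (length(u) < 2)
    stop("no partition: all values identical")
  cuts <- (u[-1] + u[-length(u)]) / 2
  obj <- vapply(cuts, function(tc) {
    lo <- values[values < tc]; hi <- values[values >= tc]
    s_lo <- sum(lo); s_hi <- sum(hi)
    e <- 0
    if (s_lo > 0) e <- e - s_lo * log(mean(lo))
    if (s_hi > 0) e <- e - s_hi * log(mean(hi))
    e
  }, numeric(1))
  cuts[which.min(obj)]
}

#' Classify lineages as dominant or rare
#'
#' Applies the minimum cross-entropy threshold to lineage reproductive
#' success (default) or to log relative abundance, labels each lineage, and
#' summarizes: the fraction of the inoculum that is dominant and the summed
#' final-biomass share of the rare lineages.  If the sample admits no
#' partition (all values identical) every lineage is labeled dominant.
#'
#' @param lt A \code{\link{lineage_table}}.
#' @param variable \code{"success"} (reproductive success) or
#'   \code{"abundance"} (log10 of the final biomass fraction).
#' @return List with \code{table} (the labeled lineage table),
#'   \code{threshold}, \code{fraction_dominant}, \code{fraction_rare},
#'   \code{rare_biomass_fraction}.
#' @export
classify_dominant_rare <- function(lt, variable = c("success", "abundance")) {
  variable <- match.arg(variable)
  x <- switch(variable,
              success = lt$reproductive_success,
              abundance = log10(pmax(lt$biomass_fraction_final, 1e-12)))
  if (variable == "abundance") x <- x - min(x) # shift to non-negative support
  thr <- tryCatch(min_cross_entropy_threshold(x), error = function(e) NA_real_)
  if (is.na(thr)) {
    lab <- rep("dominant", nrow(lt))
  } else {
    lab <- ifelse(x >= thr, "dominant", "rare")
  }
  lt$label <- lab
  rare <- lab == "rare"
  list(table = lt, threshold = thr,
       fraction_dominant = mean(lab == "dominant"),
       fraction_rare = mean(rare),
       rare_biomass_fraction = sum(lt$biomass_fraction_final[rare]))
}

#' Cell-age histogram with a bimodality report
#'
#' Normalized histogram of cell ages plus Sarle-style bimodality screening:
#' the coefficient \eqn{b = (skew^2 + 1)/kurtosis} (population moments,
#' kurtosis non-excess) exceeds 5/9 -- the value for a uniform distribution
#' -- for bimodal shapes.
#'
#' @param ages Cell ages (any unit), nonempty.
#' @param bins Number of histogram bins (default 30) or a vector of breaks.
#' @return List with \code{histogram} (a \code{hist} object with
#'   density-normalized bars), \code{bimodality_coefficient},
#'   \code{bimodal} (logical).
#' @export
age_distribution <- function(ages, bins = 30) {
  ages <- ages[!is.na(ages)]
  if (length(ages) == 0) stop("empty age sample")
  h <- graphics::hist(ages, breaks = bins, plot = FALSE)
  m <- mean(ages)
  m2 <- mean((ages - m)^2)
  if (m2 == 0) {
    bc <- NA_real_
  } else {
    skew <- mean((ages - m)^3) / m2^1.5
    kurt <- mean((ages - m)^4) / m2^2
    bc <- (skew^2 + 1) / kurt
  }
  list(histogram = h, bimodality_coefficient = bc,
       bimodal = isTRUE(bc > 5 / 9))
}

#' Write demographic outputs as CSV/JSON
#'
#' Writes \code{lineages.csv} (the labelled lineage table),
#' \code{gen_times.csv} (value_h, status) and \code{ages.csv} plus a JSON
#' summary with the dominant/rare fractions.
#'
#' @param sim A \code{hotspot_sim}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_demographics <- function(sim, dir) {
  stopifnot(inherits(sim, "hotspot_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fin <- sim$snapshots[[length(sim$snapshots)]]
  lt <- lineage_table(sim$events, fin, sim$inoculum_lineages)
  cl <- classify_dominant_rare(lt)
  utils::write.csv(cl$table, file.path(dir, "lineages.csv"),
                   row.names = FALSE)
  gt <- generation_time_sample(sim)
  utils::write.csv(gt, file.path(dir, "gen_times.csv"), row.names = FALSE)
  utils::write.csv(data.frame(age_h = fin$age_s / 3600),
                   file.path(dir, "ages.csv"), row.names = FALSE)
  jsonlite::write_json(list(threshold = cl$threshold,
                            fraction_dominant = cl$fraction_dominant,
                            fraction_rare = cl$fraction_rare,
                            rare_biomass_fraction = cl$rare_biomass_fraction),
                       file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
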