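#' Growth parameters of the simulated bacterium
#'
#' Dual-Monod obligate aerobe with maintenance and symmetric division at
#' doubled birth biomass.  The default maximum specific growth rate gives a
#' 28-minute generation time under saturating carbon and oxygen.
#'
#' @param mu_max Maximum specific growth rate, 1/h (default
#'   \code{log(2)/(28/60)} ~ 1.485).
#' @param K_C,K_O Monod half-saturation constants for carbon and oxygen (mM).
#' @param yield_Y Biomass produced per substrate mass consumed (fg/fg).
#' @param maintenance_m Maintenance rate, 1/h; cells below the dormancy floor
#'   (half the birth biomass) stop paying maintenance and rest there (no
#'   death in the model).
#' @param m_birth Birth biomass, fg; division fires at \code{2 * m_birth}.
#' @param oxygen_dependent If \code{FALSE} the oxygen Monod factor is 1 and
#'   no oxygen is consumed (facultative-anaerobe switch).
#' @param motile If \code{FALSE} cells never move (motility switch).
#' @return Object of class \code{growth_params}.
#' @export
growth_params <- function(mu_max = log(2) / (28 / 60),
                          K_C = 0.01, K_O = 0.01,
                          yield_Y = 0.5, maintenance_m = 0.005,
                          m_birth = 150,
                          oxygen_dependent = TRUE, motile = TRUE) {
  stopifnot(mu_max > 0, K_C > 0, K_O > 0, yield_Y > 0, maintenance_m >= 0,
            m_birth > 0)
  structure(list(mu_max = mu_max, K_C = K_C, K_O = K_O, yield_Y = yield_Y,
                 maintenance_m = maintenance_m, m_birth = m_birth,
                 m_division = 2 * m_birth,
                 oxygen_dependent = isTRUE(oxygen_dependent),
                 motile = isTRUE(motile)),
            class = "growth_params")
}

#' Run-and-tumble motility parameters
#'
#' @param run_speed Swimming speed, um/s.
#' @param tumble_rate Baseline tumble rate, 1/s.
#' @param chemo_bias Chemotactic bias in [0, 1): tumbling is suppressed by
#'   the factor \code{(1 - chemo_bias)} when swimming up the carbon gradient
#'   and enhanced by \code{(1 + chemo_bias)} otherwise.
#' @param pinning_film_um Water-film thickness below which capillary pinning
#'   immobilizes the cell; the run speed ramps linearly from 0 at the
#'   threshold to full speed at three times the threshold.
#' @return Object of class \code{motility_params}.
#' @export
motility_params <- function(run_speed = 20, tumble_rate = 1,
                            chemo_bias = 0.5, pinning_film_um = 1) {
  stopifnot(run_speed >= 0, tumble_rate >= 0,
            chemo_bias >= 0, chemo_bias < 1, pinning_film_um >= 0)
  structure(list(run_speed = run_speed, tumble_rate = tumble_rate,
                 chemo_bias = chemo_bias, pinning_film_um = pinning_film_um),
            class = "motility_params")
}

#' Simulation configuration
#'
#' @param psi Matric potential (kPa, <= 0), or use \code{psi_schedule}.
#' @param psi_schedule Optional piecewise-constant hydration schedule:
#'   list with \code{time_s} (breakpoints, starting at 0) and \code{psi}.
#' @param n_inoculum Number of founder cells (default 1000).
#' @param t_end_s Simulated horizon in seconds (default 30 days).
#' @param dt_s Macro time step in seconds (default 10).
#' @param seed RNG seed; a fixed seed yields an identical event log.
#' @param growth,motility Parameter objects (defaults used when NULL).
#' @param carbon_source_mM Carbon concentration clamped at the center node.
#' @param carbon_rim_mM Carbon concentration clamped at rim nodes,
#'   representing diffusive loss into the surrounding carbon-poor bulk soil
#'   (default 0).  Set to \code{NA} for a sealed (no-flux) rim, in which
#'   case the cell-free carbon field is uniform at the source concentration.
#' @param oxygen_boundary_mM Dissolved oxygen clamped at rim nodes.
#' @param D_aq_carbon,D_aq_oxygen,D_gas_oxygen Free diffusivities (um^2/s).
#' @param henry Dimensionless Henry-law multiplier on the oxygen gas path.
#' @param snapshot_times_s Times (s) at which full population snapshots are
#'   recorded; the final time is always included.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(psi = -3, psi_schedule = NULL,
                       n_inoculum = 1000, t_end_s = 30 * 86400, dt_s = 10,
                       seed = 1L, growth = NULL, motility = NULL,
                       carbon_source_mM = 0.1, carbon_rim_mM = 0,
                       oxygen_boundary_mM = 0.27,
                       D_aq_carbon = 600, D_aq_oxygen = 2000,
                       D_gas_oxygen = 2e7, henry = 30,
                       snapshot_times_s = NULL) {
  stopifnot(dt_s > 0, t_end_s >= dt_s, n_inoculum >= 1)
  if (is.null(growth)) growth <- growth_params()
  if (is.null(motility)) motility <- motility_params()
  stopifnot(inherits(growth, "growth_params"),
            inherits(motility, "motility_params"))
  if (!is.null(psi_schedule))
    stopifnot(length(psi_schedule$time_s) == length(psi_schedule$psi),
              psi_schedule$time_s[1] == 0, all(psi_schedule$psi <= 0))
  else stopifnot(psi <= 0)
  structure(list(psi = psi, psi_schedule = psi_schedule,
                 n_inoculum = as.integer(n_inoculum),
                 t_end_s = t_end_s, dt_s = dt_s, seed = as.integer(seed),
                 growth = growth, motility = motility,
                 carbon_source_mM = carbon_source_mM,
                 carbon_rim_mM = carbon_rim_mM,
                 oxygen_boundary_mM = oxygen_boundary_mM,
                 D_aq_carbon = D_aq_carbon, D_aq_oxygen = D_aq_oxygen,
                 D_gas_oxygen = D_gas_oxygen, henry = henry,
                 snapshot_times_s = snapshot_times_s),
            class = "sim_config")
}

#' Dual-Monod specific growth rate
#'
#' \eqn{\mu = \mu_{max} \frac{C}{K_C + C} \frac{O}{K_O + O}}; the oxygen
#' factor is 1 for oxygen-independent growth.
#'
#' @param C,O Local carbon and oxygen concentrations (mM), vectorized.
#' @param p A \code{\link{growth_params}}.
#' @return Specific growth rate(s), 1/h, in \code{[0, mu_max]}.
#' @examples
#' p <- growth_params()
#' monod_rate(p$K_C, 1e6, p)  # half of mu_max
#' @export
monod_rate <- function(C, O, p) {
  stopifnot(inherits(p, "growth_params"), all(C >= 0), all(O >= 0))
  ofac <- if (p$oxygen_dependent) O / (p$K_O + O) else 1
  p$mu_max * C / (p$K_C + C) * ofac
}

# Vectorized biomass update over one step.  Exact exponential update at net
# rate (mu - m); biomass floored at the dormancy floor 0.5*m_birth with
# maintenance suspended there.  Returns new biomass plus the substrate uptake
# and maintenance loss (biomass units, fg) realized along the trajectory, so
# the biomass ledger closes exactly: dB = uptake - maintenance.
.grow_core <- function(biomass, mu, dt_s, p) {
  dt_h <- .seconds_to_hours(dt_s)
  r <- mu - p$maintenance_m
  fac <- exp(r * dt_h)
  b_new <- biomass * fac
  # integral of mu*B dt along B(t) = B0 e^{rt}: B0 (e^{r dt}-1) mu / r
  growth_int <- biomass * dt_h
  nz <- abs(r) > 1e-12
  growth_int[nz] <- biomass[nz] * (fac[nz] - 1) / r[nz]
  uptake <- growth_int * mu
  # dormancy floor: maintenance can never shrink a cell below 0.5*m_birth
  # (nor below its starting biomass if it somehow began under the floor)
  floor_b <- 0.5 * p$m_birth
  b_new <- pmax(b_new, pmin(biomass, floor_b))
  maintenance <- uptake - (b_new - biomass)
  list(biomass = b_new, uptake = uptake, maintenance = maintenance)
}

#' Grow a cell for one step and divide if ripe
#'
#' Single-cell form of the growth/division update used by the simulator:
#' exact exponential biomass update at net rate \code{mu - maintenance_m},
#' division when biomass reaches twice the birth biomass (to within a 1e-9
#' relative floating-point guard), splitting into two equal daughters of age
#' zero and incremented generation.  The parent's age at the moment of
#' division is recorded as the generation time.
#'
#' @param cell List with \code{cell_id}, \code{lineage_id}, \code{generation},
#'   \code{biomass}, \code{birth_time}.
#' @param mu Local specific growth rate (1/h).
#' @param dt_s Step length (s).
#' @param now Time at the start of the step (s).
#' @param p A \code{\link{growth_params}}.
#' @param next_ids Integer ids to assign to daughters on division.
#' @return List with \code{cells} (list of one or two cell lists) and
#'   \code{event} (\code{NULL} or a division-event list).
#' @export
grow_and_maybe_divide <- function(cell, mu, dt_s, now, p = growth_params(),
                                  next_ids = c(cell$cell_id * 2L,
                                               cell$cell_id * 2L + 1L)) {
  stopifnot(mu >= 0)
  g <- .grow_core(cell$biomass, mu, dt_s, p)
  b <- g$biomass
  t_next <- now + dt_s
  if (b >= p$m_division * (1 - 1e-9)) {
    gen_time <- t_next - cell$birth_time
    kid <- function(id) {
      k <- cell
      k$cell_id <- id
      k$biomass <- b / 2
      k$birth_time <- t_next
      k$generation <- cell$generation + 1L
      k
    }
    list(cells = list(kid(next_ids[1]), kid(next_ids[2])),
         event = list(time = t_next, lineage_id = cell$lineage_id,
                      parent_cell_id = cell$cell_id,
                      child_ids = next_ids, generation_time = gen_time,
                      generation_of_children = cell$generation + 1L))
  } else {
    cell$biomass <- b
    list(cells = list(cell), event = NULL)
  }
}

# film-limited speed factor: 0 below the pinning threshold, linear ramp to 1
# at 3x the threshold
.film_speed_factor <- function(film, pinning) {
  if (pinning <= 0) return(rep(1, length(film)))
  pmin(pmax((film - pinning) / (2 * pinning), 0), 1)
}

#' One run-and-tumble motility step
#'
#' Single-cell contract of the motility update: cells in films thinner than
#' the pinning threshold do not move; otherwise the cell runs along its
#' channel at the film-limited speed, tumbling (choosing a fresh random
#' heading) with probability \eqn{1 - e^{-\lambda_{eff} dt}} where
#' \eqn{\lambda_{eff}} is the tumble rate suppressed by the chemotactic bias
#' when moving up the local carbon gradient and enhanced when moving down.
#' At a node the cell continues into a uniformly chosen wetted channel.
#'
#' @param cell List with \code{channel}, \code{offset}, \code{heading}.
#' @param local_gradient Carbon concentration difference along the channel
#'   (value at node_b minus at node_a).
#' @param film_thickness Water film thickness in the cell's channel (um).
#' @param mp A \code{\link{motility_params}}.
#' @param dt_s Step length (s).
#' @param network The \code{pore_network} (for node adjacency).
#' @return The updated cell list.
#' @export
motility_step <- function(cell, local_gradient, film_thickness, mp, dt_s,
                          network) {
  stopifnot(dt_s > 0, inherits(mp, "motility_params"))
  st <- .cells_state(list(channel = cell$channel, offset = cell$offset,
                          heading = cell$heading))
  adj <- .node_channels(network)
  nch <- nrow(network$channels)
  gradv <- numeric(nch)
  gradv[st$channel] <- local_gradient
  film <- rep(film_thickness, nch)
  out <- .motility_core(st, gradv, film, mp, dt_s, network, adj)
  list(channel = out$channel, offset = out$offset, heading = out$heading)
}

# package cell vectors into a lightweight state list
.cells_state <- function(x) {
  list(channel = as.integer(x$channel), offset = as.numeric(x$offset),
       heading = as.integer(x$heading))
}

# adjacency: for each node, the ids of incident channels, flattened for
# O(1) vectorized lookup (flat channel ids, per-node start pointer, degree)
.node_channels <- function(network) {
  ne <- nrow(network$channels)
  nn <- nrow(network$nodes)
  nd <- c(network$channels$node_a, network$channels$node_b)
  chs <- rep(seq_len(ne), 2L)
  o <- order(nd)
  deg <- tabulate(nd, nbins = nn)
  list(flat = chs[o], ptr = c(0L, cumsum(deg)), deg = deg)
}

# Vectorized run-and-tumble over one dt for all cells.
# grad: per-channel carbon difference (node_b - node_a); film: per-channel
# film thickness.  Cells crossing a node pick a uniform random incident
# channel and keep spending their remaining run length (at most 4 hops).
.motility_core <- function(st, grad, film, mp, dt_s, network, adj) {
  ch <- st$channel; off <- st$offset; hd <- st$heading
  n <- length(ch)
  if (n == 0) return(st)
  speed <- mp$run_speed * .film_speed_factor(film[ch], mp$pinning_film_um)
  # tumble first: effective rate depends on alignment with the carbon
  # gradient (up-gradient runs tumble less, down-gradient runs tumble more)
  up <- hd * sign(grad[ch]) > 0
  lam <- mp$tumble_rate * (1 + mp$chemo_bias - 2 * mp$chemo_bias * up)
  tumbles <- which(stats::runif(n) < (1 - exp(-lam * dt_s)))
  hd[tumbles] <- 1L - 2L * (stats::runif(length(tumbles)) < 0.5)
  node_a <- network$channels$node_a
  node_b <- network$channels$node_b
  remaining <- speed * dt_s / network$channels$length_um[ch] # in offset units
  for (hop in 1:4) {
    active <- which(remaining > 0)
    if (!length(active)) break
    tgt <- off[active] + hd[active] * remaining[active]
    inside <- tgt > 0 & tgt < 1
    ia <- active[inside]
    off[ia] <- tgt[inside]
    remaining[ia] <- 0
    ix <- active[!inside]
    if (!length(ix)) break
    hit_b <- hd[ix] > 0
    spent <- off[ix]
    spent[hit_b] <- 1 - spent[hit_b]
    remaining[ix] <- pmax(remaining[ix] - spent, 0)
    node <- node_a[ch[ix]]
    node[hit_b] <- node_b[ch[ix]][hit_b]
    # uniform random incident channel at the node (flat adjacency lookup)
    pick <- ceiling(stats::runif(length(ix)) * adj$deg[node])
    newch <- adj$flat[adj$ptr[node] + pick]
    ch[ix] <- newch
    from_a <- node_a[newch] == node
    off[ix] <- as.numeric(!from_a)
    hd[ix] <- 2L * from_a - 1L
  }
  list(channel = ch, offset = off, heading = hd)
}

# hydration-dependent state bundle: channel geometry, conductances,
# transport operators, per-channel film and carbon gradient support
.hydrate_state <- function(network, cfg, psi) {
  hyd <- hydration_params(psi)
  geom <- corner_water_geometry(network$channels, hyd)
  gC <- assemble_conductances(network, hyd, list(D_aq0 = cfg$D_aq_carbon))
  gO <- assemble_conductances(network, hyd,
                              list(D_aq0 = cfg$D_aq_oxygen,
                                   D_gas0 = cfg$D_gas_oxygen,
                                   henry = cfg$henry))
  c_nodes <- cfg$carbon_source_node %||% network$center_node
  c_vals <- rep(cfg$carbon_source_mM, length(c_nodes))
  rim <- cfg$carbon_rim_mM %||% NA
  if (!is.na(rim)) {
    bn <- setdiff(network$boundary_nodes, c_nodes)
    c_nodes <- c(c_nodes, bn)
    c_vals <- c(c_vals, rep(rim, length(bn)))
  }
  opC <- transport_operator(network, gC, c_nodes, c_vals)
  opO <- transport_operator(network, gO, network$boundary_nodes,
                            rep(cfg$oxygen_boundary_mM,
                                length(network$boundary_nodes)))
  list(hydration = hyd, geom = geom, opC = opC, opO = opO)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate the hotspot population
#'
#' Runs the full individual-based loop (uptake sinks, quasi-steady transport
#' solve for carbon and oxygen, Monod growth with maintenance, symmetric
#' division with lineage/generation bookkeeping, film-limited run-and-tumble
#' motility) from time 0 to the configured horizon.  Founder cells receive
#' unique lineage barcodes inherited by all progeny; every division is
#' appended to the event log.  There is no death: the population size is
#' non-decreasing.
#'
#' @param config A \code{\link{sim_config}}.
#' @param network A \code{pore_network}.
#' @param progress Print a progress line every simulated day.
#' @return Object of class \code{hotspot_sim}: list with \code{events}
#'   (data.frame: time_s, lineage_id, parent_id, child1_id, child2_id,
#'   generation_time_s, generation), \code{snapshots} (list of data.frames:
#'   time_s, cell_id, lineage_id, generation, age_s, biomass_fg, channel_id,
#'   offset, mu_per_h), \code{final_field} (data.frame: node_id, carbon_mM,
#'   oxygen_mM), \code{ledger} (per-step totals for the biomass balance),
#'   \code{inoculum_lineages}, \code{config}, \code{n_pores}.
#' @examples
#' net <- toy_pore_network(3, seed = 2)
#' cfg <- sim_config(psi = -3, n_inoculum = 20, t_end_s = 3600, seed = 7)
#' sim <- simulate_hotspot(cfg, net)
#' sim
#' @export
simulate_hotspot <- function(config, network, progress = FALSE) {
  stopifnot(inherits(config, "sim_config"), inherits(network, "pore_network"))
  if (network$segment_length_um <= 0 ||
      nrow(network$channels) < 1)
    stop("config/network mismatch: empty network")
  p <- config$growth
  mp <- config$motility
  dt <- config$dt_s
  nsteps <- floor(config$t_end_s / dt)
  set.seed(config$seed)

  sched <- config$psi_schedule
  psi_at <- function(t) {
    if (is.null(sched)) return(config$psi)
    sched$psi[findInterval(t, sched$time_s)]
  }
  hs <- .hydrate_state(network, config, psi_at(0))
  adj <- .node_channels(network)
  nch <- nrow(network$channels)
  nn <- nrow(network$nodes)
  ch_len <- network$channels$length_um
  node_a <- network$channels$node_a
  node_b <- network$channels$node_b

  # inoculate uniformly at random over (wetted) channels; corner water keeps
  # every channel wetted, so this is uniform over channels
  n0 <- config$n_inoculum
  cells <- list(
    cell_id = seq_len(n0),
    lineage_id = seq_len(n0),
    generation = rep(0L, n0),
    biomass = rep(p$m_birth, n0),
    birth_time = rep(0, n0),
    channel = sample.int(nch, n0, replace = TRUE),
    offset = stats::runif(n0),
    heading = ifelse(stats::runif(n0) < 0.5, 1L, -1L))
  next_id <- n0 + 1L

  snap_times <- sort(unique(c(config$snapshot_times_s, nsteps * dt)))
  snap_steps <- unique(pmax(1, round(snap_times / dt)))
  snapshots <- vector("list", length(snap_steps))
  names(snapshots) <- as.character(snap_steps * dt)

  events <- vector("list", 256); n_ev <- 0L
  ledger <- matrix(0, nrow = nsteps, ncol = 5,
                   dimnames = list(NULL, c("time_s", "n_cells",
                                           "total_biomass_fg", "uptake_fg",
                                           "maintenance_fg")))

  # initial fields with no uptake
  solC <- solve_quasi_steady(hs$opC)
  solO <- solve_quasi_steady(hs$opO)
  C <- solC$concentration; O <- solO$concentration
  mu_s_prev <- rep(0, n0) # per-cell mu (1/s) from the previous step

  cell_node <- function() {
    nd <- node_b[cells$channel]
    lo <- cells$offset < 0.5
    nd[lo] <- node_a[cells$channel[lo]]
    nd
  }

  for (step in seq_len(nsteps)) {
    now <- (step - 1) * dt
    if (!is.null(sched)) {
      new_psi <- psi_at(now)
      if (new_psi != psi_at(now - dt) || step == 1)
        hs <- .hydrate_state(network, config, new_psi)
    }
    nodes <- cell_node()

    # --- uptake sinks from current biomass and last step's rates ---
    demand_fg_s <- cells$biomass * mu_s_prev / p$yield_Y
    sinkC <- numeric(nn)
    agg <- rowsum(demand_fg_s, nodes)
    sinkC[as.integer(rownames(agg))] <- agg[, 1] / .SUBSTRATE_FG_PER_UM3MM
    solC <- solve_quasi_steady(hs$opC, sinkC, diagnostics = FALSE)
    C <- solC$concentration
    # flux limitation: where capping reduced the nodal sink below demand,
    # cells at that node receive proportionally reduced uptake
    scale <- rep(1, nn)
    pos <- sinkC > 0
    scale[pos] <- solC$sinks[pos] / sinkC[pos]
    if (p$oxygen_dependent) {
      sinkO <- sinkC * .O2_PER_SUBSTRATE_MOL
      solO <- solve_quasi_steady(hs$opO, sinkO, diagnostics = FALSE)
      O <- solO$concentration
      scaleO <- rep(1, nn)
      scaleO[pos] <- solO$sinks[pos] / sinkO[pos]
      scale <- pmin(scale, scaleO)
    }

    # --- growth and division ---
    mu <- monod_rate(C[nodes], O[nodes], p) * scale[nodes]
    g <- .grow_core(cells$biomass, mu, dt, p)
    cells$biomass <- g$biomass
    ledger[step, ] <- c(now + dt, length(cells$cell_id),
                        sum(cells$biomass), sum(g$uptake), sum(g$maintenance))
    div <- which(cells$biomass >= p$m_division * (1 - 1e-9))
    if (length(div)) {
      nd <- length(div)
      t_div <- now + dt
      kid1 <- next_id + seq_len(nd) - 1L
      kid2 <- kid1 + nd
      next_id <- next_id + 2L * nd
      n_ev <- n_ev + 1L
      if (n_ev > length(events)) events <- c(events, vector("list", length(events)))
      events[[n_ev]] <- cbind(time_s = t_div,
                              lineage_id = cells$lineage_id[div],
                              parent_id = cells$cell_id[div],
                              child1_id = kid1, child2_id = kid2,
                              generation_time_s = t_div - cells$birth_time[div],
                              generation = cells$generation[div] + 1L)
      half <- cells$biomass[div] / 2
      # parent slot becomes child 1; child 2 appended
      cells$cell_id[div] <- kid1
      cells$generation[div] <- cells$generation[div] + 1L
      cells$biomass[div] <- half
      cells$birth_time[div] <- t_div
      cells$cell_id <- c(cells$cell_id, kid2)
      cells$lineage_id <- c(cells$lineage_id, cells$lineage_id[div])
      cells$generation <- c(cells$generation, cells$generation[div])
      cells$biomass <- c(cells$biomass, half)
      cells$birth_time <- c(cells$birth_time, rep(t_div, nd))
      cells$channel <- c(cells$channel, cells$channel[div])
      cells$offset <- c(cells$offset, cells$offset[div])
      cells$heading <- c(cells$heading, -cells$heading[div])
      mu <- c(mu, mu[div])
    }
    mu_s_prev <- mu / 3600

    # --- motility ---
    if (p$motile && mp$run_speed > 0) {
      grad <- C[node_b] - C[node_a]
      st <- .motility_core(list(channel = cells$channel,
                                offset = cells$offset,
                                heading = cells$heading),
                           grad, hs$geom$film_thickness_um, mp, dt,
                           network, adj)
      cells$channel <- st$channel
      cells$offset <- st$offset
      cells$heading <- st$heading
    }

    if (step %in% snap_steps) {
      tnow <- step * dt
      nd2 <- cell_node()
      # localized growth rate: Monod on the current fields, flux-limited by
      # the realized/demanded uptake ratio of the step
      snapshots[[as.character(tnow)]] <-
        data.frame(time_s = tnow, cell_id = cells$cell_id,
                   lineage_id = cells$lineage_id,
                   generation = cells$generation,
                   age_s = tnow - cells$birth_time,
                   biomass_fg = cells$biomass,
                   channel_id = cells$channel, offset = cells$offset,
                   mu_per_h = monod_rate(C[nd2], O[nd2], p) * scale[nd2])
    }
    if (progress && (step * dt) %% 86400 == 0)
      message(sprintf("day %g: %d cells", step * dt / 86400,
                      length(cells$cell_id)))
  }

  ev <- if (n_ev > 0) {
    as.data.frame(do.call(rbind, events[seq_len(n_ev)]))
  } else {
    data.frame(time_s = numeric(0), lineage_id = numeric(0),
               parent_id = numeric(0), child1_id = numeric(0),
               child2_id = numeric(0), generation_time_s = numeric(0),
               generation = numeric(0))
  }
  structure(list(events = ev, snapshots = snapshots,
                 final_field = data.frame(node_id = seq_len(nn),
                                          carbon_mM = C, oxygen_mM = O),
                 ledger = as.data.frame(ledger),
                 inoculum_lineages = seq_len(n0),
                 config = config, n_pores = nch),
            class = "hotspot_sim")
}

#' @export
print.hotspot_sim <- function(x, ...) {
  fin <- x$snapshots[[length(x$snapshots)]]
  cat(sprintf("Hotspot simulation: psi = %s kPa, %d founders, %.3g days, %d pores\n",
              if (is.null(x$config$psi_schedule)) x$config$psi else "scheduled",
              x$config$n_inoculum, x$config$t_end_s / 86400, x$n_pores))
  cat(sprintf("  final population %d cells, %d division events\n",
              nrow(fin), nrow(x$events)))
  invisible(x)
}

#' @export
summary.hotspot_sim <- function(object, ...) {
  fin <- object$snapshots[[length(object$snapshots)]]
  gt <- object$events$generation_time_s / 3600
  out <- list(n_final = nrow(fin), n_events = nrow(object$events),
              total_biomass_fg = sum(fin$biomass_fg),
              mean_generation_time_h = if (length(gt)) mean(gt) else NA_real_,
              median_generation_time_h = if (length(gt)) stats::median(gt) else NA_real_,
              max_generation = max(c(0, fin$generation)))
  class(out) <- "summary.hotspot_sim"
  out
}

#' @export
print.summary.hotspot_sim <- function(x, ...) {
  cat(sprintf("final cells: %d  divisions: %d  biomass: %.4g fg\n",
              x$n_final, x$n_events, x$total_biomass_fg))
  cat(sprintf("generation time (h): mean %.3g, median %.3g; max generation %d\n",
              x$mean_generation_time_h, x$median_generation_time_h,
              x$max_generation))
  invisible(x)
}

#' Write simulator outputs as CSV
#'
#' Event-log and snapshot tables in the package's on-disk schema.
#'
#' @param sim A \code{hotspot_sim}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_sim_outputs <- function(sim, dir) {
  stopifnot(inherits(sim, "hotspot_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(sim$events, file.path(dir, "events.csv"), row.names = FALSE)
  fin <- sim$snapshots[[length(sim$snapshots)]]
  utils::write.csv(fin, file.path(dir, "snapshot_final.csv"), row.names = FALSE)
  utils::write.csv(sim$final_field, file.path(dir, "field_final.csv"),
                   row.names = FALSE)
  invisible(dir)
}
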