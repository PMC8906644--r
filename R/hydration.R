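#' Hydration parameters
#'
#' Bundle of the physical constants that translate a prescribed matric
#' potential into capillary water geometry: the matric potential itself
#' (\code{psi}, kPa, non-positive; more negative means drier soil), the
#' air--water surface tension and the solid--water contact angle.
#'
#' @param psi Matric potential in kPa, must be \code{<= 0}.
#' @param gamma Air--water surface tension in N/m (default 0.072).
#' @param contact_angle Contact angle in degrees (default 0, perfectly
#'   wetting walls; the corner-water closed form assumes this).
#' @return An object of class \code{hydration_params}.
#' @examples
#' hydration_params(-3)
#' @export
hydration_params <- function(psi, gamma = 0.072, contact_angle = 0) {
  stopifnot(is.numeric(psi), length(psi) == 1, psi <= 0,
            is.numeric(gamma), gamma > 0,
            contact_angle >= 0, contact_angle < 90)
  structure(list(psi = psi, gamma = gamma, contact_angle = contact_angle),
            class = "hydration_params")
}

#' @export
print.hydration_params <- function(x, ...) {
  cat(sprintf("Hydration: psi = %g kPa, gamma = %g N/m, contact angle = %g deg\n",
              x$psi, x$gamma, x$contact_angle))
  rc <- .curvature_radius_um(x$gamma, x$psi)
  cat(sprintf("  meniscus curvature radius r_c = %s um\n",
              if (is.finite(rc)) format(rc, digits = 4) else "Inf (saturated)"))
  invisible(x)
}

# lognormal parameters matching arithmetic mean m and arithmetic variance v
.lognormal_from_moments <- function(m, v) {
  sdlog2 <- log(1 + v / m^2)
  list(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Build a disk-shaped angular pore network
#'
#' Generates the simulation domain: a regular triangular lattice of pore
#' channels (edge length \code{segment_length_um}) clipped to a disk of radius
#' \code{disk_radius_mm}.  Each channel is an angular (triangular
#' cross-section) capillary whose central angle is drawn uniformly from
#' \code{angle_range_deg} and whose inscribed radius is drawn from a lognormal
#' distribution with the requested arithmetic mean and variance.  Structural
#' heterogeneity is imposed by \code{n_hetero_regions} randomly placed
#' circular regions inside which channel radii are rescaled by a common
#' region factor drawn uniformly from [0.5, 2].
#'
#' @param disk_radius_mm Domain radius in mm.
#' @param segment_length_um Channel segment length in um (default 100).
#' @param angle_range_deg Range of triangular central angles in degrees
#'   (default \code{c(30, 150)}).
#' @param radius_mean_um Arithmetic mean of inscribed pore radii (um,
#'   default 30).
#' @param radius_var_um2 Arithmetic variance of inscribed radii (um^2,
#'   default 10).
#' @param n_hetero_regions Number of heterogeneity regions (default 50 for
#'   the full domain; scale down with the domain).
#' @param hetero_radius_mm Radius of each heterogeneity region (default 0.5).
#' @param seed Integer seed; identical seeds give byte-identical networks.
#' @return A \code{pore_network}: list with \code{nodes} (data.frame: id,
#'   x_um, y_um, is_boundary), \code{channels} (data.frame: id, node_a,
#'   node_b, length_um, theta_deg, r_ins_um, region_id), \code{boundary_nodes},
#'   \code{center_node}, \code{disk_radius_um}, \code{segment_length_um},
#'   \code{rng_seed}.
#' @examples
#' net <- build_pore_network(0.5, seed = 1, n_hetero_regions = 3)
#' nrow(net$channels)
#' @export
build_pore_network <- function(disk_radius_mm,
                               segment_length_um = 100,
                               angle_range_deg = c(30, 150),
                               radius_mean_um = 30,
                               radius_var_um2 = 10,
                               n_hetero_regions = 50,
                               hetero_radius_mm = 0.5,
                               seed = 1L) {
  stopifnot(disk_radius_mm > 0, segment_length_um > 0, radius_var_um2 >= 0,
            length(angle_range_deg) == 2, all(angle_range_deg >= 30),
            all(angle_range_deg <= 150))
  R <- disk_radius_mm * 1000
  s <- segment_length_um
  if (s >= R)
    stop("degenerate geometry: segment length (", s,
         " um) must be smaller than the disk radius (", R, " um)")

  # triangular lattice: rows spaced s*sqrt(3)/2, odd rows offset by s/2
  rowh <- s * sqrt(3) / 2
  jmax <- ceiling(R / rowh) + 1
  imax <- ceiling(R / s) + 1
  grid <- expand.grid(i = -imax:imax, j = -jmax:jmax)
  x <- grid$i * s + ifelse(grid$j %% 2 != 0, s / 2, 0)
  y <- grid$j * rowh
  keep <- x^2 + y^2 <= R^2
  gi <- grid$i[keep]; gj <- grid$j[keep]
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  key <- paste(gi, gj)
  idx <- seq_len(n)
  names(idx) <- key

  # six-neighbour stencil; emit each undirected edge once
  nb_offsets <- function(j) {
    if (j %% 2 != 0)
      list(c(1, 0), c(0, 1), c(1, 1))   # right, up-left, up-right
    else
      list(c(1, 0), c(-1, 1), c(0, 1))
  }
  ea <- integer(0); eb <- integer(0)
  for (parity in 0:1) {
    sel <- which(gj %% 2 == parity)
    for (off in nb_offsets(parity)) {
      nk <- paste(gi[sel] + off[1], gj[sel] + off[2])
      hit <- idx[nk]
      ok <- !is.na(hit)
      ea <- c(ea, sel[ok]); eb <- c(eb, unname(hit[ok]))
    }
  }
  ne <- length(ea)
  if (ne == 0) stop("degenerate geometry: no channels inside the disk")

  set.seed(seed)
  theta <- stats::runif(ne, angle_range_deg[1], angle_range_deg[2])
  if (radius_var_um2 > 0) {
    lp <- .lognormal_from_moments(radius_mean_um, radius_var_um2)
    r_ins <- stats::rlnorm(ne, lp$meanlog, lp$sdlog)
  } else {
    r_ins <- rep(radius_mean_um, ne)
  }

  # heterogeneity regions: disk-shaped, uniform-random centers, radii scaled
  # by a region factor in [0.5, 2]; first matching region wins
  region_id <- rep(NA_integer_, ne)
  if (n_hetero_regions > 0) {
    rr <- R * sqrt(stats::runif(n_hetero_regions))
    aa <- stats::runif(n_hetero_regions, 0, 2 * pi)
    cx <- rr * cos(aa); cy <- rr * sin(aa)
    fac <- stats::runif(n_hetero_regions, 0.5, 2.0)
    hr <- hetero_radius_mm * 1000
    mx <- (x[ea] + x[eb]) / 2
    my <- (y[ea] + y[eb]) / 2
    for (k in seq_len(n_hetero_regions)) {
      inside <- is.na(region_id) & ((mx - cx[k])^2 + (my - cy[k])^2 <= hr^2)
      region_id[inside] <- k
      r_ins[inside] <- r_ins[inside] * fac[k]
    }
  }

  dist0 <- sqrt(x^2 + y^2)
  is_boundary <- dist0 > (R - 0.75 * s)
  if (!any(is_boundary)) stop("degenerate geometry: no boundary nodes")
  nodes <- data.frame(id = idx, x_um = x, y_um = y, is_boundary = is_boundary)
  channels <- data.frame(id = seq_len(ne), node_a = ea, node_b = eb,
                         length_um = s, theta_deg = theta, r_ins_um = r_ins,
                         region_id = region_id)

  net <- structure(list(nodes = nodes, channels = channels,
                        boundary_nodes = which(is_boundary),
                        center_node = which.min(dist0),
                        disk_radius_um = R, segment_length_um = s,
                        rng_seed = seed),
                   class = "pore_network")
  comp <- .connected_components(net)
  if (max(comp) > 1) {
    orphan <- which(comp != comp[net$center_node])
    stop("pore network is disconnected; orphan component of ",
         length(orphan), " nodes (first node id ", orphan[1], ")")
  }
  net
}

# BFS connected components over the channel list
.connected_components <- function(net) {
  n <- nrow(net$nodes)
  adj <- vector("list", n)
  ea <- net$channels$node_a; eb <- net$channels$node_b
  for (k in seq_along(ea)) {
    adj[[ea[k]]] <- c(adj[[ea[k]]], eb[k])
    adj[[eb[k]]] <- c(adj[[eb[k]]], ea[k])
  }
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' @export
print.pore_network <- function(x, ...) {
  cat(sprintf("Pore network: disk radius %g mm, %d nodes, %d channels (%g um segments)\n",
              x$disk_radius_um / 1000, nrow(x$nodes), nrow(x$channels),
              x$segment_length_um))
  cat(sprintf("  %d boundary nodes, center node %d, seed %d\n",
              length(x$boundary_nodes), x$center_node, x$rng_seed))
  invisible(x)
}

# total cross-sectional area of an isosceles triangular duct with apex angle
# theta (deg) and inscribed radius r: A = r^2 (cot(theta/2) + 2 cot((pi-theta)/4))
.triangle_area <- function(theta_deg, r_ins) {
  th <- theta_deg * pi / 180
  r_ins^2 * (1 / tan(th / 2) + 2 / tan((pi - th) / 4))
}

#' Corner water geometry of a pore channel
#'
#' For a prescribed matric potential, computes how much of an angular pore's
#' cross-section is water-filled and the effective thickness of the corner
#' water films.  At \code{psi = 0} (or whenever the Young--Laplace curvature
#' radius \eqn{r_c = \gamma/|\psi|} reaches the inscribed radius, the
#' capillary-entry condition) the channel is fully saturated.  Otherwise water
#' retreats to the two wall corners of half-angle \eqn{\phi = \theta/2}, each
#' holding the closed-form area \eqn{r_c^2(\cot\phi - (\pi/2 - \phi))}; the
#' film thickness is that area divided by the wetted perimeter.
#'
#' @param channel One row of a network's \code{channels} table (or any list
#'   with \code{theta_deg} and \code{r_ins_um}); vectorized over rows.
#' @param hydration A \code{\link{hydration_params}} object.
#' @return A data.frame with \code{film_thickness_um},
#'   \code{water_area_fraction}, \code{saturated}, \code{water_area_um2},
#'   \code{total_area_um2}.
#' @examples
#' net <- toy_pore_network(2, seed = 1)
#' corner_water_geometry(net$channels[1, ], hydration_params(-3))
#' @export
corner_water_geometry <- function(channel, hydration) {
  stopifnot(inherits(hydration, "hydration_params"))
  theta <- channel$theta_deg
  r_ins <- channel$r_ins_um
  A_tot <- .triangle_area(theta, r_ins)
  r_c <- .curvature_radius_um(hydration$gamma, hydration$psi)
  sat <- r_c >= r_ins
  phi <- (theta / 2) * pi / 180
  corner <- r_c^2 * (1 / tan(phi) - (pi / 2 - phi))
  A_w <- ifelse(sat, A_tot, pmin(2 * corner, A_tot))
  wetted_perim <- ifelse(sat,
                         2 * r_ins * (1 / tan(phi) + 2 / tan((pi - theta * pi / 180) / 4)),
                         4 * r_c / tan(phi))
  film <- ifelse(sat, r_ins, A_w / wetted_perim)
  data.frame(film_thickness_um = film,
             water_area_fraction = A_w / A_tot,
             saturated = sat,
             water_area_um2 = A_w,
             total_area_um2 = A_tot)
}

#' Effective channel diffusivities under partial saturation
#'
#' Bulk (total-cross-section-referenced) effective diffusivities of an
#' aqueous and a gaseous species in a partially saturated channel: the
#' aqueous pathway scales with the water area fraction, the gaseous pathway
#' with the air-filled remainder, so the two fractions partition exactly.
#'
#' @param channel Channel row(s), as in \code{\link{corner_water_geometry}}.
#' @param hydration A \code{\link{hydration_params}}.
#' @param D_aq0 Free aqueous diffusivity (um^2/s).
#' @param D_gas0 Free gaseous diffusivity (um^2/s).
#' @return data.frame with \code{D_aq_eff}, \code{D_gas_eff} (um^2/s).
#' @export
channel_diffusivities <- function(channel, hydration, D_aq0, D_gas0) {
  stopifnot(D_aq0 > 0, D_gas0 > 0)
  g <- corner_water_geometry(channel, hydration)
  data.frame(D_aq_eff = D_aq0 * g$water_area_fraction,
             D_gas_eff = D_gas0 * (1 - g$water_area_fraction))
}

#' Write / read a pore network as plain-text tables
#'
#' Two CSV files (\code{nodes.csv}, \code{channels.csv}) plus a JSON header
#' echoing geometry and seed, so a network can be regenerated or audited
#' outside R.
#'
#' @param net A \code{pore_network}.
#' @param dir Output directory (created if missing).
#' @return \code{write_pore_network} returns \code{dir} invisibly;
#'   \code{read_pore_network} returns the reconstructed \code{pore_network}.
#' @export
write_pore_network <- function(net, dir) {
  stopifnot(inherits(net, "pore_network"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(net$nodes, file.path(dir, "nodes.csv"), row.names = FALSE)
  utils::write.csv(net$channels, file.path(dir, "channels.csv"), row.names = FALSE)
  hdr <- list(disk_radius_um = net$disk_radius_um,
              segment_length_um = net$segment_length_um,
              center_node = net$center_node,
              rng_seed = net$rng_seed,
              n_nodes = nrow(net$nodes),
              n_channels = nrow(net$channels))
  jsonlite::write_json(hdr, file.path(dir, "network.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_pore_network
#' @export
read_pore_network <- function(dir) {
  nodes <- utils::read.csv(file.path(dir, "nodes.csv"))
  channels <- utils::read.csv(file.path(dir, "channels.csv"))
  hdr <- jsonlite::read_json(file.path(dir, "network.json"), simplifyVector = TRUE)
  structure(list(nodes = nodes, channels = channels,
                 boundary_nodes = which(nodes$is_boundary),
                 center_node = hdr$center_node,
                 disk_radius_um = hdr$disk_radius_um,
                 segment_length_um = hdr$segment_length_um,
                 rng_seed = hdr$rng_seed),
            class = "pore_network")
}

#' Small triangular-lattice disk for tests and examples
#'
#' A miniature domain: \code{n_rings} hexagonal rings of 100-um channels
#' around a center node, satisfying every pore-network invariant.
#'
#' @param n_rings Number of lattice rings (>= 1).
#' @param seed RNG seed for channel angles/radii.
#' @param ... Passed to \code{\link{build_pore_network}}.
#' @return A \code{pore_network}.
#' @export
toy_pore_network <- function(n_rings, seed = 1L, ...) {
  stopifnot(n_rings >= 1)
  # radius chosen so exactly n_rings rings of a 100-um lattice survive clipping
  build_pore_network(disk_radius_mm = (n_rings + 0.25) * 0.1,
                     segment_length_um = 100,
                     n_hetero_regions = 0, seed = seed, ...)
}
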