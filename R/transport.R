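#' Edge conductances for a diffusing species
#'
#' Converts per-channel effective diffusivities into diffusive conductances
#' \eqn{g = D_{eff} A_{tot} / L} (um^3/s), where \eqn{D_{eff}} is the bulk
#' effective diffusivity referenced to the full cross-section, so that
#' \eqn{g} equals free diffusivity times the phase cross-sectional area over
#' length.  For a species with both an aqueous and a gaseous pathway
#' (oxygen), the two act in parallel and the gas path carries a Henry-law
#' partitioning multiplier, so that a single aqueous-concentration field can
#' be solved: \eqn{g = (D_{aq,eff} + H D_{gas,eff}) A_{tot} / L}.
#'
#' @param network A \code{pore_network}.
#' @param hydration A \code{\link{hydration_params}}.
#' @param species List describing the species: \code{D_aq0} (um^2/s,
#'   required), \code{D_gas0} (um^2/s, default 0 = aqueous-only) and
#'   \code{henry} (dimensionless air/water multiplier on the gas path,
#'   default 1).
#' @return Numeric vector of conductances, one per channel (um^3/s).
#' @examples
#' net <- toy_pore_network(2, seed = 1)
#' g <- assemble_conductances(net, hydration_params(-3), list(D_aq0 = 600))
#' @export
assemble_conductances <- function(network, hydration, species) {
  stopifnot(inherits(network, "pore_network"), !is.null(species$D_aq0),
            species$D_aq0 > 0)
  D_gas0 <- if (is.null(species$D_gas0)) 0 else species$D_gas0
  H <- if (is.null(species$henry)) 1 else species$henry
  geom <- corner_water_geometry(network$channels, hydration)
  f <- geom$water_area_fraction
  D_eff <- species$D_aq0 * f + H * D_gas0 * (1 - f)
  D_eff * geom$total_area_um2 / network$channels$length_um
}

#' Quasi-steady diffusion operator on the pore graph
#'
#' Prefactorizes the free-node graph Laplacian for repeated quasi-steady
#' solves with changing sink fields (the conductances and Dirichlet sets are
#' fixed for a given hydration state, so the sparse Cholesky factor is
#' computed once).
#'
#' @param network A \code{pore_network}.
#' @param conductances Per-channel conductances from
#'   \code{\link{assemble_conductances}} (um^3/s).
#' @param fixed_nodes Integer node ids held at prescribed concentrations.
#' @param fixed_values Concentrations (mM) at \code{fixed_nodes}.
#' @return A \code{transport_operator}.
#' @export
transport_operator <- function(network, conductances, fixed_nodes, fixed_values) {
  stopifnot(length(fixed_nodes) >= 1,
            length(fixed_values) == length(fixed_nodes),
            length(conductances) == nrow(network$channels),
            all(conductances >= 0))
  n <- nrow(network$nodes)
  ea <- network$channels$node_a
  eb <- network$channels$node_b
  L <- Matrix::sparseMatrix(i = c(ea, eb, ea, eb), j = c(eb, ea, ea, eb),
                            x = c(-conductances, -conductances,
                                  conductances, conductances),
                            dims = c(n, n))
  free <- setdiff(seq_len(n), fixed_nodes)
  A <- L[free, free, drop = FALSE]
  # a free node (or component) with no path to any fixed node makes the
  # system singular; detect via zero diagonal or zero coupling row-sum
  coupling <- -L[free, fixed_nodes, drop = FALSE]
  diagA <- Matrix::diag(A)
  orphan <- which(diagA <= 0)
  if (length(orphan))
    stop("singular transport system: free node(s) ",
         paste(utils::head(free[orphan], 5), collapse = ", "),
         " have no conductive connection")
  fact <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(A), "CsparseMatrix"),
                           LDL = FALSE)
  structure(list(network = network, L = L, free = free,
                 fixed_nodes = fixed_nodes, fixed_values = fixed_values,
                 coupling = coupling, factor = fact, n = n,
                 b0 = as.numeric(coupling %*% fixed_values)),
            class = "transport_operator")
}

#' Solve the quasi-steady nutrient balance
#'
#' Solves \eqn{\sum_j g_{ij}(c_j - c_i) = q_i} at every free node, with
#' Dirichlet concentrations at the operator's fixed nodes.  Uptake sinks are
#' capped so that no nodal concentration is driven negative: if the solve
#' yields negative nodes, their sinks are halved and the system re-solved
#' (stored-factor backsolves, at most \code{max_cap_iter} rounds); any
#' residual negatives are clipped to zero.  The realized (possibly reduced)
#' sinks are returned so callers can scale cellular uptake accordingly.
#'
#' @param op A \code{\link{transport_operator}}.
#' @param sinks Per-node uptake rates (um^3 mM / s, >= 0); zero-filled if
#'   omitted.
#' @param max_cap_iter Maximum sink-capping rounds (default 8).
#' @param diagnostics If \code{TRUE} (default) also compute the boundary
#'   influx and the flux-conservation residual; the simulator's inner loop
#'   switches this off.
#' @return List with \code{concentration} (mM, length n), \code{sinks}
#'   (realized), \code{influx} (net boundary influx), \code{flux_residual}
#'   (relative imbalance |influx - uptake| / max(influx, tiny)).  The last
#'   two are \code{NA} when \code{diagnostics = FALSE}.
#' @examples
#' net <- toy_pore_network(2, seed = 1)
#' g <- assemble_conductances(net, hydration_params(0), list(D_aq0 = 600))
#' op <- transport_operator(net, g, net$boundary_nodes,
#'                          rep(0.27, length(net$boundary_nodes)))
#' sol <- solve_quasi_steady(op)
#' range(sol$concentration)  # uniform 0.27: no sinks, constant boundary
#' @export
solve_quasi_steady <- function(op, sinks = NULL, max_cap_iter = 8,
                               diagnostics = TRUE) {
  stopifnot(inherits(op, "transport_operator"))
  if (is.null(sinks)) sinks <- numeric(op$n)
  stopifnot(length(sinks) == op$n, all(sinks >= 0))
  s <- sinks[op$free]
  for (iter in seq_len(max_cap_iter)) {
    cf <- as.numeric(Matrix::solve(op$factor, op$b0 - s))
    neg <- cf < -1e-12
    if (!any(neg)) break
    s[neg] <- s[neg] * 0.5
  }
  cf[cf < 0] <- 0
  conc <- numeric(op$n)
  conc[op$free] <- cf
  conc[op$fixed_nodes] <- op$fixed_values
  realized <- numeric(op$n)
  realized[op$free] <- s
  if (diagnostics) {
    # net outflow from the fixed nodes into the network equals the domain
    # influx: sum_i sum_j g_ij (c_i - c_j) over fixed i
    influx <- sum((op$L %*% conc)[op$fixed_nodes])
    uptake <- sum(s)
    res <- abs(influx - uptake) / max(abs(influx), 1e-300)
  } else {
    influx <- NA_real_
    res <- NA_real_
  }
  list(concentration = conc, sinks = realized, influx = influx,
       flux_residual = res)
}
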