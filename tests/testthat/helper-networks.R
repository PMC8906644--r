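# Shared small fixtures, built in code at test time.

# a modest disk network reused across transport/agent tests
small_net <- function(seed = 5) toy_pore_network(4, seed = seed)

# hand-built 3-node chain with prescribed conductances, for closed-form
# Laplacian checks (bypasses build_pore_network on purpose)
chain_network <- function(n = 3) {
  nodes <- data.frame(id = seq_len(n), x_um = (seq_len(n) - 1) * 100,
                      y_um = 0, is_boundary = c(TRUE, rep(FALSE, n - 2), TRUE))
  channels <- data.frame(id = seq_len(n - 1), node_a = seq_len(n - 1),
                         node_b = seq_len(n - 1) + 1, length_um = 100,
                         theta_deg = 90, r_ins_um = 30,
                         region_id = NA_integer_)
  structure(list(nodes = nodes, channels = channels,
                 boundary_nodes = c(1L, n), center_node = (n + 1L) %/% 2L,
                 disk_radius_um = (n - 1) * 100, segment_length_um = 100,
                 rng_seed = 0L),
            class = "pore_network")
}

# 5-node star: center 1, leaves 2:5
star_network <- function() {
  nodes <- data.frame(id = 1:5,
                      x_um = c(0, 100, -100, 0, 0),
                      y_um = c(0, 0, 0, 100, -100),
                      is_boundary = c(FALSE, TRUE, TRUE, TRUE, TRUE))
  channels <- data.frame(id = 1:4, node_a = 1L, node_b = 2:5,
                         length_um = 100, theta_deg = 90, r_ins_um = 30,
                         region_id = NA_integer_)
  structure(list(nodes = nodes, channels = channels,
                 boundary_nodes = 2:5, center_node = 1L,
                 disk_radius_um = 100, segment_length_um = 100,
                 rng_seed = 0L),
            class = "pore_network")
}
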