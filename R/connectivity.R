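#' Periodic Gaussian kernel
#'
#' The connection-probability kernel of the network: a Gaussian wrapped on a
#' ring of circumference `m`, `sum_k exp(-(x - m*k)^2 / (2 sigma^2))` truncated
#' at `|k| <= k_max`. For `sigma <= 0.2 m` the truncation error at `k_max = 5`
#' is below `exp(-300)`.
#'
#' @param x Signed distance(s).
#' @param sigma Gaussian width (> 0), same units as `x`.
#' @param m Period.
#' @param k_max Truncation order (>= 1).
#' @return Kernel values, same shape as `x`.
#' @export
periodic_gaussian <- function(x, sigma, m = 1, k_max = 5L) {
  if (sigma <= 0) abort("sigma must be > 0")
  stopifnot(k_max >= 1)
  out <- 0
  for (k in -k_max:k_max) {
    out <- out + exp(-(x - m * k)^2 / (2 * sigma^2))
  }
  out
}

# internal: sample one block (post population A <- pre population B) of the
# adjacency. Probabilities p = K * G(dx) G(dy) [* PO modulation] normalized so
# that sum_j p = K for every postsynaptic neuron before clamping; exploits the
# grid layout via lookup tables over the distinct coordinate values.
sample_block <- function(post, pre, k, sigma, m, k_max,
                         eps = 0, po_post = NULL, po_pre = NULL,
                         exclude_self = FALSE, chunk = 512L) {
  n_a <- nrow(post); n_b <- nrow(pre)
  r_a <- as.integer(round(sqrt(n_a))); r_b <- as.integer(round(sqrt(n_b)))
  ix_a <- as.integer(round(post$x * r_a / m)); iy_a <- as.integer(round(post$y * r_a / m))
  ix_b <- as.integer(round(pre$x * r_b / m));  iy_b <- as.integer(round(pre$y * r_b / m))
  ux_a <- (0:(r_a - 1)) * m / r_a; ux_b <- (0:(r_b - 1)) * m / r_b
  gx <- outer(ux_a, ux_b, function(a, b) periodic_gaussian(a - b, sigma, m, k_max))
  gy <- gx  # square patch: same lookup for both axes
  # per-post normalization sum (separable over x and y on the product grid);
  # for same-population blocks the excluded self-pair is removed from the sum
  # so the expected in-degree over allowed pairs is exactly k
  sx <- rowSums(gx); sy <- rowSums(gy)
  s_post <- sx[ix_a + 1L] * sy[iy_a + 1L]
  if (exclude_self) s_post <- s_post - periodic_gaussian(0, sigma, m, k_max)^2
  n_clamped <- 0L; p_max <- 0
  post_idx <- integer(0); pre_idx <- integer(0)
  for (start in seq(1L, n_a, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n_a)
    p <- (k / s_post[rows]) *
      gx[ix_a[rows] + 1L, ix_b + 1L, drop = FALSE] *
      gy[iy_a[rows] + 1L, iy_b + 1L, drop = FALSE]
    if (eps != 0) {
      dpo <- outer(po_post[rows], po_pre, "-") * pi / 180
      p <- p * (1 + eps * cos(2 * dpo))
    }
    if (exclude_self) {
      self <- rows[rows <= n_b]
      if (length(self) > 0) p[cbind(match(self, rows), self)] <- 0
    }
    over <- p > 1
    if (any(over)) {
      n_clamped <- n_clamped + sum(over)
      p_max <- max(p_max, max(p))
      p[over] <- 1
    }
    hit <- which(matrix(runif(length(p)), nrow(p)) < p)
    if (length(hit) > 0) {
      post_idx <- c(post_idx, rows[(hit - 1L) %% nrow(p) + 1L])
      pre_idx <- c(pre_idx, (hit - 1L) %/% nrow(p) + 1L)
    }
  }
  list(post = post_idx, pre = pre_idx, n_clamped = n_clamped, p_max = p_max)
}

# internal: shared sampler behind sample_connectivity() and reconnect_graph()
sample_graph <- function(geom, k, sigma, m, k_max, eps_ce, eps_ci, po_deg, seed) {
  n_e <- attr(geom, "n_e"); n_i <- attr(geom, "n_i")
  if (k >= min(n_e, n_i)) abort("mean in-degree k must be smaller than every population size")
  if (!is.null(seed)) set.seed(seed)
  pops <- list(E = filter(geom, .data$population == "E"),
               I = filter(geom, .data$population == "I"))
  po <- if (is.null(po_deg)) NULL else
    list(E = po_deg[seq_len(n_e)], I = po_deg[n_e + seq_len(n_i)])
  blocks <- list()
  n_clamped <- 0L; p_max <- 0
  for (a in c("E", "I")) for (b in c("E", "I")) {
    eps_b <- if (b == "E") eps_ce else eps_ci
    bl <- sample_block(pops[[a]], pops[[b]], k, sigma, m, k_max,
                       eps = eps_b,
                       po_post = if (is.null(po)) NULL else po[[a]],
                       po_pre = if (is.null(po)) NULL else po[[b]],
                       exclude_self = a == b)
    blocks[[paste0(a, b)]] <- tibble(
      post_pop = a, post = bl$post, pre_pop = b, pre = bl$pre, w = 1
    )
    n_clamped <- n_clamped + bl$n_clamped
    p_max <- max(p_max, bl$p_max)
  }
  if (n_clamped > 0) {
    warn(sprintf("%d connection probabilities exceeded 1 (max %.3f) and were clamped",
                 n_clamped, p_max))
  }
  edges <- bind_rows(blocks)
  structure(edges,
            geometry = geom, m = m, k = k, sigma = sigma, k_max = k_max,
            n_e = n_e, n_i = n_i, n_clamped = n_clamped,
            eps_ce = eps_ce, eps_ci = eps_ci, seed = seed,
            class = c("connectivity_graph", class(tibble())))
}

#' Sample the recurrent connectivity
#'
#' Draws each ordered neuron pair independently as Bernoulli with probability
#' proportional to the product of periodic Gaussians of the coordinate
#' differences, normalized so the expected in-degree from each presynaptic
#' population equals `k` for every postsynaptic neuron. Self-connections are
#' excluded; probabilities above 1 (possible for very small `sigma`) are
#' clamped with a warning and counted. All synaptic efficacies start at
#' `w = 1`.
#'
#' @param geom A `layer_geometry` (or `orientation_layout`) tibble.
#' @param k Target mean in-degree per presynaptic population (< each
#'   population size).
#' @param sigma Gaussian footprint as a fraction of the patch size `m`.
#' @param seed Integer seed; the same seed reproduces the same graph.
#' @param k_max Truncation order of the periodic Gaussian.
#' @return An edge tibble of class `connectivity_graph` with columns
#'   `post_pop`, `post`, `pre_pop`, `pre`, `w`, and attributes (`geometry`,
#'   `k`, `sigma`, `n_clamped`, ...).
#' @export
sample_connectivity <- function(geom, k = 500, sigma = 0.2, seed = NULL, k_max = 5L) {
  m <- attr(geom, "m")
  sample_graph(geom, k, sigma * m, m, k_max, eps_ce = 0, eps_ci = 0,
               po_deg = NULL, seed = seed)
}

#' Reconnect the network according to preferred orientations
#'
#' Resamples the whole connectivity from the distance-dependent probability
#' multiplied by `1 + eps_cB * cos(2 * (PO_pre - PO_post))`, where `eps_cB`
#' depends only on the presynaptic population (`eps_ce` for excitatory
#' presynaptic neurons, `eps_ci` for inhibitory ones). With `eps > 0`, neurons
#' with similar preferred orientations become more likely to be connected;
#' the expected in-degree is preserved when preferred orientations are
#' uniformly distributed. Weights are reset to 1.
#'
#' @param graph A `connectivity_graph` from [sample_connectivity()].
#' @param po_deg Preferred orientations in degrees: either a numeric vector in
#'   layout row order (E neurons then I neurons) or a tibble with columns
#'   `population`, `neuron`, `po_deg` (e.g. from [compute_tuning()]).
#' @param eps_ce,eps_ci Reconnection modulations in \[0, 1\].
#' @param seed Integer seed.
#' @return A fresh `connectivity_graph`.
#' @export
reconnect_graph <- function(graph, po_deg, eps_ce = 0.44, eps_ci = 0.11, seed = NULL) {
  stopifnot(eps_ce >= 0, eps_ce <= 1, eps_ci >= 0, eps_ci <= 1)
  geom <- attr(graph, "geometry")
  if (is.data.frame(po_deg)) {
    po_deg <- left_join(as_tibble(geom)[, c("population", "neuron")],
                        po_deg[, c("population", "neuron", "po_deg")],
                        by = c("population", "neuron"))$po_deg
  }
  if (length(po_deg) != nrow(geom) || anyNA(po_deg)) {
    abort("a preferred orientation is required for every neuron")
  }
  sample_graph(geom, attr(graph, "k"), attr(graph, "sigma"), attr(graph, "m"),
               attr(graph, "k_max"), eps_ce = eps_ce, eps_ci = eps_ci,
               po_deg = po_deg, seed = seed)
}

#' Realized in-degree summary per block
#'
#' @param graph A `connectivity_graph`.
#' @return Tibble with `post_pop`, `pre_pop`, `mean_in_degree`, `n_edges`.
#' @export
in_degree <- function(graph) {
  n_post <- c(E = attr(graph, "n_e"), I = attr(graph, "n_i"))
  graph %>%
    group_by(.data$post_pop, .data$pre_pop) %>%
    summarise(n_edges = dplyr::n(), .groups = "drop") %>%
    mutate(mean_in_degree = .data$n_edges / n_post[.data$post_pop])
}

# internal: edge list -> CSR over global presynaptic index (0-based) for the
# compiled simulator. Global index: E neurons 0..n_e-1, I neurons n_e..n-1.
as_csr <- function(graph) {
  n_e <- attr(graph, "n_e"); n_i <- attr(graph, "n_i")
  n <- n_e + n_i
  gpre <- graph$pre - 1L + ifelse(graph$pre_pop == "I", n_e, 0L)
  gpost <- graph$post - 1L + ifelse(graph$post_pop == "I", n_e, 0L)
  ord <- order(gpre)
  gpre <- gpre[ord]; gpost <- gpost[ord]; w <- graph$w[ord]
  counts <- tabulate(gpre + 1L, nbins = n)
  ptr <- c(0L, cumsum(counts))
  list(ptr = as.integer(ptr), post = as.integer(gpost), w = as.numeric(w),
       order = ord, n_e = n_e, n_i = n_i)
}

# internal: write CSR-modified weights back into the edge tibble
set_weights <- function(graph, csr, w_new) {
  graph$w[csr$order] <- w_new
  graph
}
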