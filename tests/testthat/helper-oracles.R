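# Independent oracles used across the suite. None of these share code with
# the implementation paths they check.

# Edmonds-Karp max flow (BFS augmenting paths) on an undirected graph given
# as an edge matrix with per-edge capacities. Each undirected edge becomes
# two directed arcs whose residuals interact in the usual way.
oracle_max_flow <- function(edges, caps, s, t, n_vertices) {
  m <- nrow(edges)
  from <- c(edges[, 1], edges[, 2])
  to <- c(edges[, 2], edges[, 1])
  cap <- c(caps, caps)
  rev_ix <- c(seq_len(m) + m, seq_len(m))
  adj <- vector("list", n_vertices)
  for (i in seq_along(from)) adj[[from[i]]] <- c(adj[[from[i]]], i)
  flow <- numeric(2L * m)
  total <- 0
  repeat {
    par_arc <- integer(n_vertices)
    visited <- logical(n_vertices)
    visited[s] <- TRUE
    queue <- s
    while (length(queue) && !visited[t]) {
      v <- queue[1]
      queue <- queue[-1]
      for (a in adj[[v]]) {
        w <- to[a]
        if (!visited[w] && cap[a] - flow[a] > 1e-9) {
          visited[w] <- TRUE
          par_arc[w] <- a
          queue <- c(queue, w)
        }
      }
    }
    if (!visited[t]) break
    path <- integer(0)
    v <- t
    while (v != s) {
      a <- par_arc[v]
      path <- c(path, a)
      v <- from[a]
    }
    bottleneck <- min(cap[path] - flow[path])
    flow[path] <- flow[path] + bottleneck
    flow[rev_ix[path]] <- flow[rev_ix[path]] - bottleneck
    total <- total + bottleneck
  }
  total
}

# 4-connectivity pixel-graph edge list of a logical mask, built by direct
# neighbour enumeration (vertex ids = position in `which(mask)`).
oracle_pixel_edges <- function(mask) {
  nr <- nrow(mask)
  pix <- which(mask)
  pos <- integer(length(mask))
  pos[pix] <- seq_along(pix)
  edges <- NULL
  for (p in pix) {
    r <- (p - 1L) %% nr + 1L
    if (r < nr && pos[p + 1L] > 0L) edges <- rbind(edges, c(pos[p], pos[p + 1L]))
    if (p + nr <= length(mask) && pos[p + nr] > 0L)
      edges <- rbind(edges, c(pos[p], pos[p + nr]))
  }
  list(edges = edges, pix = pix)
}

# Min cut between two pixel-core terminal sets of a mask, via the
# Edmonds-Karp oracle with contracted super terminals.
oracle_min_cut_between_cores <- function(mask, core_a_pix, core_b_pix) {
  pg <- oracle_pixel_edges(mask)
  pos <- integer(length(mask))
  pos[pg$pix] <- seq_along(pg$pix)
  n <- length(pg$pix)
  s <- n + 1L
  t <- n + 2L
  big <- nrow(pg$edges) + 1
  edges <- rbind(pg$edges,
                 cbind(s, pos[core_a_pix]),
                 cbind(t, pos[core_b_pix]))
  caps <- c(rep(1, nrow(pg$edges)),
            rep(big, length(core_a_pix) + length(core_b_pix)))
  oracle_max_flow(edges, caps, s, t, n + 2L)
}

# Exhaustive likelihood of a small untagged pool: enumerate every
# prediction outcome for a fixed assignment of true classes (x of Nh are
# EC; by exchangeability any subset gives the same value, so average over
# all of them), accumulating the probability of observing ch HSR
# predictions.
oracle_enumerated_likelihood <- function(x, Nh, ch, ph, qh) {
  subsets <- if (x == 0L) list(integer(0))
             else utils::combn(Nh, x, simplify = FALSE)
  total <- 0
  for (ec in subsets) {
    p_hsr <- ifelse(seq_len(Nh) %in% ec, ph, qh)
    for (outcome in 0:(2^Nh - 1L)) {
      pred_hsr <- as.logical(bitwAnd(outcome, 2^(seq_len(Nh) - 1L)))
      if (sum(pred_hsr) != ch) next
      total <- total + prod(ifelse(pred_hsr, p_hsr, 1 - p_hsr))
    }
  }
  total / length(subsets)
}

# Random two-lobe mask: two ellipses joined by a thin rectangular neck,
# plus three small context disks so the fused component passes the
# median-area gate. Returns the mask and the planted neck width.
make_two_lobe_mask <- function(seed) {
  set.seed(seed)
  nr <- 110L
  nc <- 150L
  m <- matrix(0, nr, nc)
  r1 <- sample(13:17, 1)
  r2 <- sample(13:17, 1)
  cy <- sample(32:44, 1)
  gap <- sample(8:20, 1)
  c1 <- c(cy, 35)
  c2 <- c(cy, 35 + r1 + gap + r2)
  m[interfish::ellipse_mask(nr, nc, c1[1], c1[2], r1, r1)] <- 1
  m[interfish::ellipse_mask(nr, nc, c2[1], c2[2], r2, r2)] <- 1
  neck_w <- sample(2:5, 1)
  half <- neck_w %/% 2L
  rows <- (c1[1] - half):(c1[1] - half + neck_w - 1L)
  m[rows, c1[2]:c2[2]] <- 1
  for (ctr in list(c(85, 30), c(85, 75), c(85, 120)))
    m[interfish::ellipse_mask(nr, nc, ctr[1], ctr[2], 13, 13)] <- 1
  list(mask = m, neck_width = neck_w)
}

# A small raw synthetic patch wrapper used by classifier tests: EC-amp and
# no-amp patches are separable by their target-channel content.
make_toy_patch_set <- function(n_per_class, seed, size = 64L) {
  cfg <- interfish::sim_config(noise_sd = 2, spot_sigma_px = 1.2,
                               ec_foci_mean = 12)
  patches <- list()
  labels <- character(0)
  for (i in seq_len(n_per_class)) {
    for (cl in c("EC-amp", "no-amp")) {
      g <- interfish::generate_nucleus_patch(cl, cfg, seed = seed + 37L * i +
                                               (cl == "EC-amp"), size = size)
      patches[[length(patches) + 1L]] <- g$patch
      labels <- c(labels, cl)
    }
  }
  list(patches = patches, labels = labels)
}
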