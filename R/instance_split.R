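# Separation of touching nuclei: L1 distance transform, local-maximum
# centre detection, and min-cut splitting on the 4-connectivity pixel graph.

#' Parameters for min-cut instance splitting
#'
#' @param center_min_distance a pixel is a candidate nucleus centre only if
#'   its L1 distance to background exceeds this value (pixels).
#' @param area_factor only connected components larger than
#'   `area_factor x median component area` are considered for splitting.
#' @param flow_limit a component is split only when the min cut between two
#'   centres removes at most this many pixel-graph edges.
#' @return a `split_params` list.
#' @export
split_params <- function(center_min_distance = 10, area_factor = 1.25,
                         flow_limit = 60L) {
  stopifnot(center_min_distance > 0, area_factor > 0, flow_limit > 0)
  structure(list(center_min_distance = center_min_distance,
                 area_factor = area_factor,
                 flow_limit = as.integer(flow_limit)),
            class = "split_params")
}

#' L1 (Manhattan) distance transform of a binary mask
#'
#' Each foreground pixel receives its Manhattan distance to the nearest
#' background pixel; background pixels hold 0. The image border counts as
#' background, so a mask that is foreground everywhere still yields finite
#' distances.
#'
#' @param mask logical or 0/1 matrix.
#' @return integer matrix of distances.
#' @export
l1_distance_transform <- function(mask) {
  mask <- as.matrix(mask) > 0
  # pad a one-pixel background ring so the border acts as background
  padded <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  padded[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  d <- as.matrix(EBImage::distmap(padded, metric = "manhattan"))
  out <- d[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L), drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

#' Find nucleus centre candidates on a distance map
#'
#' Centres are local maxima of the distance map over the 8-neighbourhood
#' (plateau-tolerant: a connected plateau of equal maximal values collapses
#' to its lexicographically smallest pixel) whose distance value exceeds
#' `center_min_distance`.
#'
#' @param distmap integer matrix from [l1_distance_transform()].
#' @param params a [split_params()].
#' @return matrix with columns `row`, `col`, `value`, one row per centre,
#'   ordered by decreasing distance value.
#' @export
find_instance_centers <- function(distmap, params = split_params()) {
  d <- as.matrix(distmap)
  nr <- nrow(d); nc <- ncol(d)
  # pad with -Inf so border pixels compare only against real neighbours
  p <- matrix(-Inf, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- d
  nbr_max <- matrix(-Inf, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nbr_max <- pmax(nbr_max, p[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc])
  }
  empty <- matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("row", "col", "value")))
  cand <- d > params$center_min_distance
  if (!any(cand)) return(empty)
  # a connected plateau of equal value is a maximum only when no pixel of
  # the plateau has a strictly greater neighbour; it collapses to its
  # lexicographically smallest pixel
  centers <- NULL
  for (v in sort(unique(d[cand]), decreasing = TRUE)) {
    lab <- label_components(cand & d == v, connectivity = 8L)
    for (k in seq_len(max(lab))) {
      on <- lab == k
      if (max(nbr_max[on]) <= v) {
        px <- which(on, arr.ind = TRUE)
        px <- px[order(px[, 1], px[, 2]), , drop = FALSE]
        centers <- rbind(centers, c(px[1, 1], px[1, 2], v))
      }
    }
  }
  if (is.null(centers)) return(empty)
  colnames(centers) <- c("row", "col", "value")
  centers[order(-centers[, "value"], centers[, "row"], centers[, "col"]),
          , drop = FALSE]
}

# Build the 4-connectivity pixel graph of a set of foreground pixel indices
# (linear indices into an nr x nc grid). Returns an igraph with vertex
# attribute `pix` = linear pixel index.
pixel_graph_4 <- function(pix, nr, nc) {
  pos <- integer(nr * nc)
  pos[pix] <- seq_along(pix)
  r <- (pix - 1L) %% nr + 1L
  cl <- (pix - 1L) %/% nr + 1L
  edges <- integer(0)
  # right neighbour (same row, col+1) and down neighbour (row+1, same col)
  right <- ifelse(cl < nc, pix + nr, NA_integer_)
  down <- ifelse(r < nr, pix + 1L, NA_integer_)
  for (nb in list(right, down)) {
    ok <- !is.na(nb)
    ok[ok] <- pos[nb[ok]] > 0L
    if (any(ok)) edges <- c(edges, rbind(pos[pix[ok]], pos[nb[ok]]))
  }
  g <- igraph::make_empty_graph(n = length(pix), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::set_vertex_attr(g, "pix", value = pix)
}

#' Split touching nuclei by minimum cut on the pixel graph
#'
#' Connected components of the binary mask (4-connectivity) whose area
#' exceeds `area_factor x median component area` and which contain at least
#' two centre candidates are considered for splitting. For each such
#' component the minimum number of pixel-graph edges separating the two
#' strongest centres is computed on the unit-capacity 4-connectivity pixel
#' graph; each centre's terminal is its core region (the 4-connected
#' component of pixels deeper than `center_min_distance` in the distance
#' map), so the cut runs through the neck between the nuclei. Centres
#' sharing one core are not separable and their component stays whole. If
#' the cut size is at most `flow_limit`, the cut edges are removed and the
#' sides become distinct instances; sides still holding two or more centres
#' are split again. Cuts remove adjacencies, never pixels, so the
#' foreground pixel set is preserved exactly.
#'
#' @param mask binary matrix (any labeling is flattened to foreground).
#' @param params a [split_params()].
#' @return a `nucleus_mask` with one label per instance. The cut sizes used
#'   are recorded in attribute `"cut_sizes"`.
#' @export
split_overlapping_nuclei <- function(mask, params = split_params()) {
  binary <- as.matrix(mask) > 0
  nr <- nrow(binary); nc <- ncol(binary)
  comp <- as.matrix(EBImage::bwlabel(binary))  # 4-connectivity
  ncomp <- max(comp)
  if (ncomp == 0L) return(nucleus_mask(matrix(0L, nr, nc)))
  areas <- tabulate(comp[comp > 0], nbins = ncomp)
  gate <- params$area_factor * stats::median(areas)
  dmap <- l1_distance_transform(binary)
  out <- matrix(0L, nr, nc)
  next_label <- 1L
  cut_sizes <- integer(0)

  split_once <- function(pix) {
    # pix: linear indices of one connected piece; returns NULL when the
    # piece stays whole, else a list of the pieces after one cut. The two
    # strongest centres lying in distinct core regions (4-connected
    # components of pixels deeper than center_min_distance) are the
    # terminals; each core is contracted through a high-capacity super
    # vertex so the cut severs the neck between nuclei rather than the
    # 4 edges around a single centre pixel.
    if (length(pix) <= gate) return(NULL)
    sub <- matrix(FALSE, nr, nc); sub[pix] <- TRUE
    sub_d <- ifelse(sub, dmap, 0L)
    centers <- find_instance_centers(sub_d, params)
    if (nrow(centers) < 2L) return(NULL)
    cores <- label_components(sub_d > params$center_min_distance,
                              connectivity = 4L)
    ctr_core <- cores[cbind(centers[, "row"], centers[, "col"])]
    b <- which(ctr_core != ctr_core[1L])[1L]
    if (is.na(b)) return(NULL)  # all centres share one core: not separable
    g <- pixel_graph_4(pix, nr, nc)
    ne_real <- igraph::ecount(g)
    big <- ne_real + 1
    pixpos <- integer(nr * nc); pixpos[pix] <- seq_along(pix)
    core_a <- pixpos[which(cores == ctr_core[1L])]
    core_b <- pixpos[which(cores == ctr_core[b])]
    s <- length(pix) + 1L; t <- length(pix) + 2L
    g <- igraph::add_vertices(g, 2L)
    g <- igraph::add_edges(g, c(rbind(s, core_a), rbind(t, core_b)))
    caps <- c(rep(1, ne_real), rep(big, length(core_a) + length(core_b)))
    mf <- igraph::max_flow(g, source = s, target = t, capacity = caps)
    if (mf$value > params$flow_limit) return(NULL)
    cut_sizes <<- c(cut_sizes, mf$value)
    g2 <- igraph::delete_edges(g, mf$cut)
    g2 <- igraph::delete_vertices(g2, c(s, t))
    memb <- igraph::components(g2)$membership
    unname(split(igraph::vertex_attr(g2, "pix"), memb))
  }

  for (k in seq_len(ncomp)) {
    queue <- list(which(comp == k))
    while (length(queue)) {
      pix <- queue[[1]]; queue <- queue[-1]
      pieces <- split_once(pix)
      if (is.null(pieces)) {
        out[pix] <- next_label
        next_label <- next_label + 1L
      } else {
        queue <- c(pieces, queue)
      }
    }
  }
  res <- nucleus_mask(out)
  attr(res, "cut_sizes") <- cut_sizes
  res
}
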