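# Deterministic FISH foci detection by projection onto an orthogonalized
# Gaussian kernel, plus per-nucleus copy-number and co-occurrence statistics.
#
# The detector models an isolated FISH amplification as an isotropic 2-D
# Gaussian of standard deviation sigma riding on a locally constant
# background: intensity(x, y) ~ c * g(x, y) + d. Projecting each pixel
# neighbourhood v onto the unit vector g_perp (the Gaussian kernel
# orthogonalized against the constant vector) yields the peak coefficient c,
# which is zero for any locally constant region regardless of brightness.

#' Parameters for stat-FISH foci detection
#'
#' @param sigma Gaussian standard deviation of the spot model, pixels.
#' @param kernel_size odd side length n of the square neighbourhood; default
#'   `ceiling(6 * sigma)` rounded up to the next odd integer, covering
#'   +/- 3 sigma.
#' @param c_min threshold on the projection coefficient `v . g_perp`. The
#'   default 15 corresponds to three times the response standard deviation
#'   under the default background noise (SD 5 on the 8-bit scale; the
#'   response to i.i.d. noise has the same SD because `g_perp` has unit
#'   norm). Use [calibrate_c_min()] to recompute it for other backgrounds.
#' @param b_min minimum raw brightness of a focus pixel. Interpreted on the
#'   same scale as the channel passed to [detect_foci()]: 0-255 for raw
#'   channels, 0-1 for rescaled patches (divide by 255).
#' @param s_min minimum pixel area of a connected focus component.
#' @return a `statfish_params` list.
#' @export
statfish_params <- function(sigma = 1.5, kernel_size = NULL, c_min = 15,
                            b_min = 50, s_min = 2L) {
  stopifnot(sigma > 0, s_min >= 1)
  if (is.null(kernel_size)) {
    kernel_size <- ceiling(6 * sigma)
    if (kernel_size %% 2L == 0L) kernel_size <- kernel_size + 1L
  }
  if (kernel_size %% 2L != 1L || kernel_size < 3L)
    stop("kernel_size must be an odd integer >= 3")
  structure(list(sigma = sigma, kernel_size = as.integer(kernel_size),
                 c_min = c_min, b_min = b_min, s_min = as.integer(s_min)),
            class = "statfish_params")
}

#' Build the orthogonalized Gaussian kernel
#'
#' Gram-Schmidt orthogonalization of the Gaussian kernel g against the
#' constant vector: `g_perp = (g - mean(g) 1) / ||g - mean(g) 1||`. By
#' construction `g_perp . 1 = 0` and `||g_perp|| = 1`, so the filter
#' response to any locally constant neighbourhood is exactly zero.
#'
#' @param params a [statfish_params()].
#' @return list with `g` and `g_perp` (n x n matrices).
#' @export
build_orthogonal_kernel <- function(params = statfish_params()) {
  n <- params$kernel_size
  ctr <- (n + 1) / 2
  g <- outer(seq_len(n) - ctr, seq_len(n) - ctr,
             function(i, j) exp(-(i^2 + j^2) / (2 * params$sigma^2)))
  centered <- g - mean(g)
  nrm <- sqrt(sum(centered^2))
  if (nrm < 1e-8)
    stop("degenerate kernel: sigma too large for the window, g is constant")
  list(g = g, g_perp = centered / nrm)
}

#' Label connected components of a binary matrix
#'
#' @param binary logical matrix.
#' @param connectivity 4 or 8.
#' @return integer label matrix (0 background).
#' @export
label_components <- function(binary, connectivity = 8L) {
  binary <- as.matrix(binary) > 0
  if (connectivity == 4L)
    return(as.matrix(EBImage::bwlabel(binary)))
  nr <- nrow(binary); nc <- ncol(binary)
  pix <- which(binary)
  out <- matrix(0L, nr, nc)
  if (!length(pix)) return(out)
  pos <- integer(nr * nc); pos[pix] <- seq_along(pix)
  r <- (pix - 1L) %% nr + 1L
  cl <- (pix - 1L) %/% nr + 1L
  edges <- integer(0)
  # right, down, down-right, up-right neighbours cover all 8-adjacencies
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))
  for (o in offs) {
    nr2 <- r + o[1]; nc2 <- cl + o[2]
    ok <- nr2 >= 1L & nr2 <= nr & nc2 >= 1L & nc2 <= nc
    nb <- (nc2 - 1L) * nr + nr2
    ok[ok] <- pos[nb[ok]] > 0L
    if (any(ok)) edges <- c(edges, rbind(pos[pix[ok]], pos[nb[ok]]))
  }
  g <- igraph::make_empty_graph(n = length(pix), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  out[pix] <- igraph::components(g)$membership
  out
}

#' Detect FISH foci in one channel of a segmented nucleus
#'
#' Convolves the channel with `g_perp` (zero-padded, same-size response),
#' keeps pixels inside the nucleus whose response reaches `c_min` and whose
#' raw brightness reaches `b_min`, and groups them into 8-connected
#' components; components of at least `s_min` pixels are the reported foci.
#' Pixels within half a kernel width of the image border are excluded from
#' candidacy, where zero padding would bias the response.
#'
#' @param channel intensity matrix (8-bit scale, or unit scale with a
#'   matching `b_min`).
#' @param nucleus_mask logical matrix of the nucleus pixels.
#' @param params a [statfish_params()].
#' @return a `foci_set`: list with `labels` (component label matrix), `foci`
#'   (data frame: `label`, `row`, `col` centroids, `area`), `n_foci`,
#'   `copy_number_signal` (percent of nucleus area covered by foci), and
#'   `nucleus_area`.
#' @export
detect_foci <- function(channel, nucleus_mask, params = statfish_params()) {
  channel <- as.matrix(channel)
  nucleus_mask <- as.matrix(nucleus_mask) > 0
  if (!all(dim(channel) == dim(nucleus_mask)))
    stop("channel and mask extents differ")
  if (!any(nucleus_mask)) stop("empty nucleus mask")
  kern <- build_orthogonal_kernel(params)
  resp <- as.matrix(EBImage::filter2(channel, kern$g_perp, boundary = 0))
  half <- params$kernel_size %/% 2L
  nr <- nrow(channel); nc <- ncol(channel)
  interior <- matrix(FALSE, nr, nc)
  if (nr > 2 * half && nc > 2 * half)
    interior[(half + 1L):(nr - half), (half + 1L):(nc - half)] <- TRUE
  cand <- nucleus_mask & interior & resp >= params$c_min &
    channel >= params$b_min
  lab <- label_components(cand, connectivity = 8L)
  keep <- which(tabulate(lab[lab > 0]) >= params$s_min)
  relab <- integer(max(lab, 1L)); relab[keep] <- seq_along(keep)
  lab[lab > 0] <- relab[lab[lab > 0]]
  foci <- if (length(keep)) {
    do.call(rbind, lapply(seq_along(keep), function(k) {
      px <- which(lab == k, arr.ind = TRUE)
      data.frame(label = k, row = mean(px[, 1]), col = mean(px[, 2]),
                 area = nrow(px))
    }))
  } else data.frame(label = integer(0), row = numeric(0), col = numeric(0),
                    area = integer(0))
  fs <- structure(list(labels = lab, foci = foci, n_foci = nrow(foci),
                       nucleus_area = sum(nucleus_mask)),
                  class = "foci_set")
  fs$copy_number_signal <- copy_number_signal(fs, nucleus_mask)
  fs
}

#' @export
print.foci_set <- function(x, ...) {
  cat(sprintf("<foci_set> %d foci, copy-number signal %.2f%%\n",
              x$n_foci, x$copy_number_signal))
  invisible(x)
}

#' Copy-number signal of a nucleus
#'
#' Percentage of the nucleus pixel area covered by detected foci pixels.
#'
#' @param foci a `foci_set` computed on this nucleus.
#' @param nucleus_mask logical matrix of the nucleus pixels.
#' @return percentage in \[0, 100\].
#' @export
copy_number_signal <- function(foci, nucleus_mask) {
  area <- sum(as.matrix(nucleus_mask) > 0)
  if (area == 0) stop("zero-area nucleus mask")
  100 * sum(foci$foci$area) / area
}

#' Image-level summary of per-nucleus copy-number signal
#'
#' @param foci_sets list of `foci_set`, one per nucleus of an image.
#' @return list with `mean` and `variance` (population variance, i.e.
#'   divisor n) of the copy-number signal, and `per_nucleus` (data frame:
#'   `nucleus`, `n_foci`, `copy_number_signal`).
#' @export
image_statistics <- function(foci_sets) {
  stopifnot(length(foci_sets) >= 1)
  cns <- vapply(foci_sets, function(f) f$copy_number_signal, numeric(1))
  nf <- vapply(foci_sets, function(f) f$n_foci, numeric(1))
  m <- mean(cns)
  list(mean = m, variance = mean((cns - m)^2),
       per_nucleus = data.frame(nucleus = seq_along(foci_sets), n_foci = nf,
                                copy_number_signal = cns))
}

#' Co-occurrence of foci between two probe channels
#'
#' Two foci co-occur when their pixel components overlap in at least one
#' pixel. Counts partition by overlap status: `n_cooccurring` is the number
#' of channel-A foci that overlap any channel-B focus; `n_a_only` and
#' `n_b_only` count foci without any overlap (a B focus overlapping several
#' A foci is counted once, by leaving `n_b_only`).
#'
#' @param foci_a,foci_b `foci_set`s over the same nucleus grid.
#' @return named integer vector `(n_a_only, n_b_only, n_cooccurring)`.
#' @export
foci_cooccurrence <- function(foci_a, foci_b) {
  if (!all(dim(foci_a$labels) == dim(foci_b$labels)))
    stop("foci sets computed on different grids")
  both <- foci_a$labels > 0 & foci_b$labels > 0
  a_hit <- unique(foci_a$labels[both])
  b_hit <- unique(foci_b$labels[both])
  c(n_a_only = foci_a$n_foci - length(a_hit),
    n_b_only = foci_b$n_foci - length(b_hit),
    n_cooccurring = length(a_hit))
}

#' Calibrate the projection threshold on background-only patches
#'
#' Generates pure-noise patches at the stated background level, measures the
#' SD of the `g_perp` filter response, and returns `k` times that SD.
#'
#' @param params a [statfish_params()] (for the kernel).
#' @param noise_sd background noise SD on the channel's intensity scale.
#' @param k multiple of the response SD (default 3).
#' @param n_patches,size number and side of calibration patches.
#' @param seed RNG seed.
#' @return suggested `c_min`.
#' @export
calibrate_c_min <- function(params = statfish_params(), noise_sd = 5, k = 3,
                            n_patches = 10L, size = 64L, seed = 1L) {
  set.seed(seed)
  kern <- build_orthogonal_kernel(params)
  half <- params$kernel_size %/% 2L
  vals <- unlist(lapply(seq_len(n_patches), function(i) {
    m <- matrix(abs(stats::rnorm(size * size, 0, noise_sd)), size, size)
    r <- as.matrix(EBImage::filter2(m, kern$g_perp, boundary = 0))
    r[(half + 1):(size - half), (half + 1):(size - half)]
  }))
  k * stats::sd(vals)
}
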