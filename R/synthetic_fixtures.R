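# Seeded generator of synthetic interphase FISH images with known ground
# truth: class labels, planted foci coordinates and tagging status. Every
# downstream module is testable against these fixtures without external data.

AMP_CLASSES <- c("EC-amp", "HSR-amp", "no-amp")

#' Simulation configuration for synthetic FISH fixtures
#'
#' Defaults emulate the three interphase amplification phenotypes: EC-amp
#' nuclei carry many small bright puncta (Poisson-distributed count), HSR-amp
#' nuclei one or two large contiguous bright regions, no-amp nuclei the 2-4
#' puncta expected from a normal diploid/tetraploid locus. Each nucleus also
#' carries two centromeric puncta, and EC-amp nuclei are RFP-tagged with a
#' fixed Bernoulli probability (emulating a ~95%-pure tagged line).
#'
#' @param seed integer RNG seed.
#' @param n_nuclei number of nuclei in a field image.
#' @param class_mixture named proportions over `EC-amp`, `HSR-amp`, `no-amp`;
#'   must sum to 1.
#' @param ec_foci_mean Poisson mean of puncta per EC-amp nucleus.
#' @param hsr_blob_count integer range (2-vector) of blobs per HSR-amp nucleus.
#' @param noamp_foci_range integer range of puncta per no-amp nucleus.
#' @param spot_sigma_px Gaussian standard deviation of a punctum, pixels.
#' @param spot_amplitude peak intensity of a punctum, 8-bit scale.
#' @param noise_sd additive Gaussian background noise SD, 8-bit scale.
#' @param rfp_tag_probability_ec probability an EC-amp nucleus is RFP-tagged.
#' @param nucleus_radius_px integer range of nucleus semi-axes for field
#'   images, pixels.
#' @param min_separation_px minimum distance between planted puncta centres;
#'   defaults to `4 * spot_sigma_px + 1` so neighbouring puncta stay
#'   resolvable.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_nuclei = 50L,
                       class_mixture = c("EC-amp" = 1/3, "HSR-amp" = 1/3,
                                         "no-amp" = 1/3),
                       ec_foci_mean = 30, hsr_blob_count = c(1L, 2L),
                       noamp_foci_range = c(2L, 4L), spot_sigma_px = 1.5,
                       spot_amplitude = 200, noise_sd = 5,
                       rfp_tag_probability_ec = 0.95,
                       nucleus_radius_px = c(24L, 40L),
                       min_separation_px = NULL) {
  stopifnot(abs(sum(class_mixture) - 1) < 1e-9,
            all(names(class_mixture) %in% AMP_CLASSES),
            ec_foci_mean >= 0, all(hsr_blob_count >= 0),
            all(noamp_foci_range >= 0), spot_sigma_px > 0)
  if (is.null(min_separation_px)) min_separation_px <- 4 * spot_sigma_px + 1
  structure(list(seed = as.integer(seed), n_nuclei = as.integer(n_nuclei),
                 class_mixture = class_mixture, ec_foci_mean = ec_foci_mean,
                 hsr_blob_count = as.integer(hsr_blob_count),
                 noamp_foci_range = as.integer(noamp_foci_range),
                 spot_sigma_px = spot_sigma_px,
                 spot_amplitude = spot_amplitude, noise_sd = noise_sd,
                 rfp_tag_probability_ec = rfp_tag_probability_ec,
                 nucleus_radius_px = as.integer(nucleus_radius_px),
                 min_separation_px = min_separation_px),
            class = "sim_config")
}

#' Filled ellipse indicator matrix
#'
#' @param nr,nc grid extent.
#' @param cr,cc centre (row, col).
#' @param a,b semi-axes in pixels.
#' @param theta rotation in radians.
#' @return logical matrix, TRUE inside the ellipse.
#' @export
ellipse_mask <- function(nr, nc, cr, cc, a, b, theta = 0) {
  r <- matrix(seq_len(nr), nr, nc) - cr
  cl <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cc
  u <- cos(theta) * r + sin(theta) * cl
  v <- -sin(theta) * r + cos(theta) * cl
  (u / a)^2 + (v / b)^2 <= 1
}

# Add an isotropic Gaussian punctum in place (over a local window only).
add_spot <- function(img, cr, cc, amplitude, sigma) {
  w <- ceiling(4 * sigma)
  rr <- max(1, cr - w):min(nrow(img), cr + w)
  cc2 <- max(1, cc - w):min(ncol(img), cc + w)
  g <- outer(rr - cr, cc2 - cc, function(i, j) exp(-(i^2 + j^2) / (2 * sigma^2)))
  img[rr, cc2] <- img[rr, cc2] + amplitude * g
  img
}

# Sample k points inside `allowed` (logical matrix) with pairwise minimum
# separation; simple rejection sampling with a retry budget.
sample_separated <- function(k, allowed, min_sep,
                             max_tries = 600L * max(k, 1L), warn = TRUE) {
  idx <- which(allowed, arr.ind = TRUE)
  if (!nrow(idx)) stop("no admissible pixels for spot placement")
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pts) < k && tries < max_tries) {
    cand <- idx[sample.int(nrow(idx), 1L), ]
    if (!nrow(pts) ||
        min(sqrt(rowSums((pts - matrix(cand, nrow(pts), 2, byrow = TRUE))^2))) >
          min_sep)
      pts <- rbind(pts, cand)
    tries <- tries + 1L
  }
  if (warn && nrow(pts) < k)
    warning(sprintf("placed only %d of %d spots at separation %.1f",
                    nrow(pts), k, min_sep))
  pts
}

#' Generate one synthetic nucleus patch with ground truth
#'
#' Produces a raw 8-bit patch (default 256 x 256) containing one elliptical
#' DAPI nucleus with smooth texture, a target-probe channel whose content
#' depends on the amplification class, a centromeric channel with two
#' puncta, and an RFP channel that is bright iff the nucleus is tagged.
#'
#' @param class_label one of `"EC-amp"`, `"HSR-amp"`, `"no-amp"`.
#' @param config a [sim_config()].
#' @param seed RNG seed for this nucleus (defaults to `config$seed`).
#' @param size patch side in pixels.
#' @return list with `patch` (a raw `nucleus_patch`) and `truth` (class
#'   label, planted foci centres/amplitudes, tagged flag, instance mask).
#' @export
generate_nucleus_patch <- function(class_label, config = sim_config(),
                                   seed = config$seed, size = 256L) {
  class_label <- match.arg(class_label, AMP_CLASSES)
  set.seed(seed)
  n <- size
  # nucleus: ellipse with semi-axes 28-42% of the patch side
  a <- round(stats::runif(1, 0.28, 0.42) * n)
  b <- round(stats::runif(1, 0.7, 1.0) * a)
  if (min(a, b) < 4) stop("degenerate nucleus radius (< 4 px)")
  theta <- stats::runif(1, 0, pi)
  cr <- n / 2 + stats::runif(1, -0.03, 0.03) * n
  cc <- n / 2 + stats::runif(1, -0.03, 0.03) * n
  nuc <- ellipse_mask(n, n, cr, cc, a, b, theta)

  # DAPI: filled ellipse, smooth low-frequency texture, additive noise
  texture <- as.matrix(EBImage::gblur(matrix(stats::rnorm(n * n), n, n),
                                      sigma = 8))
  dapi <- matrix(0, n, n)
  dapi[nuc] <- 120 + 25 * texture[nuc]
  dapi <- dapi + stats::rnorm(n * n, 0, config$noise_sd)

  sig <- config$spot_sigma_px
  margin <- ceiling(2 * sig) + 1
  interior <- nuc & ellipse_mask(n, n, cr, cc, a - margin, b - margin, theta)

  target <- matrix(0, n, n)
  foci_centers <- matrix(numeric(0), 0, 2)
  amplitudes <- numeric(0)
  requested <- 0L
  if (class_label == "EC-amp") {
    # small nuclei can saturate at the packing limit of the separation
    # constraint; the truth records both requested and placed counts
    requested <- stats::rpois(1, config$ec_foci_mean)
    if (requested > 0) {
      foci_centers <- sample_separated(requested, interior,
                                       config$min_separation_px, warn = FALSE)
      amplitudes <- rep(config$spot_amplitude, nrow(foci_centers))
    }
  } else if (class_label == "no-amp") {
    requested <- sample(config$noamp_foci_range[1]:config$noamp_foci_range[2],
                        1L)
    foci_centers <- sample_separated(requested, interior,
                                     config$min_separation_px, warn = FALSE)
    amplitudes <- rep(config$spot_amplitude, nrow(foci_centers))
  } else { # HSR-amp: 1-2 contiguous bright regions, each 5-15% of the nucleus
    nb <- sample(config$hsr_blob_count[1]:config$hsr_blob_count[2], 1L)
    nuc_area <- sum(nuc)
    for (i in seq_len(nb)) {
      frac <- stats::runif(1, 0.05, 0.15)
      ba <- sqrt(frac * nuc_area / pi)  # circle-equivalent radius
      ctr <- sample_separated(1, interior, 0)
      bm <- ellipse_mask(n, n, ctr[1], ctr[2], ba * stats::runif(1, 0.9, 1.3),
                         ba * stats::runif(1, 0.7, 1.0),
                         stats::runif(1, 0, pi)) & nuc
      target[bm] <- pmax(target[bm], 0.9 * config$spot_amplitude)
      foci_centers <- rbind(foci_centers, ctr)
      amplitudes <- c(amplitudes, 0.9 * config$spot_amplitude)
    }
  }
  if (class_label != "HSR-amp" && nrow(foci_centers))
    for (i in seq_len(nrow(foci_centers)))
      target <- add_spot(target, foci_centers[i, 1], foci_centers[i, 2],
                         amplitudes[i], sig)
  if (config$noise_sd > 0)
    target <- target + abs(stats::rnorm(n * n, 0, config$noise_sd))

  cen <- matrix(0, n, n)
  cen_pts <- sample_separated(2L, interior, config$min_separation_px)
  for (i in seq_len(nrow(cen_pts)))
    cen <- add_spot(cen, cen_pts[i, 1], cen_pts[i, 2],
                    config$spot_amplitude, sig)

  tagged <- class_label == "EC-amp" &&
    stats::runif(1) < config$rfp_tag_probability_ec
  rfp <- matrix(0, n, n)
  if (tagged) rfp[nuc] <- stats::runif(1, 80, 160) + 10 * texture[nuc]
  rfp <- rfp + abs(stats::rnorm(n * n, 0, min(config$noise_sd, 2)))

  arr <- array(0, c(n, n, 4L))
  arr[, , 1] <- dapi; arr[, , 2] <- target; arr[, , 3] <- cen; arr[, , 4] <- rfp
  arr <- round(pmin(pmax(arr, 0), 255))
  dimnames(arr) <- list(NULL, NULL, CHANNEL_NAMES)
  patch <- structure(list(pixels = arr, nucleus = nuc, label = 1L,
                          bbox = c(0L, 0L, n, n), window_index = 0L,
                          boundary = FALSE, source_image_id = "synthetic",
                          channels = CHANNEL_NAMES, rescaled = FALSE,
                          flags = character(0)), class = "nucleus_patch")
  truth <- list(class = class_label, foci_centers = foci_centers,
                requested_foci = requested, amplitudes = amplitudes,
                tagged = tagged, mask = nuc)
  list(patch = patch, truth = truth)
}

#' Generate a synthetic field image with many nuclei
#'
#' Places `config$n_nuclei` nuclei on a jittered grid (one nucleus per
#' randomly assigned cell), drawing each class from `config$class_mixture`.
#' With `overlap = FALSE` nuclei keep a margin from each other and the mask
#' carries one label per nucleus; with `overlap = TRUE` every even-indexed
#' nucleus is placed against its predecessor so fused components exercise
#' instance splitting (the returned mask labels are still the planted
#' instances).
#'
#' @param config a [sim_config()].
#' @param overlap allow nuclei to touch/overlap.
#' @return list with `image` (an `mc_image`), `mask` (planted
#'   `nucleus_mask`, one label per nucleus), and `truth` (list of per-nucleus
#'   ground-truth records, index k for label k).
#' @export
generate_field_image <- function(config = sim_config(), overlap = FALSE) {
  stopifnot(config$n_nuclei >= 1)
  set.seed(config$seed)
  rmax <- max(config$nucleus_radius_px)
  # nuclei sit on a jittered grid: one per cell, so any count places
  cell <- 2L * rmax + 10L
  gdim <- ceiling(sqrt(config$n_nuclei))
  side <- gdim * cell + 2L * rmax
  canvas <- array(0, c(side, side, 4L))
  mask <- matrix(0L, side, side)
  truth <- vector("list", config$n_nuclei)
  mix <- config$class_mixture[AMP_CLASSES]
  mix[is.na(mix)] <- 0
  classes <- sample(AMP_CLASSES, config$n_nuclei, replace = TRUE, prob = mix)
  cells <- sample.int(gdim^2, config$n_nuclei)   # random cell assignment
  centers <- matrix(numeric(0), 0, 2)
  nucleus_seeds <- sample.int(.Machine$integer.max, config$n_nuclei)
  for (k in seq_len(config$n_nuclei)) {
    if (overlap && k %% 2L == 0L) {
      # collide with the previous nucleus: offset by about one radius
      ang <- stats::runif(1, 0, 2 * pi)
      ctr <- centers[k - 1L, ] + 1.1 * rmax * c(cos(ang), sin(ang))
      ctr <- pmin(pmax(ctr, rmax + 4), side - rmax - 4)
    } else {
      gi <- (cells[k] - 1L) %/% gdim
      gj <- (cells[k] - 1L) %% gdim
      jitter_amp <- max(cell / 2 - rmax - 2, 0)
      ctr <- c(rmax + gi * cell + cell / 2,
               rmax + gj * cell + cell / 2) +
        stats::runif(2, -jitter_amp, jitter_amp)
    }
    centers <- rbind(centers, ctr)
    # render the nucleus on a local patch sized to the radius range
    psz <- 2L * (rmax + ceiling(0.1 * rmax)) + 9L
    sub <- generate_nucleus_patch(classes[k], config, seed = nucleus_seeds[k],
                                  size = psz)
    # rescale the generic patch ellipse to the configured radius range:
    # generate_nucleus_patch draws semi-axes as a fraction of `size`, and
    # psz was chosen so those fall inside nucleus_radius_px bounds.
    rr0 <- round(ctr[1]) - (psz %/% 2L); cc0 <- round(ctr[2]) - (psz %/% 2L)
    rr <- (rr0 + 1):(rr0 + psz); cc <- (cc0 + 1):(cc0 + psz)
    keep <- rr >= 1 & rr <= side; keepc <- cc >= 1 & cc <= side
    sm <- sub$truth$mask
    canvas[rr[keep], cc[keepc], ] <-
      pmax(canvas[rr[keep], cc[keepc], , drop = FALSE],
           sub$patch$pixels[keep, keepc, , drop = FALSE])
    mk <- mask[rr[keep], cc[keepc]]
    mk[sm[keep, keepc]] <- k
    mask[rr[keep], cc[keepc]] <- mk
    ct <- sub$truth
    ct$center <- round(ctr)
    ct$foci_centers <- if (nrow(ct$foci_centers))
      ct$foci_centers + matrix(c(rr0, cc0), nrow(ct$foci_centers), 2,
                               byrow = TRUE) else ct$foci_centers
    ct$mask <- NULL
    truth[[k]] <- ct

  }
  list(image = mc_image(canvas, CHANNEL_NAMES), mask = nucleus_mask(mask),
       truth = truth)
}

#' Simulate a tagging experiment at the count level
#'
#' Draws the category counts of an RFP-tagging experiment under the
#' binomial-mixture model used by the tagging estimator: tagged nuclei are
#' all truly EC-amp; untagged nuclei are a mix of `true_untagged` EC-amp
#' nuclei that escaped tagging and truly HSR-amp nuclei. Each nucleus is
#' predicted HSR-amp with its class-conditional probability (`ph` for true
#' EC-amp, `qh` for true HSR-amp).
#'
#' @param n total nuclei.
#' @param true_untagged number of true EC-amp nuclei that are not tagged.
#' @param n_true_ec total number of true EC-amp nuclei (tagged + untagged).
#' @param ph,pe prediction probabilities given true EC-amp (`ph + pe = 1`).
#' @param qh,qe prediction probabilities given true HSR-amp (`qh + qe = 1`).
#' @param seed RNG seed.
#' @return a [tagging_experiment()] plus the observed 4-category counts in
#'   attribute `"observed"` (tagged/untagged x HSR/EC prediction).
#' @export
simulate_tagging_experiment <- function(n = 500L, true_untagged = 15L,
                                        n_true_ec = round(n / 2),
                                        ph = 0.2642, pe = 0.7358,
                                        qh = 0.9763, qe = 0.0237, seed = 1L) {
  stopifnot(true_untagged <= n_true_ec, n_true_ec <= n)
  set.seed(seed)
  Ne <- n_true_ec - true_untagged          # tagged (all true EC)
  n_hsr <- n - n_true_ec                   # untagged true HSR
  Nh <- true_untagged + n_hsr
  ch_ec <- stats::rbinom(1, true_untagged, ph)
  ch_hsr <- stats::rbinom(1, n_hsr, qh)
  ch <- ch_ec + ch_hsr
  ce <- Nh - ch
  tag_h <- stats::rbinom(1, Ne, ph)        # tagged nuclei predicted HSR
  exp_ <- tagging_experiment(Ne = Ne, ch = ch, ce = ce,
                             ph = ph, pe = pe, qh = qh, qe = qe)
  attr(exp_, "observed") <- c(tagged_hsr = tag_h, tagged_ec = Ne - tag_h,
                              untagged_hsr = ch, untagged_ec = ce)
  attr(exp_, "true_untagged") <- true_untagged
  exp_
}
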