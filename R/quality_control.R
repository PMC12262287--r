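# Image- and nucleus-level quality gates deciding whether the target
# pipeline and/or the centromeric branch may run.

#' Histogram-based target-probe quality score
#'
#' Bins the target FISH channel into 50 equal-width intensity buckets over
#' \[0, 256) and locates the highest histogram peak on each side of bin 25
#' (0-based: bins 0-24 versus 25-49). A peak is a bin whose count exceeds
#' both neighbours; a plateau of equal counts is counted once, at its left
#' edge; the first and last bins compare against their single neighbour.
#' The quality score is `Q = h1 / h2`, the left (background) peak height
#' over the right (signal) peak height; images with `Q < 0.2` are low
#' quality — heavy probe bleeding pushes background mass rightward and
#' shrinks h1 relative to h2.
#'
#' @param target_channel intensity matrix on the 0-255 scale.
#' @return list with `q_score` (NA when a side has no peak), `h1`, `h2`,
#'   `target_pass`, and `reason` (non-empty when undefined).
#' @export
target_quality_score <- function(target_channel) {
  v <- as.vector(as.matrix(target_channel))
  if (!length(v)) stop("empty image")
  bins <- pmin(floor(v / 5.12), 49)   # 50 bins over [0, 256)
  counts <- tabulate(bins + 1L, nbins = 50L)
  # run-length encode so plateaus count once, at their left edge
  rl <- rle(counts)
  nruns <- length(rl$values)
  starts <- cumsum(c(1L, rl$lengths[-nruns]))
  is_peak <- vapply(seq_len(nruns), function(i) {
    left_ok <- i == 1L || rl$values[i] > rl$values[i - 1L]
    right_ok <- i == nruns || rl$values[i] > rl$values[i + 1L]
    left_ok && right_ok
  }, logical(1))
  peak_bins <- starts[is_peak] - 1L          # 0-based bin of each peak
  peak_heights <- rl$values[is_peak]
  left <- peak_heights[peak_bins <= 24L]
  right <- peak_heights[peak_bins >= 25L]
  if (!length(left) || !length(right)) {
    side <- if (!length(left)) "left" else "right"
    return(list(q_score = NA_real_, h1 = if (length(left)) max(left) else NA,
                h2 = if (length(right)) max(right) else NA,
                target_pass = FALSE,
                reason = paste0("no ", side, "-side histogram peak")))
  }
  h1 <- max(left); h2 <- max(right)
  q <- h1 / h2
  list(q_score = q, h1 = h1, h2 = h2, target_pass = q >= 0.2, reason = "")
}

#' Per-nucleus target-signal gate
#'
#' Keeps a nucleus only if the mean rescaled target signal over its pixels
#' is at least 0.05; nuclei below that carry too little oncogenic FISH
#' signal to classify.
#'
#' @param patch a rescaled `nucleus_patch`.
#' @return TRUE to keep the nucleus.
#' @export
nucleus_signal_gate <- function(patch) {
  stopifnot(inherits(patch, "nucleus_patch"), patch$rescaled)
  tgt <- patch$pixels[, , match("target", patch$channels)]
  mean(tgt[patch$nucleus]) >= 0.05
}

#' Pearson kurtosis (m4 / m2^2, normal reference value 3)
#' @param x numeric vector.
#' @return kurtosis, or NA when the variance is zero.
#' @export
pearson_kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^4) / m2^2
}

#' Image-level centromeric-probe gate
#'
#' Computes the Pearson kurtosis of the per-nucleus mean centromeric
#' intensities. A kurtosis above 3 (the normal reference) marks a
#' heavy-tailed, unreliable centromeric stain; the centromeric branch is
#' then disabled for the image and classification falls back to the
#' target-only model.
#'
#' @param nucleus_mean_intensities numeric vector, one mean per nucleus
#'   (at least 4 nuclei).
#' @return list with `kurtosis` (NA when degenerate) and `centromere_pass`.
#' @export
centromere_image_gate <- function(nucleus_mean_intensities) {
  if (length(nucleus_mean_intensities) < 4L)
    stop("kurtosis gate needs at least 4 nuclei")
  k <- pearson_kurtosis(nucleus_mean_intensities)
  list(kurtosis = k, centromere_pass = !is.na(k) && k <= 3,
       reason = if (is.na(k)) "zero variance across nuclei" else "")
}

#' Per-nucleus centromeric-signal gate
#'
#' The centromeric branch is allowed for a nucleus only when its maximum
#' raw centromeric intensity reaches 10 on the 0-255 scale; below that the
#' nucleus defaults to the target-only prediction.
#'
#' @param centromere_channel raw 8-bit matrix over the nucleus.
#' @return TRUE when the centromeric branch may run.
#' @export
centromere_nucleus_gate <- function(centromere_channel) {
  max(as.matrix(centromere_channel)) >= 10
}

#' Full quality report for one image
#'
#' @param image an `mc_image` with at least a `target` channel.
#' @param mask a `nucleus_mask`.
#' @return list with the target Q-score fields and, when a centromeric
#'   channel is present and at least 4 nuclei exist, the kurtosis gate.
#' @export
quality_report <- function(image, mask) {
  rep_ <- target_quality_score(get_channel(image, "target"))
  ids <- setdiff(sort(unique(as.vector(mask))), 0L)
  if ("centromere" %in% image$channels && length(ids) >= 4L) {
    cen <- get_channel(image, "centromere")
    means <- vapply(ids, function(k) mean(cen[mask == k]), numeric(1))
    g <- centromere_image_gate(means)
    rep_$centromere_kurtosis <- g$kurtosis
    rep_$centromere_pass <- g$centromere_pass
    rep_$centromere_reason <- g$reason
  }
  rep_
}
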