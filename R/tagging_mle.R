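# Maximum-likelihood estimation of fluorescent-tagging accuracy in a mixed
# EC-amp / HSR-amp population.
#
# Setup: two isogenic lines, one truly EC-amplified and nuclear-RFP tagged,
# one truly HSR-amplified and untagged, are mixed and imaged. Tagging is
# imperfect, so some true EC-amp nuclei appear untagged. Among the Nh
# untagged nuclei, x are true EC-amp; each true EC-amp nucleus is predicted
# HSR-amp with probability ph (EC-amp with pe = 1 - ph) and each true
# HSR-amp nucleus is predicted HSR-amp with probability qh (EC-amp with
# qe = 1 - qh), the class-conditional prediction probabilities measured on
# the pure lines. Conditional on x, the probability of observing ch
# HSR-predicted untagged nuclei (out of ch + ce = Nh) is
#
#   P(ch | x) = sum_{ah=0}^{x} C(x, ah) C(Nh - x, ch - ah)
#               ph^ah pe^(x - ah) qh^(ch - ah) qe^(ce + ah - x)
#
# where ah counts the true EC-amp untagged nuclei predicted HSR-amp. Under
# a uniform prior on 0 <= x <= Nh the MLE of x is the integer argmax.

#' Construct a tagging experiment
#'
#' @param Ne number of tagged nuclei.
#' @param ch,ce untagged nuclei predicted HSR-amp / EC-amp.
#' @param ph,pe prediction probabilities (HSR, EC) given true EC-amp;
#'   must sum to 1.
#' @param qh,qe prediction probabilities (HSR, EC) given true HSR-amp;
#'   must sum to 1.
#' @param Nh number of untagged nuclei; derived as `ch + ce` when omitted,
#'   validated against it otherwise.
#' @param tag_threshold raw 0-255 intensity above which a nucleus counts as
#'   tagged (strictly greater; default 10).
#' @return a `tagging_experiment` list.
#' @export
tagging_experiment <- function(Ne, ch, ce, ph, pe, qh, qe, Nh = NULL,
                               tag_threshold = 10) {
  if (is.null(Nh)) Nh <- ch + ce
  stopifnot(Nh == ch + ce, all(c(Ne, ch, ce) >= 0),
            abs(ph + pe - 1) < 1e-9, abs(qh + qe - 1) < 1e-9,
            all(c(ph, pe, qh, qe) >= 0))
  structure(list(Nh = as.integer(Nh), Ne = as.integer(Ne),
                 ch = as.integer(ch), ce = as.integer(ce),
                 ph = ph, pe = pe, qh = qh, qe = qe,
                 tag_threshold = tag_threshold),
            class = "tagging_experiment")
}

#' @export
print.tagging_experiment <- function(x, ...) {
  cat(sprintf(paste0("<tagging_experiment> Nh=%d (ch=%d, ce=%d), Ne=%d, ",
                     "p=(%.4f, %.4f), q=(%.4f, %.4f)\n"),
              x$Nh, x$ch, x$ce, x$Ne, x$ph, x$pe, x$qh, x$qe))
  invisible(x)
}

#' Classify a nucleus by its RFP channel
#'
#' @param rfp_channel raw 8-bit intensities over the nucleus pixels.
#' @param boundary_flag TRUE when the nucleus touches the image border;
#'   such nuclei are excluded because their maximum may be clipped.
#' @param threshold tagged iff the maximum intensity strictly exceeds this.
#' @return `"excluded"`, `"tagged"` or `"untagged"`.
#' @export
tag_nucleus <- function(rfp_channel, boundary_flag = FALSE, threshold = 10) {
  if (boundary_flag) return("excluded")
  if (max(as.numeric(rfp_channel)) > threshold) "tagged" else "untagged"
}

# xlog: 0 * log(0) = 0, so zero-probability events with zero exponent
# contribute a factor of 1. Vectorized over k.
xlog <- function(k, p) {
  out <- k * log(p)
  out[k == 0] <- 0
  out
}

#' Log-likelihood of x untagged true EC-amp nuclei
#'
#' Evaluates the combinatorial sum over `ah` (true EC-amp untagged nuclei
#' predicted HSR-amp) in log space with log-gamma binomials; terms whose
#' combinatorial arguments are invalid (`ch - ah < 0`,
#' `ch - ah > Nh - x`, `ce + ah - x < 0`) vanish.
#'
#' @param x hypothesized count of untagged true EC-amp nuclei, in
#'   `[0, Nh]`.
#' @param exp_ a [tagging_experiment()].
#' @return log-likelihood (`-Inf` when no term is admissible).
#' @export
tagging_log_likelihood <- function(x, exp_) {
  stopifnot(inherits(exp_, "tagging_experiment"))
  if (x < 0 || x > exp_$Nh) stop("x must lie in [0, Nh]")
  ah <- 0:x
  valid <- exp_$ch - ah >= 0 & exp_$ch - ah <= exp_$Nh - x &
    exp_$ce + ah - x >= 0
  ah <- ah[valid]
  if (!length(ah)) return(-Inf)
  terms <- lchoose(x, ah) + lchoose(exp_$Nh - x, exp_$ch - ah) +
    xlog(ah, exp_$ph) + xlog(x - ah, exp_$pe) +
    xlog(exp_$ch - ah, exp_$qh) + xlog(exp_$ce + ah - x, exp_$qe)
  terms <- terms[is.finite(terms)]
  if (!length(terms)) return(-Inf)
  m <- max(terms)
  m + log(sum(exp(terms - m)))
}

#' Maximum-likelihood estimate of the untagged true EC-amp count
#'
#' Integer argmax of [tagging_log_likelihood()] over `0 <= x <= Nh` under a
#' uniform prior; ties resolve to the smallest x.
#'
#' @param exp_ a [tagging_experiment()].
#' @return integer `x_hat`.
#' @export
estimate_untagged_count <- function(exp_) {
  ll <- vapply(0:exp_$Nh, tagging_log_likelihood, numeric(1), exp_ = exp_)
  as.integer(which.max(ll) - 1L)  # which.max returns the first maximum
}

#' Tagging accuracy from the estimated untagged count
#'
#' @param x_hat estimate from [estimate_untagged_count()].
#' @param exp_ a [tagging_experiment()].
#' @return list with `untagged_fraction` and `tagging_accuracy`, as
#'   percentages rounded to 2 decimals.
#' @export
tagging_accuracy <- function(x_hat, exp_) {
  if (exp_$Ne + x_hat == 0) stop("no true EC-amp nuclei (Ne + x_hat = 0)")
  uf <- 100 * x_hat / (exp_$Ne + x_hat)
  list(untagged_fraction = round(uf, 2), tagging_accuracy = round(100 - uf, 2))
}

#' Chi-square goodness-of-fit of the tagging model
#'
#' Expected counts for the 4 categories (tag status x predicted class) are
#' built from `x_hat`: all `Ne` tagged nuclei are true EC-amp (predicted
#' HSR with probability `ph`); the untagged pool holds `x_hat` true EC-amp
#' and `Nh - x_hat` true HSR-amp nuclei. The Pearson statistic over the 4
#' categories is referred to a chi-square distribution with 3 degrees of
#' freedom.
#'
#' @param x_hat estimate from [estimate_untagged_count()].
#' @param exp_ a [tagging_experiment()].
#' @param observed named counts
#'   `(tagged_hsr, tagged_ec, untagged_hsr, untagged_ec)`, summing to
#'   `Nh + Ne`.
#' @return list with `statistic`, `df = 3`, `p_value`, `expected`.
#' @export
tagging_fit_check <- function(x_hat, exp_, observed) {
  need <- c("tagged_hsr", "tagged_ec", "untagged_hsr", "untagged_ec")
  stopifnot(all(need %in% names(observed)))
  observed <- observed[need]
  if (sum(observed) != exp_$Nh + exp_$Ne)
    stop("observed counts must total Nh + Ne")
  expected <- c(
    tagged_hsr = exp_$Ne * exp_$ph,
    tagged_ec = exp_$Ne * exp_$pe,
    untagged_hsr = x_hat * exp_$ph + (exp_$Nh - x_hat) * exp_$qh,
    untagged_ec = x_hat * exp_$pe + (exp_$Nh - x_hat) * exp_$qe)
  if (any(expected == 0 & observed > 0))
    stop("observed counts in a category with zero expectation: ",
         paste(need[expected == 0 & observed > 0], collapse = ", "))
  use <- expected > 0
  stat <- sum((observed[use] - expected[use])^2 / expected[use])
  list(statistic = stat, df = 3L, p_value = chisq_survival(stat, 3L),
       expected = expected)
}

#' Run the full tagging analysis
#'
#' @param exp_ a [tagging_experiment()].
#' @param observed optional 4-category observed counts for the fit check.
#' @return a `tagging_fit` list: `x_hat`, `untagged_fraction`,
#'   `tagging_accuracy`, and when `observed` is given `chisq`, `df`,
#'   `p_value`.
#' @export
tagging_fit <- function(exp_, observed = NULL) {
  x_hat <- estimate_untagged_count(exp_)
  acc <- tagging_accuracy(x_hat, exp_)
  out <- c(list(x_hat = x_hat), acc)
  if (!is.null(observed)) {
    fc <- tagging_fit_check(x_hat, exp_, observed)
    out$chisq <- fc$statistic; out$df <- fc$df; out$p_value <- fc$p_value
  }
  structure(out, class = "tagging_fit")
}

#' @export
print.tagging_fit <- function(x, ...) {
  cat(sprintf("<tagging_fit> x_hat = %d, untagged %.2f%%, accuracy %.2f%%\n",
              x$x_hat, x$untagged_fraction, x$tagging_accuracy))
  if (!is.null(x$chisq))
    cat(sprintf("  fit: chi-square %.4f (df %d), p = %.4f\n", x$chisq, x$df,
                x$p_value))
  invisible(x)
}
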