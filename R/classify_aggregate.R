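# Per-nucleus amplification classification (deterministic heuristic baseline
# plus a configurable neural training harness), bootstrap aggregation,
# sample-level calls and heterogeneity comparison.

#' Heuristic amplification classification from image statistics
#'
#' HSR-amplified images concentrate their FISH signal in few contiguous
#' blobs, giving a low mean and low variance of the per-nucleus copy-number
#' signal; EC-amplified images spread signal over many puncta with high
#' cell-to-cell variability. An image is called HSR-like iff
#' `mean < mean_cut` and `variance < var_cut` (strict inequalities),
#' EC-like otherwise.
#'
#' @param mean,variance image-level copy-number-signal statistics from
#'   [image_statistics()].
#' @param mean_cut,var_cut decision thresholds (defaults 10 and 64).
#' @return `"HSR-like"` or `"EC-like"`.
#' @export
heuristic_classify <- function(mean, variance, mean_cut = 10, var_cut = 64) {
  stopifnot(mean_cut > 0, var_cut > 0)
  if (mean < mean_cut && variance < var_cut) "HSR-like" else "EC-like"
}

#' Exhaustive threshold grid search for the heuristic classifier
#'
#' @param stats data frame with columns `mean`, `variance` and `truth`
#'   (truth in `"HSR-like"` / `"EC-like"`).
#' @param mean_grid,var_grid candidate cut-offs.
#' @return list with `mean_cut`, `var_cut`, `accuracy`; ties broken by the
#'   smallest `(mean_cut, var_cut)` pair.
#' @export
threshold_grid_search <- function(stats, mean_grid, var_grid) {
  if (!length(mean_grid) || !length(var_grid)) stop("empty grid")
  if (length(unique(stats$truth)) < 2L)
    stop("grid search needs at least two classes present")
  best <- NULL
  for (mc in sort(mean_grid)) for (vc in sort(var_grid)) {
    pred <- ifelse(stats$mean < mc & stats$variance < vc,
                   "HSR-like", "EC-like")
    acc <- mean(pred == stats$truth)
    if (is.null(best) || acc > best$accuracy)
      best <- list(mean_cut = mc, var_cut = vc, accuracy = acc)
  }
  best
}

# ---- neural classifier harness --------------------------------------------
# A compact feed-forward softmax network trained with Adam on downsampled
# patch features. It exposes the training-loop semantics that matter for
# the pipeline — cross-entropy loss, patience-based early stopping
# (validation loss for the three-class model, validation AUC for the binary
# model) and per-epoch balanced stratified sampling — at a scale that runs
# on one CPU.

#' Configuration of the neural classifier harness
#'
#' @param n_classes 2 (amp vs no-amp gate) or 3 (EC/HSR/no-amp).
#' @param hidden_units integer vector of hidden-layer widths.
#' @param learning_rate Adam step size; defaults to 1e-4 for the
#'   three-class model and 5e-4 for the binary model.
#' @param patience early-stopping patience in epochs (default 7).
#' @param max_epochs training budget (default 200).
#' @param balanced_sampling draw each epoch's batch with equal weight per
#'   stratum (binary model); strata are `tissue x label` when a tissue
#'   factor is supplied, else labels.
#' @param feature_size patches are block-averaged to
#'   `feature_size x feature_size` per channel before flattening.
#' @param seed RNG seed for initialization and sampling.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(n_classes = 3L, hidden_units = c(32L),
                              learning_rate = NULL, patience = 7L,
                              max_epochs = 200L, balanced_sampling = FALSE,
                              feature_size = 8L, seed = 1L) {
  stopifnot(n_classes %in% c(2L, 3L), all(hidden_units > 0), patience > 0,
            max_epochs > 0, feature_size > 0)
  if (is.null(learning_rate))
    learning_rate <- if (n_classes == 3L) 1e-4 else 5e-4
  structure(list(n_classes = as.integer(n_classes),
                 hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate, patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 balanced_sampling = balanced_sampling,
                 feature_size = as.integer(feature_size),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

# Block-average a matrix down to fs x fs.
block_mean <- function(m, fs) {
  n <- nrow(m)
  idx <- ceiling(seq_len(n) / (n / fs))
  rowsum(t(rowsum(m, idx)), idx) / (n / fs)^2
}

#' Extract features from a patch for the classifier harness
#' @param patch a `nucleus_patch` (raw or rescaled).
#' @param feature_size downsampled side length.
#' @return numeric feature vector (dapi + target blocks, unit scale).
#' @export
patch_features <- function(patch, feature_size = 8L) {
  sc <- if (patch$rescaled) 1 else 255
  ix <- function(ch) match(ch, patch$channels)
  f <- c(block_mean(patch$pixels[, , ix("dapi")] / sc, feature_size),
         block_mean(patch$pixels[, , ix("target")] / sc, feature_size))
  as.numeric(f)
}

#' Balanced per-epoch sample indices over strata
#'
#' Draws `max(stratum size)` indices with replacement from every stratum,
#' so each stratum contributes equal expected weight to the epoch
#' regardless of its size (majority strata are effectively down-weighted).
#'
#' @param strata integer/factor stratum id per observation.
#' @return integer vector of row indices.
#' @export
balanced_stratum_indices <- function(strata) {
  strata <- as.integer(factor(strata))
  per <- max(tabulate(strata))
  unlist(lapply(unique(strata), function(s) {
    pool <- which(strata == s)
    pool[sample.int(length(pool), per, replace = TRUE)]
  }))
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

nn_init <- function(d, hidden, k) {
  sizes <- c(d, hidden, k)
  lapply(seq_len(length(sizes) - 1L), function(i) {
    list(W = matrix(stats::rnorm(sizes[i] * sizes[i + 1L],
                                 sd = sqrt(2 / sizes[i])),
                    sizes[i], sizes[i + 1L]),
         b = rep(0, sizes[i + 1L]))
  })
}

nn_forward <- function(layers, X) {
  acts <- list(X)
  for (i in seq_along(layers)) {
    Z <- acts[[i]] %*% layers[[i]]$W +
      matrix(layers[[i]]$b, nrow(acts[[i]]), length(layers[[i]]$b),
             byrow = TRUE)
    acts[[i + 1L]] <- if (i < length(layers)) pmax(Z, 0) else Z
  }
  list(acts = acts, probs = softmax(acts[[length(acts)]]))
}

nn_gradients <- function(layers, acts, probs, Y) {
  n <- nrow(Y)
  delta <- (probs - Y) / n
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    grads[[i]] <- list(W = t(acts[[i]]) %*% delta, b = colSums(delta))
    if (i > 1L)
      delta <- (delta %*% t(layers[[i]]$W)) * (acts[[i]] > 0)
  }
  grads
}

cross_entropy <- function(probs, Y) -mean(rowSums(Y * log(pmax(probs, 1e-12))))

binary_auc <- function(score, y) {
  # probability that a positive outranks a negative (ties count half)
  r <- rank(score)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train the neural classifier harness
#'
#' Full-batch Adam on cross-entropy loss. Early stopping monitors the
#' validation loss for the three-class model and the validation AUC for the
#' binary model, halting when the monitored quantity has not improved for
#' `patience` epochs and restoring the best checkpoint. With
#' `balanced_sampling = TRUE` each epoch trains on a batch drawn with equal
#' expected weight from every stratum (`tissue x label` when `tissue` is
#' supplied), down-weighting majority strata.
#'
#' @param patches list of `nucleus_patch` objects.
#' @param labels factor or character vector of class labels (length of
#'   `patches`); for `n_classes = 2` exactly two levels.
#' @param config a [classifier_config()].
#' @param validation optional list(patches, labels) used for early
#'   stopping; defaults to the training data.
#' @param tissue optional stratification factor for balanced sampling.
#' @return a `fish_classifier` handle with `predict` support via
#'   [classifier_predict()].
#' @export
classifier_train <- function(patches, labels, config = classifier_config(),
                             validation = NULL, tissue = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("training data contains a single class")
  if (nlevels(labels) != config$n_classes)
    stop("label levels do not match n_classes")
  set.seed(config$seed)
  X <- t(vapply(patches, patch_features, numeric(2 * config$feature_size^2),
                feature_size = config$feature_size))
  Y <- diag(config$n_classes)[as.integer(labels), , drop = FALSE]
  if (is.null(validation)) {
    Xv <- X; Yv <- Y
  } else {
    Xv <- t(vapply(validation$patches, patch_features,
                   numeric(2 * config$feature_size^2),
                   feature_size = config$feature_size))
    Yv <- diag(config$n_classes)[as.integer(factor(validation$labels,
                                                   levels = levels(labels))), ,
                                 drop = FALSE]
  }
  strata <- if (is.null(tissue)) as.integer(labels)
            else as.integer(interaction(tissue, labels, drop = TRUE))
  layers <- nn_init(ncol(X), config$hidden_units, config$n_classes)
  adam <- list(m = rapply(layers, function(x) x * 0, how = "replace"),
               v = rapply(layers, function(x) x * 0, how = "replace"),
               t = 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(metric = -Inf, loss = Inf, layers = layers, epoch = 0L)
  wait <- 0L
  history <- numeric(0)
  for (epoch in seq_len(config$max_epochs)) {
    idx <- if (config$balanced_sampling) balanced_stratum_indices(strata)
           else seq_len(nrow(X))
    fw <- nn_forward(layers, X[idx, , drop = FALSE])
    gr <- nn_gradients(layers, fw$acts, fw$probs, Y[idx, , drop = FALSE])
    adam$t <- adam$t + 1
    for (i in seq_along(layers)) for (p in c("W", "b")) {
      adam$m[[i]][[p]] <- b1 * adam$m[[i]][[p]] + (1 - b1) * gr[[i]][[p]]
      adam$v[[i]][[p]] <- b2 * adam$v[[i]][[p]] + (1 - b2) * gr[[i]][[p]]^2
      mhat <- adam$m[[i]][[p]] / (1 - b1^adam$t)
      vhat <- adam$v[[i]][[p]] / (1 - b2^adam$t)
      layers[[i]][[p]] <- layers[[i]][[p]] -
        config$learning_rate * mhat / (sqrt(vhat) + eps)
    }
    val <- nn_forward(layers, Xv)
    loss <- cross_entropy(val$probs, Yv)
    if (config$n_classes == 2L) {
      metric <- binary_auc(val$probs[, 2], Yv[, 2])
      history <- c(history, metric)
    } else {
      metric <- -loss
      history <- c(history, loss)
    }
    improved <- metric > best$metric + 1e-12
    if (improved || (metric >= best$metric - 1e-12 && loss < best$loss - 1e-12))
      best <- list(metric = max(metric, best$metric), loss = loss,
                   layers = layers, epoch = epoch)
    # the patience clock follows the monitored metric (AUC for the binary
    # model, validation loss otherwise); equal-metric checkpoints with
    # lower loss refresh the weights but not the clock
    if (improved) wait <- 0L else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  converged <- best$epoch < config$max_epochs
  if (!converged)
    warning("no early stop within max_epochs; returning best checkpoint")
  structure(list(layers = best$layers, config = config,
                 classes = levels(labels), history = history,
                 best_epoch = best$epoch), class = "fish_classifier")
}

#' Predict class posteriors for patches
#'
#' @param model a `fish_classifier` from [classifier_train()].
#' @param patches list of `nucleus_patch` objects.
#' @return data frame of `nucleus_prediction` rows: one posterior column
#'   per class, `hard_label` (argmax class) and `source = "cnn"`.
#' @export
classifier_predict <- function(model, patches) {
  X <- t(vapply(patches, patch_features,
                numeric(2 * model$config$feature_size^2),
                feature_size = model$config$feature_size))
  probs <- nn_forward(model$layers, X)$probs
  colnames(probs) <- model$classes
  data.frame(nucleus_id = seq_along(patches), probs, check.names = FALSE,
             hard_label = model$classes[max.col(probs, ties.method = "first")],
             source = "cnn")
}

#' Merge per-window predictions of one nucleus by mean posterior
#'
#' Large nuclei tiled into several windows produce one prediction per
#' window; the nucleus call is the argmax of the averaged posteriors.
#'
#' @param predictions data frame of predictions with posterior columns
#'   `classes` and a `nucleus_id` column.
#' @param classes posterior column names.
#' @return one row per nucleus with averaged posteriors and `hard_label`.
#' @export
combine_window_predictions <- function(predictions,
                                       classes = intersect(
                                         c("EC-amp", "HSR-amp", "no-amp"),
                                         names(predictions))) {
  agg <- stats::aggregate(predictions[classes],
                          by = list(nucleus_id = predictions$nucleus_id), mean)
  agg$hard_label <- classes[max.col(agg[classes], ties.method = "first")]
  agg
}

#' Combine a target-only prediction with the centromeric focal gate
#'
#' The centromeric branch returns `"focal-amp"` or `"no-focal-amp"` per
#' nucleus. `no-focal-amp` overrides the target-only call to `no-amp`
#' (apparent signal without focal amplification is aneuploidy, not ecDNA or
#' HSR); `focal-amp` restricts the call to the better of EC-amp / HSR-amp;
#' an absent gate (failed centromere QC) passes the target-only call
#' through unchanged.
#'
#' @param target_pred named posterior vector over
#'   `c("EC-amp", "HSR-amp", "no-amp")`.
#' @param focal_pred `"focal-amp"`, `"no-focal-amp"`, or NULL when the gate
#'   is unavailable.
#' @return list with `hard_label`, `posteriors`, `source`.
#' @export
combine_focal_gate <- function(target_pred, focal_pred = NULL) {
  stopifnot(abs(sum(target_pred) - 1) < 1e-6)
  if (is.null(focal_pred))
    return(list(hard_label = names(which.max(target_pred)),
                posteriors = target_pred, source = "target_only"))
  focal_pred <- match.arg(focal_pred, c("focal-amp", "no-focal-amp"))
  if (focal_pred == "no-focal-amp")
    return(list(hard_label = "no-amp", posteriors = target_pred,
                source = "focal_gate"))
  amp <- target_pred[c("EC-amp", "HSR-amp")]
  list(hard_label = names(which.max(amp)), posteriors = target_pred,
       source = "focal_gate")
}

#' Bootstrap majority-vote sample call distribution
#'
#' Repeatedly draws `cells_per_draw` cells uniformly with replacement,
#' records the modal label of the draw (ties broken uniformly at random),
#' and returns the fraction of iterations each class won.
#'
#' @param labels character vector of per-cell hard labels.
#' @param cells_per_draw cells per bootstrap draw (default 10).
#' @param n_iterations bootstrap iterations (default 100).
#' @param seed RNG seed.
#' @param classes label universe for the output vector.
#' @return named numeric vector of win fractions summing to 1.
#' @export
bootstrap_sample_call <- function(labels, cells_per_draw = 10L,
                                  n_iterations = 100L, seed = 1L,
                                  classes = c("EC-amp", "HSR-amp", "no-amp")) {
  stopifnot(length(labels) >= 1, cells_per_draw > 0, n_iterations > 0)
  set.seed(seed)
  wins <- stats::setNames(numeric(length(classes)), classes)
  for (i in seq_len(n_iterations)) {
    draw <- labels[sample.int(length(labels), cells_per_draw, replace = TRUE)]
    tab <- table(draw)
    top <- names(tab)[tab == max(tab)]
    win <- if (length(top) == 1L) top else sample(top, 1L)
    wins[win] <- wins[win] + 1
  }
  wins / n_iterations
}

#' Sample-level amplification call from class fractions
#'
#' Thresholds are applied in order: `no-amp` when its fraction reaches
#' `noamp_cut` (default 0.80), else `HSR-amp` at `hsr_cut` (0.80), else
#' `EC-amp` at `ec_cut` (0.50); otherwise the sample is heterogeneous.
#'
#' @param fractions named fractions over
#'   `c("EC-amp", "HSR-amp", "no-amp")`, summing to 1.
#' @param noamp_cut,hsr_cut,ec_cut inclusive thresholds.
#' @return one of `"no-amp"`, `"HSR-amp"`, `"EC-amp"`, `"heterogeneous"`.
#' @export
sample_rule_call <- function(fractions, noamp_cut = 0.80, hsr_cut = 0.80,
                             ec_cut = 0.50) {
  stopifnot(abs(sum(fractions) - 1) < 1e-6)
  gv <- function(k) if (k %in% names(fractions)) fractions[[k]] else 0
  if (gv("no-amp") >= noamp_cut) return("no-amp")
  if (gv("HSR-amp") >= hsr_cut) return("HSR-amp")
  if (gv("EC-amp") >= ec_cut) return("EC-amp")
  "heterogeneous"
}

#' Upper-tail chi-square probability
#' @param statistic chi-square statistic.
#' @param df degrees of freedom.
#' @return `P(X2_df >= statistic)`.
#' @export
chisq_survival <- function(statistic, df)
  stats::pchisq(statistic, df, lower.tail = FALSE)

#' Chi-square comparison of two class-count vectors
#'
#' Pearson chi-square on the 2 x k contingency table of class counts from
#' two samples. Classes with zero counts in both samples are dropped before
#' computing the degrees of freedom (`df = k - 1` over the retained
#' classes).
#'
#' @param counts_a,counts_b named integer vectors over the same classes.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
heterogeneity_chisq <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == length(counts_b))
  if (sum(counts_a) == 0 || sum(counts_b) == 0)
    stop("a sample has no counts")
  keep <- counts_a + counts_b > 0
  tab <- rbind(counts_a[keep], counts_b[keep])
  k <- sum(keep)
  if (k < 2L) return(list(statistic = 0, df = 0L, p_value = 1))
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expd)^2 / expd)
  df <- k - 1L
  list(statistic = stat, df = df, p_value = chisq_survival(stat, df))
}
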