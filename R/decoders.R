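#' Train one-vs-rest SVM movement decoders
#'
#' One soft-margin RBF-kernel SVM per movement, trained against all other
#' movements and rest on identical feature rows. Scores are the tanh of
#' the decision margin, so they lie in \[-1, 1\] and preserve the zero
#' crossing used by [arbitrate()]. Class imbalance (rest bins outnumber
#' movement bins) is handled by inverse-frequency class weights. The RBF
#' bandwidth defaults to the median heuristic on pairwise training
#' distances; `cost` defaults to 1.
#'
#' @param features Bins x features numeric matrix (or `mwp_features`
#'   object).
#' @param labels Character vector, one label per bin, containing "rest"
#'   and the movement labels.
#' @param movements Movements to build decoders for; default every
#'   non-rest label present.
#' @param cost Soft-margin cost C.
#' @param gamma RBF bandwidth; `NULL` = median heuristic.
#' @param min_bins Minimum labelled bins required per movement.
#' @param seed Seed for the gamma-heuristic subsample (training itself is
#'   deterministic).
#' @return A `decoder_bank`.
#' @export
train_decoders <- function(features, labels, movements = NULL, cost = 1,
                           gamma = NULL, min_bins = 20, seed = 1) {
  if (inherits(features, "mwp_features")) features <- features$features
  features <- as.matrix(features)
  if (nrow(features) != length(labels))
    stop("train_decoders: one label per feature row required")
  if (is.null(movements)) movements <- setdiff(unique(labels), "rest")
  if (length(movements) < 1 || length(unique(labels)) < 2)
    stop("train_decoders: need at least 2 classes")
  counts <- table(factor(labels, levels = c("rest", movements)))
  low <- counts[movements] < min_bins
  if (any(low))
    stop("train_decoders: too few bins for ",
         paste(movements[low], collapse = ", "), " (counts: ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
         "; need >= ", min_bins, ")")
  if (is.null(gamma)) {
    idx <- if (nrow(features) > 400)
      with_seed(seed, sample.int(nrow(features), 400)) else seq_len(nrow(features))
    d2 <- stats::dist(features[idx, , drop = FALSE])^2
    med <- stats::median(d2[d2 > 0])
    gamma <- if (is.finite(med) && med > 0) 1 / med else 1 / ncol(features)
  }
  models <- lapply(movements, function(m) {
    y <- factor(ifelse(labels == m, m, "other"), levels = c(m, "other"))
    wts <- 1 / table(y)
    wts <- wts / sum(wts) * 2
    fit <- e1071::svm(features, y, kernel = "radial", gamma = gamma,
                      cost = cost, class.weights = wts, scale = TRUE)
    dv <- attr(stats::predict(fit, features, decision.values = TRUE),
               "decision.values")[, 1]
    # libsvm's margin sign depends on label ordering; calibrate so the
    # target class scores positive
    flip <- mean(dv[y == m]) < mean(dv[y == "other"])
    list(fit = fit, flip = flip)
  })
  names(models) <- movements
  structure(list(models = models, movements = movements, gamma = gamma,
                 cost = cost, n_features = ncol(features), seed = seed,
                 feature_names = colnames(features)),
            class = "decoder_bank")
}

#' @export
print.decoder_bank <- function(x, ...) {
  cat(sprintf("Decoder bank: %s (one-vs-rest RBF SVM, gamma = %.3g, C = %g, %d features)\n",
              paste(x$movements, collapse = "/"), x$gamma, x$cost,
              x$n_features))
  invisible(x)
}

#' Score feature rows with every decoder in the bank
#'
#' @param bank A [train_decoders()] result.
#' @param feature_rows A single feature row or a bins x features matrix
#'   matching the bank's feature dimensionality.
#' @return Matrix bins x movements of scores in \[-1, 1\].
#' @export
score_bin <- function(bank, feature_rows) {
  stopifnot(inherits(bank, "decoder_bank"))
  if (is.null(dim(feature_rows)))
    feature_rows <- matrix(feature_rows, nrow = 1)
  feature_rows <- as.matrix(feature_rows)
  if (ncol(feature_rows) != bank$n_features)
    stop("score_bin: feature rows have ", ncol(feature_rows),
         " columns; bank expects ", bank$n_features)
  scores <- vapply(bank$movements, function(m) {
    mod <- bank$models[[m]]
    dv <- attr(stats::predict(mod$fit, feature_rows,
                              decision.values = TRUE),
               "decision.values")[, 1]
    if (mod$flip) dv <- -dv
    tanh(dv)
  }, numeric(nrow(feature_rows)))
  if (is.null(dim(scores)))
    scores <- matrix(scores, nrow = 1, dimnames = list(NULL, bank$movements))
  scores
}

#' Arbitrate per-movement scores into a single decision
#'
#' The movement with the highest score drives the decision if and only if
#' that score exceeds zero; otherwise the decision is rest. Exact ties are
#' broken by the fixed movement order of the score vector.
#'
#' @param scores Named numeric vector of per-movement scores (one bin), or
#'   a bins x movements matrix.
#' @return Character decision(s): a movement name or "rest".
#' @export
arbitrate <- function(scores) {
  if (is.null(dim(scores))) {
    if (any(!is.finite(scores))) stop("arbitrate: scores must be finite")
    i <- which.max(scores)
    return(if (scores[i] > 0) names(scores)[i] else "rest")
  }
  if (any(!is.finite(scores))) stop("arbitrate: scores must be finite")
  mv <- colnames(scores)
  best <- max.col(scores, ties.method = "first")
  ifelse(scores[cbind(seq_len(nrow(scores)), best)] > 0, mv[best], "rest")
}

#' Decode feature rows: scores plus arbitrated decisions
#'
#' @param object A `decoder_bank`.
#' @param newdata Feature matrix (bins x features) or `mwp_features`.
#' @param ... Unused.
#' @return Data frame with one score column per movement and a `decision`
#'   column.
#' @export
predict.decoder_bank <- function(object, newdata, ...) {
  if (inherits(newdata, "mwp_features")) newdata <- newdata$features
  s <- score_bin(object, newdata)
  out <- as.data.frame(s)
  names(out) <- paste0("score_", object$movements)
  out$decision <- arbitrate(s)
  out
}

#' Save / load a decoder bank
#'
#' The bank is serialized to an RDS container with a JSON manifest
#' (`<path>.json`) recording hyperparameters, movements, feature
#' dimensionality and package version.
#'
#' @param bank A `decoder_bank`.
#' @param path Output path (e.g. `bank.rds`).
#' @return `path` invisibly; `load_decoder_bank()` returns the bank.
#' @export
save_decoder_bank <- function(bank, path) {
  stopifnot(inherits(bank, "decoder_bank"))
  saveRDS(bank, path)
  jsonlite::write_json(
    list(movements = bank$movements, gamma = bank$gamma, cost = bank$cost,
         n_features = bank$n_features, seed = bank$seed,
         package_version = as.character(utils::packageVersion("neurobypass"))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_decoder_bank
#' @export
load_decoder_bank <- function(path) {
  bank <- readRDS(path)
  if (!inherits(bank, "decoder_bank"))
    stop("load_decoder_bank: ", path, " does not contain a decoder bank")
  bank
}
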