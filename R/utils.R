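#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's
#' RNG state, so seeded package internals never perturb user-level
#' random streams. `seed = NULL` leaves the RNG untouched.
#'
#' @param seed integer scalar or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Stratified train/test split
#'
#' Samples a fraction of each class independently so both sides of the
#' split keep the whole dataset's class prevalence to within one sample
#' per class.
#'
#' @param labels binary (0/1) vector.
#' @param fraction fraction assigned to the training side.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return Logical vector, `TRUE` for training samples.
#' @examples
#' table(stratifiedSplit(rep(c(0, 1), c(90, 10)), 0.6, seed = 1))
#' @export
stratifiedSplit <- function(labels, fraction, seed = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  labels <- as.integer(labels)
  train <- logical(length(labels))
  withSeed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      nTrain <- round(fraction * length(idx))
      nTrain <- max(1L, min(length(idx) - 1L, nTrain))
      train[sample(idx, nTrain)] <- TRUE
    }
  })
  train
}

#' Stratified cross-validation folds
#'
#' Assigns each sample to one of `k` folds, balancing the classes so every
#' fold contains both classes whenever each class has at least `k` members.
#'
#' @param labels binary (0/1) vector.
#' @param k number of folds.
#' @param seed integer seed, or `NULL`.
#' @return Integer vector of fold ids in `1:k`.
#' @export
stratifiedFolds <- function(labels, k, seed = NULL) {
  stopifnot(k >= 2)
  labels <- as.integer(labels)
  if (min(table(labels)) < k) {
    stop("each class needs at least ", k, " samples for ", k,
         "-fold stratified CV")
  }
  folds <- integer(length(labels))
  withSeed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

# shared argument checks -------------------------------------------------

assertBinaryLabels <- function(labels, what = "labels") {
  if (anyNA(labels) || !all(labels %in% c(0, 1))) {
    stop(what, " must be a binary 0/1 vector with no missing values")
  }
  invisible(as.integer(labels))
}

assertBothClasses <- function(labels, what = "labels") {
  labels <- assertBinaryLabels(labels, what)
  if (length(unique(labels)) < 2L) {
    stop(what, " must contain both classes")
  }
  invisible(labels)
}
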