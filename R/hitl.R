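# Human-in-the-loop iterative fine-tuning scaffold: predict, export masks
# for correction, ingest corrections, retrain, evaluate on a frozen test
# set, stop when all tracked metrics reach their thresholds.

content_key <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Initialize a human-in-the-loop training state
#'
#' The test set is frozen at construction and never merged into training;
#' content hashes guard against leakage across splits.
#'
#' @param train,val,test Named lists of `list(image, mask)` pairs (names
#'   are sample ids).
#' @param train_fun `function(train_pool, seed)` returning a trained
#'   model.
#' @param eval_fun `function(model, test)` returning a named list of
#'   metrics in \[0,1\].
#' @return A `hitl_state`.
#' @export
hitl_state <- function(train, val, test, train_fun, eval_fun) {
  stopifnot(is.function(train_fun), is.function(eval_fun),
            length(test) >= 1)
  keys <- list(train = vapply(train, content_key, ""),
               val = vapply(val, content_key, ""),
               test = vapply(test, content_key, ""))
  if (length(intersect(keys$test, c(keys$train, keys$val))))
    stop("test set leaks into train/val")
  structure(list(train = train, val = val, test = test,
                 test_keys = keys$test, train_fun = train_fun,
                 eval_fun = eval_fun, model = NULL, cycle = 0L,
                 history = list(), audit = list()),
            class = "hitl_state")
}

#' Run one correction-retrain-evaluate cycle
#'
#' Validates corrected pairs (mask shape must match the image), refuses
#' any pair whose content hash already lives in the frozen test set,
#' merges corrections into the training pool (newest wins per id, with an
#' audit record), retrains, and evaluates on the held-out test set.
#'
#' @param state A [hitl_state()].
#' @param new_pairs Named list of corrected `list(image, mask)` pairs;
#'   names matching existing train ids replace those samples.
#' @param seed Seed forwarded to `train_fun`.
#' @return The updated state; the new `cycle_report` (cycle index,
#'   dataset sizes, metrics, stop decision `NA` until thresholds are
#'   checked) is appended to `state$history`.
#' @export
run_cycle <- function(state, new_pairs = list(), seed = 1L) {
  stopifnot(inherits(state, "hitl_state"))
  for (id in names(new_pairs)) {
    p <- new_pairs[[id]]
    if (!identical(dim(as_gray(p$image)), dim(p$mask)))
      stop("correction/image shape mismatch for id ", id)
    if (content_key(p) %in% state$test_keys)
      stop("corrected pair ", id, " duplicates a held-out test sample")
  }
  for (id in names(new_pairs)) {
    if (!is.null(state$train[[id]]))
      state$audit[[length(state$audit) + 1L]] <-
        list(cycle = state$cycle + 1L, id = id, action = "replaced")
    else
      state$audit[[length(state$audit) + 1L]] <-
        list(cycle = state$cycle + 1L, id = id, action = "added")
    state$train[[id]] <- new_pairs[[id]]
  }
  state$cycle <- state$cycle + 1L
  state$model <- state$train_fun(state$train, seed)
  metrics <- state$eval_fun(state$model, state$test)
  report <- list(cycle_index = state$cycle,
                 n_train = length(state$train), n_val = length(state$val),
                 n_test = length(state$test), metrics = metrics,
                 stop_decision = NA)
  state$history[[state$cycle]] <- report
  state
}

#' Stopping decision from cycle history
#'
#' TRUE iff every tracked metric of the latest cycle meets its threshold
#' (defaults 0.90, the confluency-model goal; use 0.95 for the count
#' model).
#'
#' @param history List of cycle reports (e.g. `state$history`).
#' @param thresholds Named thresholds; names must appear in the report
#'   metrics.
#' @return Logical stop decision.
#' @export
check_stop <- function(history, thresholds = c(accuracy = 0.90,
                                               f1 = 0.90)) {
  stopifnot(length(history) >= 1)
  m <- history[[length(history)]]$metrics
  missing <- setdiff(names(thresholds), names(m))
  if (length(missing)) stop("metrics missing: ",
                            paste(missing, collapse = ", "))
  all(unlist(m[names(thresholds)]) >= thresholds)
}
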