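# Dataset splitting: random train/valid/test partitions and homology-
# cluster-grouped cross-validation with a whole-cluster holdout.

#' Random train/valid/test split
#'
#' Partitions `n` items by the given ratios (default 8:1:1). Sizes are
#' floor-allocated for the validation and test partitions with the
#' remainder assigned to training; identical seeds yield identical
#' splits. Optionally stratified on a label vector, in which case the
#' allocation is applied within each stratum.
#'
#' @param n number of items (or a data frame, whose row count is used).
#' @param ratios length-3 positive weights for train/valid/test.
#' @param seed integer seed.
#' @param stratify optional label vector of length `n` for stratified
#'   allocation.
#' @return a `dataset_split`: list with integer index vectors `train`,
#'   `valid`, `test`.
#' @export
split_random <- function(n, ratios = c(8, 1, 1), seed, stratify = NULL) {
  if (is.data.frame(n)) n <- nrow(n)
  abort_if(length(ratios) != 3L || any(ratios < 0) || sum(ratios) <= 0,
           "ratios must be three non-negative values with a positive sum")
  abort_if(n < 1L, "dataset is empty")
  alloc_one <- function(idx) {
    m <- length(idx)
    frac <- ratios / sum(ratios)
    n_valid <- floor(m * frac[2]); n_test <- floor(m * frac[3])
    n_train <- m - n_valid - n_test
    perm <- idx[sample.int(m)]
    list(train = perm[seq_len(n_train)],
         valid = perm[seq_len(n_valid) + n_train],
         test = perm[seq_len(n_test) + n_train + n_valid])
  }
  out <- with_seed(seed, {
    if (is.null(stratify)) {
      alloc_one(seq_len(n))
    } else {
      abort_if(length(stratify) != n, "stratify must have length n")
      parts <- lapply(split(seq_len(n), stratify), alloc_one)
      list(train = sort(unlist(lapply(parts, `[[`, "train"), use.names = FALSE)),
           valid = sort(unlist(lapply(parts, `[[`, "valid"), use.names = FALSE)),
           test = sort(unlist(lapply(parts, `[[`, "test"), use.names = FALSE)))
    }
  })
  out <- lapply(out, as.integer)
  structure(c(out, list(mode = "random", seed = as.integer(seed))),
            class = "dataset_split")
}

#' Homology-grouped cross-validation split with whole-cluster holdout
#'
#' Reserves approximately `holdout_fraction` of the records as a holdout
#' test set chosen by whole homology clusters (greedy packing to the
#' nearest achievable fraction), then deals the remaining clusters into
#' `n_folds` folds round-robin by descending cluster size. No cluster
#' ever spans two partitions, so training and evaluation proteins stay
#' evolutionarily independent.
#'
#' @param cluster_ids character vector: homology cluster of each record.
#' @param n_folds number of cross-validation folds.
#' @param holdout_fraction target fraction of records in the holdout.
#' @param seed integer seed.
#' @return a `dataset_split`: list with `folds` (integer fold id per
#'   record, `NA` for holdout records) and `holdout` (record indices).
#' @export
split_grouped <- function(cluster_ids, n_folds = 10L, holdout_fraction = 0.2,
                          seed) {
  abort_if(anyNA(cluster_ids), "every record needs a cluster_id")
  n <- length(cluster_ids)
  sizes <- table(cluster_ids)
  with_seed(seed, {
    target <- holdout_fraction * n
    holdout_clusters <- character(0)
    if (target > 0) {
      # greedy whole-cluster packing toward the target fraction
      order_c <- sample(names(sizes))
      got <- 0
      for (cl in order_c) {
        s <- as.integer(sizes[[cl]])
        if (abs(got + s - target) <= abs(got - target)) {
          holdout_clusters <- c(holdout_clusters, cl)
          got <- got + s
        }
        if (got >= target) break
      }
    }
    rest <- setdiff(names(sizes), holdout_clusters)
    abort_if(length(rest) < n_folds,
             sprintf("fewer clusters (%d) than folds (%d)", length(rest), n_folds))
    # round-robin by descending size (ties broken by the shuffled order)
    rest <- rest[sample.int(length(rest))]
    rest <- rest[order(-as.integer(sizes[rest]))]
    fold_of <- stats::setNames(rep(seq_len(n_folds), length.out = length(rest)),
                               rest)
    folds <- rep(NA_integer_, n)
    in_rest <- cluster_ids %in% rest
    folds[in_rest] <- as.integer(fold_of[cluster_ids[in_rest]])
    structure(list(folds = folds,
                   holdout = which(cluster_ids %in% holdout_clusters),
                   mode = "grouped", n_folds = as.integer(n_folds),
                   seed = as.integer(seed)),
              class = "dataset_split")
  })
}

#' Write / read a split as JSON with explicit index lists
#'
#' @param split a `dataset_split`.
#' @param path output path.
#' @return `path` (writer) or a `dataset_split` (reader).
#' @export
write_split_json <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_split_json
#' @export
read_split_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in intersect(c("train", "valid", "test", "holdout", "folds"), names(x))) {
    x[[f]] <- as.integer(x[[f]])
  }
  structure(x, class = "dataset_split")
}
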