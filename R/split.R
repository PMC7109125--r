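#' Split a dataset into train/valid/test partitions
#'
#' Partition sizes follow the integer-ratio convention of the benchmark
#' protocol: `test = floor(n * r_test / sum(r))`,
#' `valid = floor(n * r_valid / sum(r))`, and the train partition takes the
#' remainder, so the three sets are disjoint and exhaustive (49094 items at
#' 6:2:2 give a 9818-item test partition). Assignment is a seeded
#' permutation; in stratified mode items with and without the positive label
#' (canal-containing images) are partitioned separately at the same ratios,
#' balancing the class across partitions.
#'
#' @param n_items number of items (>= 10 when all three partitions are
#'   required and non-stratified sizes would otherwise be empty).
#' @param ratio positive integers `(train, valid, test)`.
#' @param seed RNG seed; identical seeds give identical partitions.
#' @param labels optional logical per-item flags for stratification.
#' @param stratified balance `labels` across partitions.
#' @return List of integer index vectors `train`, `valid`, `test`.
#' @export
split_dataset <- function(n_items, ratio = c(6, 2, 2), seed = 0L,
                          labels = NULL, stratified = FALSE) {
  if (any(ratio <= 0) || length(ratio) != 3L)
    stop("ratio must be 3 positive numbers (train, valid, test)")
  if (stratified) {
    if (is.null(labels)) stop("stratified split requires labels")
    if (length(labels) != n_items)
      stop("labels length must equal n_items")
    pos <- which(labels); neg <- which(!labels)
    if (length(pos) == 0 || length(neg) == 0)
      stop("impossible stratification: a class has no items")
    a <- split_dataset(length(pos), ratio, seed)
    b <- split_dataset(length(neg), ratio, seed + 1L)
    return(list(train = sort(c(pos[a$train], neg[b$train])),
                valid = sort(c(pos[a$valid], neg[b$valid])),
                test = sort(c(pos[a$test], neg[b$test]))))
  }
  s <- sum(ratio)
  n_test <- floor(n_items * ratio[3] / s)
  n_valid <- floor(n_items * ratio[2] / s)
  n_train <- n_items - n_valid - n_test
  perm <- with_seed(seed, sample.int(n_items))
  list(train = sort(perm[seq_len(n_train)]),
       valid = sort(perm[n_train + seq_len(n_valid)]),
       test = sort(perm[n_train + n_valid + seq_len(n_test)]))
}
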