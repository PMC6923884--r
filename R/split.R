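# Stratified train/evaluation/validation splitting, class weighting and
# network architecture enumeration.

# largest-remainder apportionment of n into parts proportional to
# fractions; remainder ties go to the earlier part
largest_remainder <- function(n, fractions) {
  quota <- n * fractions
  base <- floor(quota)
  rem <- quota - base
  left <- round(n - sum(base))
  if (left > 0) {
    extra <- order(-rem, seq_along(rem))[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Stratified three-way split
#'
#' Partitions samples into training / evaluation / validation sets whose
#' sizes follow largest-remainder rounding of `n * fractions` and whose
#' per-class proportions stay within one sample of the global prevalence.
#' Per class, largest-remainder allocation is applied under the constraint
#' that partition totals match the global targets (leftover samples go to
#' the partition with the largest fractional remainder among those with
#' remaining capacity).  Deterministic given the seed.
#'
#' @param y named binary vector (names are sample ids), or an
#'   [outcome_table()] combined with `outcome_name`.
#' @param outcome_name outcome to stratify on when `y` is an outcome table.
#' @param fractions length-3 fractions summing to 1; default
#'   `c(0.50, 0.25, 0.25)`.
#' @param seed shuffling seed.
#' @return a `split_assignment`: `train_ids`, `eval_ids`, `valid_ids`,
#'   `fractions`, `seed`.
#' @export
stratified_split <- function(y, outcome_name = NULL,
                             fractions = c(0.50, 0.25, 0.25), seed = 1) {
  if (inherits(y, "outcome_table")) {
    if (is.null(outcome_name)) stop("outcome_name required with outcome table")
    y <- outcome_vector(y, outcome_name)
  }
  if (is.null(names(y))) names(y) <- paste0("s", seq_along(y))
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n <- length(y)
  targets <- largest_remainder(n, fractions)
  classes <- sort(unique(y))
  if (min(table(y)) < 2)
    stop("a class has fewer samples than partitions can stratify (min 2)")
  if (min(table(y)) < length(fractions))
    warning("a class has fewer samples than partitions; ",
            "some partitions will lack that class")
  alloc <- matrix(0L, length(classes), length(fractions))
  rems <- matrix(0, length(classes), length(fractions))
  for (ci in seq_along(classes)) {
    nc <- sum(y == classes[ci])
    quota <- nc * fractions
    alloc[ci, ] <- floor(quota)
    rems[ci, ] <- quota - floor(quota)
  }
  capacity <- targets - colSums(alloc)
  for (ci in seq_along(classes)) {
    left <- sum(y == classes[ci]) - sum(alloc[ci, ])
    while (left > 0) {
      open <- which(capacity > 0)
      j <- open[order(-rems[ci, open], open)][1]
      alloc[ci, j] <- alloc[ci, j] + 1L
      capacity[j] <- capacity[j] - 1L
      rems[ci, j] <- 0
      left <- left - 1
    }
  }
  parts <- vector("list", length(fractions))
  with_seed(seed, {
    for (ci in seq_along(classes)) {
      ids <- sample(names(y)[y == classes[ci]])
      at <- 0
      for (j in seq_along(fractions)) {
        take <- alloc[ci, j]
        parts[[j]] <- c(parts[[j]], ids[seq_len(take) + at])
        at <- at + take
      }
    }
  })
  structure(list(train_ids = parts[[1]], eval_ids = parts[[2]],
                 valid_ids = parts[[3]], fractions = fractions, seed = seed),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("split_assignment: train %d / eval %d / valid %d (seed %d)\n",
              length(x$train_ids), length(x$eval_ids), length(x$valid_ids),
              x$seed))
  invisible(x)
}

#' Inverse-frequency class weights
#'
#' Per-class weights proportional to the inverse class frequency,
#' normalized so the mean per-sample weight is 1 (the total weighted sample
#' count equals n).
#'
#' @param y binary 0/1 vector with both classes present.
#' @return named numeric vector of per-class weights (`"0"`, `"1"`).
#' @export
class_weights <- function(y) {
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab == 0)) stop("both classes must be present")
  k <- length(tab)
  w <- length(y) / (k * as.numeric(tab))
  setNames(w, names(tab))
}

#' Enumerate hidden-layer architectures
#'
#' All hidden-size sequences with depth in `depths` and widths drawn from
#' `widths`.  With `constraint = "non_increasing"` only non-increasing
#' sequences are kept (e.g. `c(8, 8, 8, 2)`), the shape of every
#' well-performing small funnel network; `"all"` keeps every sequence.
#' Order is deterministic: by depth, then lexicographic with larger widths
#' first.
#'
#' @param depths hidden-layer counts (default 1:4).
#' @param widths allowed layer widths (default `c(2, 4, 8)`).
#' @param constraint `"non_increasing"` or `"all"`.
#' @return list of integer vectors.
#' @export
enumerate_architectures <- function(depths = 1:4, widths = c(2, 4, 8),
                                    constraint = c("non_increasing", "all")) {
  constraint <- match.arg(constraint)
  widths <- sort(unique(widths), decreasing = TRUE)
  out <- list()
  for (d in sort(depths)) {
    grid <- do.call(expand.grid, rev(replicate(d, widths, simplify = FALSE)))
    grid <- grid[, rev(seq_len(d)), drop = FALSE]
    for (i in seq_len(nrow(grid))) {
      arch <- as.integer(grid[i, ])
      if (constraint == "non_increasing" && is.unsorted(rev(arch))) next
      out[[length(out) + 1L]] <- arch
    }
  }
  unique(out)
}
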