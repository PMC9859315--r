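#' Natural-breaks (Fisher–Jenks) classification
#'
#' Optimal 1-D classification minimising the total within-class sum of
#' squared deviations, computed by dynamic programming over the sorted
#' values (the Fisher algorithm), so the partition is globally optimal and
#' deterministic — ties in the optimum resolve to the partition whose class
#' boundaries sit lowest.
#'
#' @param values numeric vector to classify (the accessibility scores of
#'   the accessible units, in this pipeline).
#' @param n_classes number of classes, default 5; must not exceed the
#'   number of distinct values.
#' @return List with `classes` (integer class index per input value, 1 =
#'   lowest), `breaks` (numeric vector of length `n_classes + 1`: the
#'   minimum followed by each class's maximum) and `cost` (the minimised
#'   within-class sum of squares).
#' @export
grade_natural_breaks <- function(values, n_classes = 5L) {
  if (length(values) == 0) stop("no values to classify")
  n_classes <- as.integer(n_classes)
  if (length(unique(values)) < n_classes) {
    stop("fewer distinct values (", length(unique(values)),
         ") than classes (", n_classes, "); reduce n_classes")
  }
  o <- order(values)
  x <- values[o]
  n <- length(x)
  s <- cumsum(x)
  s2 <- cumsum(x * x)
  # within-class SS of sorted x[i..j], vectorised over i
  ssd_to <- function(i, j) {
    si <- c(0, s)[i]; s2i <- c(0, s2)[i]
    (s2[j] - s2i) - (s[j] - si)^2 / (j - i + 1)
  }
  cost <- matrix(Inf, n_classes, n)
  from <- matrix(NA_integer_, n_classes, n)
  cost[1, ] <- ssd_to(1L, seq_len(n))
  from[1, ] <- 1L
  if (n_classes > 1) {
    for (m in 2:n_classes) {
      for (j in m:n) {
        i <- m:j
        cand <- cost[m - 1, i - 1L] + ssd_to(i, j)
        k <- which.min(cand) # first minimum -> lowest boundary
        cost[m, j] <- cand[k]
        from[m, j] <- i[k]
      }
    }
  }
  # backtrack class boundaries over the sorted order
  upper <- integer(n_classes)
  j <- n
  for (m in n_classes:1) {
    upper[m] <- j
    j <- from[m, j] - 1L
  }
  cls_sorted <- rep(seq_len(n_classes), times = diff(c(0L, upper)))
  classes <- integer(n)
  classes[o] <- cls_sorted
  list(classes = classes,
       breaks = c(x[1], x[upper]),
       cost = cost[n_classes, n])
}
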