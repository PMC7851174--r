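#' Hellinger distance between two composition vectors
#'
#' The Hellinger distance between two probability vectors \eqn{x} and \eqn{y}
#' is \eqn{\sqrt{\tfrac12 \sum_i (\sqrt{x_i} - \sqrt{y_i})^2}}. It is bounded
#' in \eqn{[0, 1]}: 0 for identical compositions and 1 for compositions with
#' disjoint support. On square-rooted vectors it is the Euclidean distance
#' scaled by \eqn{1/\sqrt{2}}, which is why the pipeline works on
#' square-root transformed splicing ratios: Euclidean geometry on that scale
#' is Hellinger geometry on the ratios.
#'
#' @param x,y Non-negative numeric vectors of equal length summing to 1.
#' @return A single number in \eqn{[0, 1]}.
#' @examples
#' hellinger_distance(c(0.5, 0.5), c(0.98, 0.02))
#' @export
hellinger_distance <- function(x, y) {
  if (length(x) != length(y)) {
    stop_format("length mismatch: %d vs %d", length(x), length(y))
  }
  check_composition(x, what = "x")
  check_composition(y, what = "y")
  sqrt(0.5 * sum((sqrt(x) - sqrt(y))^2))
}

#' Pairwise Hellinger distance matrix of splicing-ratio profiles
#'
#' @param ratios Numeric matrix, samples in rows, transcripts in columns;
#'   each row a composition summing to 1.
#' @return A `"dist"` object with entries in \eqn{[0, 1]}.
#' @seealso [hellinger_distance()]
#' @export
hellinger_dist <- function(ratios) {
  ratios <- as.matrix(ratios)
  if (any(ratios < 0)) stop_format("ratios contain negative entries")
  bad <- abs(rowSums(ratios) - 1) > 1e-6
  if (any(bad)) {
    stop_format("%d row(s) do not sum to 1", sum(bad))
  }
  dist(sqrt(ratios)) / sqrt(2)
}
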