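#' Per-sample adjusted transcript relative expression
#'
#' Covariate adjustment happens on the square-root scale (see
#' [adjust_covariates()]). To express effects on the relative-expression
#' scale, each residual is re-centered by adding back the per-transcript
#' grand mean of the square-root ratios and back-transformed by squaring,
#' then clipped to \eqn{[0, 1]}. With no covariates this reconstructs the raw
#' splicing ratios exactly.
#'
#' @param residuals Samples-by-transcripts matrix of sqrt-scale residuals.
#' @param center Per-transcript grand mean of the square-root ratios.
#' @return Matrix of adjusted relative expression values in \eqn{[0, 1]}.
#' @export
adjusted_relative_expression <- function(residuals, center) {
  residuals <- as.matrix(residuals)
  if (length(center) != ncol(residuals)) {
    stop_format("center length (%d) != transcript count (%d)",
                length(center), ncol(residuals))
  }
  x <- sweep(residuals, 2L, center, "+")^2
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Group means of adjusted relative expression
#'
#' @inheritParams adjusted_relative_expression
#' @param groups Dosage (or other) labels, one per sample.
#' @return Groups-by-transcripts matrix of means; row names are group levels.
#' @export
group_adjusted_means <- function(residuals, center, groups) {
  x <- adjusted_relative_expression(residuals, center)
  g <- .as_groups(groups, nrow(x))
  if (any(tabulate(g) == 0L)) stop_format("empty group")
  m <- rowsum(x, g) / tabulate(g)
  rownames(m) <- levels(g)
  m
}

#' Splicing-QTL effect size: maximum difference (MD)
#'
#' The effect size of an sQTL is the absolute maximum difference in mean
#' adjusted transcript relative expression between genotype groups, taken
#' over all transcripts and all group pairs. MD lies in \eqn{[0, 1]}; values
#' below 0.05 are conventionally excluded from reported sQTLs.
#'
#' @param group_means Groups-by-transcripts matrix of mean adjusted relative
#'   expression (see [group_adjusted_means()]).
#' @return A single number in \eqn{[0, 1]}.
#' @examples
#' effect_size_md(rbind(A = c(0.5, 0.3, 0.2), B = c(0.3, 0.4, 0.3)))
#' @export
effect_size_md <- function(group_means) {
  m <- as.matrix(group_means)
  if (nrow(m) < 2) stop_format("need >= 2 groups")
  if (anyNA(m)) stop_format("empty group or missing group means")
  max(apply(m, 2L, function(col) max(col) - min(col)))
}
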