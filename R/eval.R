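#' Tanimoto/Jaccard segmentation error
#'
#' Volume-overlap error between a predicted and a reference mask:
#' `1 - |A intersect B| / |A union B|`. 0 means perfect overlap, 1 means
#' disjoint masks.
#'
#' @param pred,truth congruent [binary_mask] objects (or logical arrays).
#' @return Error in \[0, 1\].
#' @examples
#' a <- binary_mask(matrix(c(TRUE, TRUE, FALSE, FALSE), 2))
#' jaccard_error(a, a)  # 0
#' @export
jaccard_error <- function(pred, truth) {
  p <- if (inherits(pred, "binary_mask")) pred$data else pred
  t <- if (inherits(truth, "binary_mask")) truth$data else truth
  if (!identical(dim(p), dim(t)))
    stop("masks are not congruent: ", paste(dim(p), collapse = "x"),
         " vs ", paste(dim(t), collapse = "x"))
  uni <- sum(p | t)
  if (uni == 0) stop("Jaccard error undefined: both masks empty")
  1 - sum(p & t) / uni
}

#' Dice coefficient between two masks
#'
#' @inheritParams jaccard_error
#' @return `2 |A intersect B| / (|A| + |B|)` in \[0, 1\].
#' @export
dice_coefficient <- function(pred, truth) {
  p <- if (inherits(pred, "binary_mask")) pred$data else pred
  t <- if (inherits(truth, "binary_mask")) truth$data else truth
  if (!identical(dim(p), dim(t))) stop("masks are not congruent")
  denom <- sum(p) + sum(t)
  if (denom == 0) stop("Dice undefined: both masks empty")
  2 * sum(p & t) / denom
}

#' Batch segmentation evaluation with per-category aggregates
#'
#' Computes the Jaccard error and Dice coefficient per case and aggregates
#' mean and population standard deviation (n denominator) per nodule
#' category, the layout used for reporting error rates by nodule type.
#'
#' @param cases list of lists with fields `pred`, `truth` ([binary_mask])
#'   and `category` (character).
#' @return An `eval_report`: list with `per_case` and `aggregate` data
#'   frames.
#' @export
evaluate_batch <- function(cases) {
  if (length(cases) == 0) stop("need at least one case")
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    data.frame(case = i, category = cs$category %||% "all",
               jaccard_error = jaccard_error(cs$pred, cs$truth),
               dice = dice_coefficient(cs$pred, cs$truth),
               truth_voxels = sum(if (inherits(cs$truth, "binary_mask"))
                 cs$truth$data else cs$truth),
               pred_voxels = sum(if (inherits(cs$pred, "binary_mask"))
                 cs$pred$data else cs$pred))
  })
  per_case <- do.call(rbind, rows)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  agg <- do.call(rbind, lapply(split(per_case, per_case$category),
    function(df) data.frame(category = df$category[1], n = nrow(df),
                            mean_error = mean(df$jaccard_error),
                            sd_error = pop_sd(df$jaccard_error))))
  rownames(agg) <- NULL
  structure(list(per_case = per_case, aggregate = agg),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", nrow(x$per_case), "cases\n")
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}
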