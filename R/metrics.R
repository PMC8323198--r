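## Region-level evaluation: DSC, PPV and sensitivity, as scored by the
## BRATS online system, computed on whole 3-D volumes per case.
##
## Empty-mask convention (the online scorer's rule is undocumented):
## both masks empty -> 1 (a correct all-negative prediction is not
## penalized); exactly one empty -> 0.

mask_counts <- function(P, G) {
  if (!identical(dim(P), dim(G)))
    stop("mask shapes differ: ", paste(dim(P), collapse = "x"), " vs ",
         paste(dim(G), collapse = "x"))
  p <- as.logical(P); g <- as.logical(G)
  c(np = sum(p), ng = sum(g), ni = sum(p & g))
}

#' Dice similarity coefficient of two binary masks
#'
#' `2|P n G| / (|P| + |G|)`; returns 1 when both masks are empty.
#'
#' @param P,G Binary masks (logical or 0/1 numeric) of identical shape;
#'   `P` the prediction, `G` the reference.
#' @return Scalar in `[0, 1]`.
#' @export
dsc <- function(P, G) {
  n <- mask_counts(P, G)
  if (n[["np"]] + n[["ng"]] == 0) return(1)
  2 * n[["ni"]] / (n[["np"]] + n[["ng"]])
}

#' Positive predictive value (precision) of two binary masks
#'
#' `|P n G| / |P|`; an empty prediction scores 1 against an empty
#' reference and 0 otherwise.
#'
#' @inheritParams dsc
#' @return Scalar in `[0, 1]`.
#' @export
ppv <- function(P, G) {
  n <- mask_counts(P, G)
  if (n[["np"]] == 0) return(if (n[["ng"]] == 0) 1 else 0)
  n[["ni"]] / n[["np"]]
}

#' Sensitivity (recall) of two binary masks
#'
#' `|P n G| / |G|`; an empty reference scores 1 against an empty
#' prediction and 0 otherwise.
#'
#' @inheritParams dsc
#' @return Scalar in `[0, 1]`.
#' @export
sensitivity <- function(P, G) {
  n <- mask_counts(P, G)
  if (n[["ng"]] == 0) return(if (n[["np"]] == 0) 1 else 0)
  n[["ni"]] / n[["ng"]]
}

#' Evaluate one predicted label volume against ground truth
#'
#' Computes DSC, PPV and sensitivity for the three evaluation regions
#' (complete, core, enhancing) on the whole 3-D volumes.
#'
#' @param pred,truth 3-D integer label volumes (values 0..4) of
#'   identical shape.
#' @return A `region_report` data frame: one row per region with the
#'   three metrics and the voxel counts `n_pred`, `n_truth`,
#'   `n_intersect`.
#' @export
evaluate_case <- function(pred, truth) {
  pred <- validate_labels(pred)
  truth <- validate_labels(truth)
  if (!identical(dim(pred), dim(truth)))
    stop("prediction and truth shapes differ")
  rows <- lapply(EVAL_REGIONS, function(r) {
    P <- region_hard(pred, r); G <- region_hard(truth, r)
    n <- mask_counts(P, G)
    data.frame(region = r, dsc = dsc(P, G), ppv = ppv(P, G),
               sensitivity = sensitivity(P, G),
               n_pred = n[["np"]], n_truth = n[["ng"]],
               n_intersect = n[["ni"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("region_report", class(out))
  out
}

#' Evaluate a cohort of predictions
#'
#' @param cases Named (or unnamed) list of `list(pred =, truth =)`
#'   pairs of label volumes.
#' @param csv Optional path; when given, the per-case table is written
#'   as CSV.
#' @return List with `mean` (unweighted per-region means over cases)
#'   and `per_case` (long-format table).
#' @export
evaluate_cohort <- function(cases, csv = NULL) {
  if (!length(cases)) stop("empty cohort")
  ids <- names(cases)
  if (is.null(ids)) ids <- sprintf("case_%03d", seq_along(cases))
  per <- do.call(rbind, lapply(seq_along(cases), function(i) {
    rep <- evaluate_case(cases[[i]]$pred, cases[[i]]$truth)
    cbind(case_id = ids[i], as.data.frame(rep), stringsAsFactors = FALSE)
  }))
  agg <- aggregate(per[, c("dsc", "ppv", "sensitivity")],
                   by = list(region = per$region), FUN = mean)
  agg <- agg[match(EVAL_REGIONS, agg$region), ]
  rownames(agg) <- NULL
  if (!is.null(csv)) write.csv(per, csv, row.names = FALSE)
  list(mean = agg, per_case = per)
}

#' Write a region report as JSON
#'
#' @param report A `region_report` or the `mean` table from
#'   [evaluate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(as.data.frame(report), path, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @importFrom stats aggregate
NULL
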