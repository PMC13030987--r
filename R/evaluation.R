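# axis-aligned rectangle IOU between one box and a set of boxes (vectorized)
rect_iou <- function(x1, y1, w1, h1, x2, y2, w2, h2) {
  ix <- pmax(0, pmin(x1 + w1 / 2, x2 + w2 / 2) - pmax(x1 - w1 / 2, x2 - w2 / 2))
  iy <- pmax(0, pmin(y1 + h1 / 2, y2 + h2 / 2) - pmax(y1 - h1 / 2, y2 - h2 / 2))
  inter <- ix * iy
  inter / (w1 * h1 + w2 * h2 - inter)
}

# greedy matching core: predictions in `order_idx` order take the
# highest-IOU unmatched truth of the same class and layer
greedy_match <- function(predicted, truth, order_idx, iou_threshold) {
  truth_taken <- rep(FALSE, nrow(truth))
  match_truth <- rep(NA_integer_, nrow(predicted))
  match_iou <- rep(NA_real_, nrow(predicted))
  truth_key <- paste(truth$cell_class, truth$z_index)
  pred_key <- paste(predicted$cell_class, predicted$z_index)
  cand_by_key <- split(seq_len(nrow(truth)), truth_key)
  for (p in order_idx) {
    cand <- cand_by_key[[pred_key[p]]]
    cand <- cand[!truth_taken[cand]]
    if (length(cand) == 0L) next
    iou <- rect_iou(
      predicted$x_um[p], predicted$y_um[p], predicted$width_um[p], predicted$height_um[p],
      truth$x_um[cand], truth$y_um[cand], truth$width_um[cand], truth$height_um[cand]
    )
    best <- which.max(iou)
    if (iou[best] >= iou_threshold) {
      match_truth[p] <- cand[best]
      match_iou[p] <- iou[best]
      truth_taken[cand[best]] <- TRUE
    }
  }
  list(match_truth = match_truth, match_iou = match_iou, truth_taken = truth_taken)
}

box_ids <- function(boxes) {
  if ("box_id" %in% names(boxes)) boxes$box_id else seq_len(nrow(boxes))
}

pred_order <- function(predicted) {
  order(-predicted$confidence, box_ids(predicted), method = "radix")
}

#' Match predicted boxes to ground-truth boxes by IOU
#'
#' One-to-one greedy matching in descending predicted-confidence order
#' (ties broken by `box_id`): each prediction takes the highest-IOU
#' unmatched truth box of the same class on the same layer, provided the
#' IOU reaches the threshold.
#'
#' @param predicted,truth Detection tibbles (see [read_detection_table()]);
#'   an optional `box_id` column gives stable identifiers.
#' @param iou_threshold Minimum IOU for a match (default 0.5).
#' @return A `match_result`: list with `matches` (tibble `pred_id`,
#'   `truth_id`, `iou`), `unmatched_pred`, `unmatched_truth`,
#'   `iou_threshold`.
#' @export
match_boxes <- function(predicted, truth, iou_threshold = 0.5) {
  pid <- box_ids(predicted)
  tid <- box_ids(truth)
  gm <- greedy_match(predicted, truth, pred_order(predicted), iou_threshold)
  hit <- !is.na(gm$match_truth)
  structure(
    list(
      matches = tibble(
        pred_id = pid[hit],
        truth_id = tid[gm$match_truth[hit]],
        iou = gm$match_iou[hit]
      ),
      unmatched_pred = pid[!hit],
      unmatched_truth = tid[!gm$truth_taken],
      iou_threshold = iou_threshold
    ),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> %d match(es) at IOU >= %g; %d unmatched prediction(s), %d unmatched truth(s)\n",
    nrow(x$matches), x$iou_threshold, length(x$unmatched_pred), length(x$unmatched_truth)
  ))
  invisible(x)
}

#' Precision-recall curves and average precision
#'
#' Sweeps the confidence threshold over the distinct predicted confidences
#' (descending). At each step precision = TP / (TP + FP) and recall =
#' TP / |truth| cumulatively; matches are assigned greedily in confidence
#' order at the given IOU threshold, per class and layer. Average precision
#' integrates the curve with right-running-maximum interpolated precision:
#' `AP = sum_k (r_k - r_{k-1}) * max(precision at recall >= r_k)`.
#'
#' @param predicted,truth Detection tibbles; `truth` must be non-empty for
#'   every class scored.
#' @param iou_threshold Minimum IOU counting a prediction as true positive.
#' @param by_class Score each class separately (default TRUE, the classes
#'   being those present in `truth`).
#' @return A `pr_curve` object: list with `points` (tibble `cell_class`,
#'   `confidence`, `tp`, `fp`, `precision`, `recall`) and `ap` (tibble
#'   `cell_class`, `average_precision`, `n_truth`, `n_predictions`).
#' @export
precision_recall <- function(predicted, truth, iou_threshold = 0.5, by_class = TRUE) {
  if (nrow(truth) == 0L) {
    stop_spatcube("recall undefined: ground-truth set is empty")
  }
  classes <- if (by_class) sort(unique(truth$cell_class)) else "all"

  curve_for <- function(k) {
    tr <- if (by_class) truth[truth$cell_class == k, ] else truth
    pr <- if (by_class) predicted[predicted$cell_class == k, ] else predicted
    n_truth <- nrow(tr)
    if (n_truth == 0L) stop_spatcube("no ground-truth boxes for class '%s'", k)
    if (nrow(pr) == 0L) {
      return(list(
        points = tibble(cell_class = k, confidence = numeric(0), tp = integer(0),
                        fp = integer(0), precision = numeric(0), recall = numeric(0)),
        ap = tibble(cell_class = k, average_precision = 0,
                    n_truth = n_truth, n_predictions = 0L)
      ))
    }
    ord <- pred_order(pr)
    gm <- greedy_match(pr, tr, ord, iou_threshold)
    is_tp <- !is.na(gm$match_truth[ord])
    conf <- pr$confidence[ord]
    cum_tp <- cumsum(is_tp)
    cum_fp <- cumsum(!is_tp)
    precision <- cum_tp / (cum_tp + cum_fp)
    recall <- cum_tp / n_truth
    # one curve point per distinct threshold: the last index at each value
    last <- rev(!duplicated(rev(conf)))
    # AP over the full prediction sequence with right-running-max precision
    p_interp <- rev(cummax(rev(precision)))
    dr <- diff(c(0, recall))
    ap <- sum(dr * p_interp)
    list(
      points = tibble(
        cell_class = k, confidence = conf[last], tp = cum_tp[last],
        fp = cum_fp[last], precision = precision[last], recall = recall[last]
      ),
      ap = tibble(cell_class = k, average_precision = ap,
                  n_truth = n_truth, n_predictions = nrow(pr))
    )
  }

  parts <- lapply(classes, curve_for)
  structure(
    list(
      points = bind_rows(lapply(parts, `[[`, "points")),
      ap = bind_rows(lapply(parts, `[[`, "ap")),
      iou_threshold = iou_threshold
    ),
    class = "pr_curve"
  )
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve> IOU >= %g\n", x$iou_threshold))
  print(x$ap)
  invisible(x)
}

#' @rdname precision_recall
#' @param x A `pr_curve`.
#' @param ... Unused.
#' @export
tidy.pr_curve <- function(x, ...) x$points

#' @rdname precision_recall
#' @export
glance.pr_curve <- function(x, ...) {
  tibble(
    mean_average_precision = mean(x$ap$average_precision),
    n_classes = nrow(x$ap),
    iou_threshold = x$iou_threshold
  )
}

#' Per-region predicted versus true cell counts
#'
#' Counts cell centroids per 3D region and class for a predicted and a
#' ground-truth cell set. Region bounds are half-open (`min <= p < max`).
#' Overlapping regions are allowed but flagged with a warning.
#'
#' @param predicted_cells,truth_cells Tibbles with `cell_class`, `x_um`,
#'   `y_um`, `z_um`.
#' @param regions Tibble with `region`, `xmin`, `xmax`, `ymin`, `ymax`,
#'   `zmin`, `zmax` (um).
#' @return A tibble: `region`, `cell_class`, `n_predicted`, `n_true`.
#' @export
count_comparison <- function(predicted_cells, truth_cells, regions) {
  assert_cols(regions, c("region", "xmin", "xmax", "ymin", "ymax", "zmin", "zmax"),
              "regions table")
  if (nrow(regions) > 1L) {
    overlaps <- FALSE
    for (i in seq_len(nrow(regions) - 1L)) {
      for (j in seq.int(i + 1L, nrow(regions))) {
        if (regions$xmin[i] < regions$xmax[j] && regions$xmin[j] < regions$xmax[i] &&
            regions$ymin[i] < regions$ymax[j] && regions$ymin[j] < regions$ymax[i] &&
            regions$zmin[i] < regions$zmax[j] && regions$zmin[j] < regions$zmax[i]) {
          overlaps <- TRUE
        }
      }
    }
    if (overlaps) warn("some regions overlap; counts are still reported per region")
  }
  classes <- sort(unique(c(predicted_cells$cell_class, truth_cells$cell_class)))
  in_region <- function(cells, r) {
    cells$x_um >= r$xmin & cells$x_um < r$xmax &
      cells$y_um >= r$ymin & cells$y_um < r$ymax &
      cells$z_um >= r$zmin & cells$z_um < r$zmax
  }
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    sel_p <- in_region(predicted_cells, r)
    sel_t <- in_region(truth_cells, r)
    tibble(
      region = r$region,
      cell_class = classes,
      n_predicted = vapply(classes, function(k) {
        sum(sel_p & predicted_cells$cell_class == k)
      }, integer(1), USE.NAMES = FALSE),
      n_true = vapply(classes, function(k) {
        sum(sel_t & truth_cells$cell_class == k)
      }, integer(1), USE.NAMES = FALSE)
    )
  })
  bind_rows(rows)
}
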