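# Automatic keypoint matching between a model's vocabulary and a novel
# dataset's vocabulary: per-image bipartite matching of predictions to
# ground truth on Euclidean cost, affinity averaging across images, and a
# final bipartite assignment yielding a conversion table.

# Hungarian algorithm (potentials / shortest augmenting path, O(n^3)),
# minimizing total cost. `cost` may be rectangular; rows <= cols required
# (callers pad). Returns for each row its assigned column.
hungarian <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  INF <- Inf
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1); way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j + 1]) next
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j + 1]) {
          minv[j + 1] <- cur
          way[j + 1] <- j0
        }
        if (minv[j + 1] < delta) {
          delta <- minv[j + 1]
          j1 <- j
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) assign[p[j + 1]] <- j
  assign
}

#' Minimum-cost bipartite assignment
#'
#' Solves the assignment problem on an arbitrary rectangular cost matrix.
#' Unequal sizes are handled by padding with a large sentinel cost;
#' sentinel assignments are discarded, leaving surplus rows/columns
#' unassigned.
#'
#' @param cost Numeric matrix (rows = one side, columns = the other).
#' @param maximize Maximize instead of minimize.
#' @return Integer vector, one entry per row: the assigned column or
#'   `NA` for unassigned rows.
#' @export
solve_assignment <- function(cost, maximize = FALSE) {
  stopifnot(is.matrix(cost), all(is.finite(cost)))
  if (maximize) cost <- max(cost) - cost
  n <- nrow(cost); m <- ncol(cost)
  d <- max(n, m)
  sentinel <- max(abs(cost)) * d + 1
  padded <- matrix(sentinel, d, d)
  padded[seq_len(n), seq_len(m)] <- cost
  a <- hungarian(padded)
  a <- a[seq_len(n)]
  a[a > m] <- NA_integer_
  a
}

#' Match predicted to ground-truth keypoints for one image
#'
#' Minimum-total-Euclidean-cost bipartite assignment between a model's
#' predictions and a dataset's ground-truth keypoints. With unequal
#' vocabulary sizes, surplus keypoints stay unmatched.
#'
#' @param predictions Tibble: `keypoint`, `x`, `y` and optionally
#'   `confidence`.
#' @param truth Tibble: `keypoint`, `x`, `y` (ground truth; rows with
#'   non-finite coordinates are ignored).
#' @param confidence_floor Predictions below this confidence are excluded
#'   before matching (default 0: include all).
#' @return Binary match matrix, rows = prediction keypoints, columns =
#'   ground-truth keypoints (at most one 1 per row and column).
#' @export
match_image <- function(predictions, truth, confidence_floor = 0) {
  pred <- tibble::as_tibble(predictions)
  gt <- tibble::as_tibble(truth)
  gt <- gt[is.finite(gt$x) & is.finite(gt$y), ]
  keep <- if ("confidence" %in% names(pred) && confidence_floor > 0)
    pred$confidence >= confidence_floor else rep(TRUE, nrow(pred))
  M <- matrix(0L, nrow(pred), nrow(gt),
              dimnames = list(pred$keypoint, gt$keypoint))
  if (nrow(gt) == 0 || !any(keep)) {
    warn("empty prediction or ground-truth set: empty match matrix")
    return(M)
  }
  act <- which(keep)
  cost <- outer(seq_along(act), seq_len(nrow(gt)), function(i, j) {
    sqrt((pred$x[act[i]] - gt$x[j])^2 + (pred$y[act[i]] - gt$y[j])^2)
  })
  if (length(act) <= nrow(gt)) {
    a <- solve_assignment(cost)
    for (i in seq_along(act)) if (!is.na(a[i])) M[act[i], a[i]] <- 1L
  } else {
    a <- solve_assignment(t(cost))
    for (j in seq_len(nrow(gt))) if (!is.na(a[j])) M[act[a[j]], j] <- 1L
  }
  M
}

#' Average match matrices into an affinity matrix
#'
#' @param matches List of equally shaped binary match matrices (one per
#'   image).
#' @return Real matrix in `[0, 1]`: elementwise mean.
#' @export
aggregate_matches <- function(matches) {
  stopifnot(length(matches) >= 1)
  d <- dim(matches[[1]])
  for (m in matches) {
    if (!identical(dim(m), d)) abort("match matrix shape mismatch")
  }
  Reduce(`+`, matches) / length(matches)
}

#' Derive the final conversion table from an affinity matrix
#'
#' Runs a maximum-total-affinity assignment and keeps pairs whose
#' affinity reaches `min_affinity` (majority-of-images agreement by
#' default).
#'
#' @param affinity Matrix from [aggregate_matches()] (rows = model
#'   keypoints, columns = dataset keypoints).
#' @param min_affinity Acceptance threshold in `[0, 1]`.
#' @return Tibble: `model_keypoint`, `dataset_keypoint`, `affinity`
#'   (injective partial mapping).
#' @export
derive_table <- function(affinity, min_affinity = 0.5) {
  stopifnot(is.matrix(affinity), all(affinity >= 0), all(affinity <= 1))
  rn <- rownames(affinity) %||% paste0("model_", seq_len(nrow(affinity)))
  cn <- colnames(affinity) %||% paste0("data_", seq_len(ncol(affinity)))
  flip <- nrow(affinity) > ncol(affinity)
  A <- if (flip) t(affinity) else affinity
  a <- solve_assignment(A, maximize = TRUE)
  rows <- lapply(seq_along(a), function(i) {
    j <- a[i]
    if (is.na(j) || A[i, j] < min_affinity) return(NULL)
    if (flip) {
      tibble::tibble(model_keypoint = rn[j], dataset_keypoint = cn[i],
                     affinity = A[i, j])
    } else {
      tibble::tibble(model_keypoint = rn[i], dataset_keypoint = cn[j],
                     affinity = A[i, j])
    }
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    warn("no keypoint pair reached min_affinity: empty conversion table")
    out <- tibble::tibble(model_keypoint = character(),
                          dataset_keypoint = character(),
                          affinity = numeric())
  }
  dplyr::arrange(out, .data$model_keypoint)
}

#' Automatic keypoint matching against an annotated dataset
#'
#' Runs zero-shot inference on every image (unless predictions are
#' supplied), matches predictions to ground truth per image, averages the
#' match matrices into an affinity matrix, and derives the final
#' conversion table.
#'
#' @param model A trained `pose_model` (ignored when `predictions` given).
#' @param images Named list of image matrices.
#' @param annotations Local-name annotation tibble (`image_id`,
#'   `keypoint`, `x`, `y`, `flag`); only rows with flag > 0 participate.
#' @param predictions Optional precomputed predictions tibble with an
#'   `image_id` column.
#' @param min_affinity Acceptance threshold for [derive_table()].
#' @param confidence_floor Per-image prediction filter (default 0: the
#'   matching uses all predictions).
#' @return List of class `keypoint_match`: `table` (conversion table),
#'   `affinity`, `n_images`.
#' @export
match_keypoints <- function(model = NULL, images, annotations,
                            predictions = NULL, min_affinity = 0.5,
                            confidence_floor = 0) {
  if (is.null(predictions)) {
    stopifnot(inherits(model, "pose_model"))
    predictions <- predict(model, images)
  }
  ids <- intersect(unique(predictions$image_id),
                   unique(annotations$image_id))
  if (length(ids) == 0) abort("no shared image ids")
  matches <- lapply(ids, function(id) {
    match_image(predictions[predictions$image_id == id, ],
                dplyr::filter(annotations, .data$image_id == id,
                              .data$flag > 0),
                confidence_floor = confidence_floor)
  })
  affinity <- aggregate_matches(matches)
  structure(list(table = derive_table(affinity, min_affinity),
                 affinity = affinity, n_images = length(ids)),
            class = "keypoint_match")
}

#' @export
print.keypoint_match <- function(x, ...) {
  cat(sprintf("<keypoint_match: %d pairs accepted over %d images>\n",
              nrow(x$table), x$n_images))
  print(x$table)
  invisible(x)
}

#' Convert a matching table to a conversion map
#'
#' Serializes the dataset-to-model direction (`local name -> super-set
#' name`) so the matching output feeds [project_annotations()] directly.
#'
#' @param table Table from [derive_table()] / [match_keypoints()].
#' @param dataset_id Dataset identifier for the map entry.
#' @return A [conversion_map()].
#' @export
as_conversion_map <- function(table, dataset_id = "dataset") {
  if (inherits(table, "keypoint_match")) table <- table$table
  m <- setNames(table$model_keypoint, table$dataset_keypoint)
  args <- list(m)
  names(args) <- dataset_id
  do.call(conversion_map, args)
}
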