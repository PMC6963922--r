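split_names <- function() c("calibration", "validation", "prediction")

#' Stratified random split into calibration / validation / prediction
#'
#' @param labels origin codes 0:2.
#' @param counts 3 x 3 matrix (or data.frame) of per-class counts: rows =
#'   classes 0,1,2, columns = calibration, validation, prediction. Row
#'   sums must equal the class totals exactly.
#' @param seed assignment seed (fixed seed gives identical assignment).
#' @return character vector of split names, one per sample.
#' @export
split_samples <- function(labels, counts, seed = 1L) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3L, 3L)))
    hsi_abort("counts must be a 3 x 3 matrix (classes x splits)",
              "hsi_invalid_argument")
  totals <- vapply(0:2, function(cl) sum(labels == cl), integer(1))
  if (!all(rowSums(counts) == totals))
    hsi_abort(sprintf(
      "split counts do not add up: requested row sums (%s) vs class totals (%s)",
      paste(rowSums(counts), collapse = ", "),
      paste(totals, collapse = ", ")), "hsi_arithmetic_error")
  out <- character(length(labels))
  with_seed(seed, {
    for (cl in 0:2) {
      idx <- sample(which(labels == cl))
      asg <- rep(split_names(), times = counts[cl + 1L, ])
      out[idx] <- asg
    }
  })
  out
}

#' Split counts proportional to the study design
#'
#' Allocates each class total across calibration/validation/prediction in
#' the proportions 0.5 / 0.25 / 0.25 (the study's split ratios to within
#' rounding), remainders going to the calibration set.
#'
#' @param totals integer vector of 3 class totals.
#' @param fractions allocation fractions (validation, prediction taken
#'   from positions 2 and 3; calibration absorbs the remainder).
#' @return 3 x 3 integer matrix, rows = classes, cols = splits.
#' @export
proportional_counts <- function(totals, fractions = c(0.5, 0.25, 0.25)) {
  m <- t(vapply(totals, function(n) {
    v <- floor(n * fractions[2:3])
    c(n - sum(v), v)
  }, numeric(3)))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(origin_names(), split_names())
  m
}

#' Confusion matrix (rows = true origin, columns = predicted)
#'
#' @param true integer origin codes 0:2.
#' @param pred a `prediction` or an integer vector.
#' @param split optional split label stored with the matrix.
#' @return a `confusion_matrix` (3 x 3 integer matrix, Gansu/Ningxia/
#'   Xinjiang order, with a `split` attribute).
#' @export
confusion <- function(true, pred, split = NULL) {
  if (inherits(pred, "prediction")) pred <- pred$label
  if (length(true) != length(pred))
    hsi_abort(sprintf("%d true labels vs %d predictions", length(true),
                      length(pred)), "hsi_shape_error")
  if (!all(true %in% 0:2) || !all(pred %in% 0:2))
    hsi_abort("labels must be origin codes 0, 1 or 2", "hsi_label_error")
  m <- matrix(0L, 3L, 3L, dimnames = list(true = 0:2, predicted = 0:2))
  for (k in seq_along(true))
    m[true[k] + 1L, pred[k] + 1L] <- m[true[k] + 1L, pred[k] + 1L] + 1L
  structure(m, split = split, class = c("confusion_matrix", class(m)))
}

#' Classification accuracy of a confusion matrix
#'
#' 100 x (correctly classified / total). Full precision is kept
#' internally; presentation rounds to 2 decimals.
#'
#' @param cm a `confusion_matrix` or any square count matrix.
#' @return accuracy in percent.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) hsi_abort("empty confusion matrix", "hsi_empty_input")
  100 * sum(diag(as.matrix(cm))) / total
}

#' Evaluate one fitted model over the three splits
#'
#' @param predict_fun function(table) returning a `prediction`.
#' @param table a split-assigned `spectrum_table`.
#' @return named list of `confusion_matrix` per split.
#' @export
evaluate_splits <- function(predict_fun, table) {
  out <- lapply(split_names(), function(sp) {
    tb <- table_split(table, sp)
    confusion(tb$label, predict_fun(tb), split = sp)
  })
  names(out) <- split_names()
  out
}

# one block: three count rows then the Total (%) row, with a total
# column per split (layout of the published tables)
format_block <- function(cms) {
  rows <- lapply(0:2, function(r) {
    cells <- unlist(lapply(split_names(), function(sp)
      c(cms[[sp]][r + 1L, ], "")))
    c(as.character(r), cells)
  })
  tot <- c("Total (%)", unlist(lapply(split_names(), function(sp)
    c("", "", "", sprintf("%.2f", round(accuracy(cms[[sp]]), 2))))))
  do.call(rbind, c(rows, list(tot)))
}

#' Write the publication-style report
#'
#' One CSV and one aligned text table per feature set, each holding the
#' 3 x 3 confusion blocks of every model for the calibration, validation
#' and prediction splits plus their Total (%) rows; plus a summary CSV of
#' all accuracy cells.
#'
#' @param results nested list `results[[feature_set]][[model]]` of
#'   per-split confusion matrices (as from [evaluate_splits()]).
#' @param dir output directory (created if missing).
#' @return invisible character vector of files written.
#' @export
report <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  summary_rows <- list()
  for (fs in names(results)) {
    lines <- character(0)
    tab_rows <- list()
    for (mod in names(results[[fs]])) {
      cms <- results[[fs]][[mod]]
      missing <- setdiff(split_names(), names(cms))
      if (length(missing))
        hsi_abort(sprintf("report is missing split(s): %s for %s/%s",
                          paste(missing, collapse = ", "), fs, mod),
                  "hsi_report_error")
      blk <- format_block(cms)
      tab_rows[[mod]] <- cbind(Model = c(toupper(mod), rep("", 3)), blk)
      lines <- c(lines, sprintf("== %s / %s ==", fs, toupper(mod)),
                 utils::capture.output(print(lapply(cms, unclass))), "")
      for (sp in split_names())
        summary_rows[[length(summary_rows) + 1L]] <- data.frame(
          feature_set = fs, model = mod, split = sp,
          accuracy = round(accuracy(cms[[sp]]), 2))
    }
    tab <- do.call(rbind, tab_rows)
    colnames(tab) <- c("Model", "Category",
                       paste0("cal_", 0:2), "cal_total",
                       paste0("val_", 0:2), "val_total",
                       paste0("pred_", 0:2), "pred_total")
    csv <- file.path(dir, sprintf("confusion_%s.csv", fs))
    write.csv(as.data.frame(tab), csv, row.names = FALSE)
    txt <- file.path(dir, sprintf("confusion_%s.txt", fs))
    writeLines(lines, txt)
    files <- c(files, csv, txt)
  }
  summary_csv <- file.path(dir, "accuracy_summary.csv")
  write.csv(do.call(rbind, summary_rows), summary_csv, row.names = FALSE)
  invisible(c(files, summary_csv))
}
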