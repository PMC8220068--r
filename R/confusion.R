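# Split a reported-labels cell ("Chasing;Fighting") into its labels.
.split_labels <- function(x) strsplit(as.character(x), ";", fixed = TRUE)

#' Validate a label-response table
#'
#' Rows are (subject, block, true_class, reported) where `reported`
#' holds one to three labels separated by `";"` — observers may assign
#' up to three labels per video. Block indices must be contiguous
#' from 1.
#'
#' @param responses data.frame with columns `subject`, `block`,
#'   `true_class`, `reported`.
#' @return `responses`, invisibly; stops on violation.
#' @export
validate_label_responses <- function(responses) {
  .check_response_rows(responses)
  blocks <- sort(unique(responses$block))
  if (!identical(as.integer(blocks), seq_along(blocks)))
    stop("block indices must be contiguous from 1")
  invisible(responses)
}

# Column/label-count checks alone; applies to any subset of a table.
.check_response_rows <- function(responses) {
  need <- c("subject", "block", "true_class", "reported")
  missing <- setdiff(need, names(responses))
  if (length(missing))
    stop("response table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(responses)) {
    counts <- lengths(.split_labels(responses$reported))
    if (any(counts < 1L | counts > 3L))
      stop("each trial must report between 1 and 3 labels")
  }
  invisible(responses)
}

#' Build a confusion matrix from labeling responses
#'
#' Entry `m[i, j]` counts how often label `j` was reported for a trial
#' of true class `i`. A multi-label trial contributes one count per
#' reported label.
#'
#' @param responses a label-response table (see
#'   [validate_label_responses()]).
#' @param labels ordered class names defining rows and columns.
#' @return An integer matrix with `dimnames = list(true, reported)`, of
#'   class `confusion_matrix`.
#' @export
build_confusion <- function(responses, labels) {
  .check_response_rows(responses)
  m <- matrix(0L, length(labels), length(labels),
              dimnames = list(true = labels, reported = labels))
  if (nrow(responses) == 0L) return(structure(m, class = c("confusion_matrix", "matrix")))
  rep_list <- .split_labels(responses$reported)
  truth <- rep(as.character(responses$true_class), lengths(rep_list))
  reported <- unlist(rep_list, use.names = FALSE)
  bad <- setdiff(unique(c(truth, reported)), labels)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  tab <- table(factor(truth, levels = labels),
               factor(reported, levels = labels))
  m[] <- as.integer(tab)
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Per-class recall, precision and F1 from a confusion matrix
#'
#' `recall_i = m_ii / sum_j m_ij` (fraction of class-`i` videos
#' correctly classified), `precision_j = m_jj / sum_i m_ij` (fraction of
#' `j` reports that were correct), `F1 = 2 P R / (P + R)`.
#' Zero-denominator cases are reported as `NA` (undefined), never as 0.
#'
#' @param M a square confusion matrix with class dimnames.
#' @return A data.frame with columns `class`, `recall`, `precision`,
#'   `f1`.
#' @export
classification_metrics <- function(M) {
  M <- unclass(M)
  if (nrow(M) != ncol(M)) stop("confusion matrix must be square")
  diagM <- diag(M)
  rs <- rowSums(M)
  cs <- colSums(M)
  recall <- ifelse(rs > 0, diagM / rs, NA_real_)
  precision <- ifelse(cs > 0, diagM / cs, NA_real_)
  denom <- precision + recall
  f1 <- ifelse(!is.na(denom) & denom > 0,
               2 * precision * recall / denom, NA_real_)
  data.frame(class = rownames(M) %||% as.character(seq_len(nrow(M))),
             recall = recall, precision = precision, f1 = f1,
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise mislabeling probability
#'
#' For each unordered class pair,
#' `P_MS(i, j) = (m_ij + m_ji) / total off-diagonal count`: the fraction
#' of all labeling errors attributable to confusing `i` with `j`.
#' Entries sum to 1 over unordered pairs.
#'
#' @param M a square confusion matrix with at least one off-diagonal
#'   count.
#' @return A symmetric matrix with zero diagonal, class
#'   `mislabeling_matrix`.
#' @export
mislabeling_probability <- function(M) {
  M <- unclass(M)
  if (nrow(M) != ncol(M)) stop("confusion matrix must be square")
  off <- M
  diag(off) <- 0
  total <- sum(off)
  if (total == 0)
    stop("mislabeling probability undefined: no off-diagonal counts")
  P <- (off + t(off)) / total
  structure(P, class = c("mislabeling_matrix", "matrix"))
}

#' Block-wise learning trend in classification performance
#'
#' Per block, recall/precision/F1 are computed from each subject's
#' block confusion matrix, averaged across classes (undefined cells
#' dropped) and then across subjects; an ordinary least-squares line of
#' each block-mean metric on block index tests for latent learning.
#' The t statistic carries `n_blocks - 2` degrees of freedom.
#'
#' @param responses a label-response table covering at least 3 blocks.
#' @param labels class names; defaults to those present.
#' @return A data.frame with one row per metric: `metric`, `slope`,
#'   `t`, `df`, `p`, plus attribute `block_means` (block x metric).
#' @export
blockwise_learning_fit <- function(responses, labels = NULL) {
  validate_label_responses(responses)
  if (is.null(labels))
    labels <- sort(unique(as.character(responses$true_class)))
  blocks <- sort(unique(responses$block))
  if (length(blocks) < 3L)
    stop("insufficient data: need >= 3 blocks, got ", length(blocks))
  subject_block_means <- function(b) {
    sub <- responses[responses$block == b, ]
    per_subject <- lapply(split(sub, sub$subject), function(srows) {
      met <- classification_metrics(build_confusion(srows, labels))
      c(recall = mean(met$recall, na.rm = TRUE),
        precision = mean(met$precision, na.rm = TRUE),
        f1 = mean(met$f1, na.rm = TRUE))
    })
    colMeans(do.call(rbind, per_subject), na.rm = TRUE)
  }
  bm <- t(vapply(blocks, subject_block_means, numeric(3)))
  rownames(bm) <- blocks
  fits <- lapply(colnames(bm), function(metric) {
    fit <- stats::lm(bm[, metric] ~ blocks)
    co <- summary(fit)$coefficients
    if (nrow(co) < 2L || is.na(co["blocks", "Estimate"]))
      return(data.frame(metric = metric, slope = 0, t = NA_real_,
                        df = length(blocks) - 2L, p = NA_real_))
    data.frame(metric = metric,
               slope = co["blocks", "Estimate"],
               t = co["blocks", "t value"],
               df = length(blocks) - 2L,
               p = co["blocks", "Pr(>|t|)"])
  })
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  attr(out, "block_means") <- bm
  out
}
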