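## Split protocol and per-class evaluation.

#' Subject-level train/validation/test split
#'
#' Partitions subjects (never windows) into three splits at the given
#' ratios, so no subject contributes windows to two splits. Subjects are
#' ordered by their dominant class before interleaved assignment, which
#' stratifies the subject-level class mix across splits; the assignment
#' is then deterministic in the seed.
#'
#' @param fw a \linkS4class{FeatureWindows}
#' @param ratios numeric(3) summing to 1 (default 7:2:1)
#' @param seed integer seed
#' @return list(train, validation, test) of
#'   \linkS4class{FeatureWindows}
#' @export
splitDataset <- function(fw, ratios = c(0.7, 0.2, 0.1), seed = 1) {
  stopifnot(is(fw, "FeatureWindows"))
  .stopIfNot(abs(sum(ratios) - 1) < 1e-9, "ratios must sum to 1")
  subj <- unique(fw@subject)
  .stopIfNot(length(subj) >= 3,
             "need >= 3 subjects for a subject-level split")
  .withSeed(seed, {
    ## dominant class per subject, for stratified interleaving
    dom <- vapply(subj, function(s) {
      tb <- table(fw@labels[fw@subject == s])
      names(tb)[which.max(tb)]
    }, "")
    subj <- subj[order(dom, runif(length(subj)))]
    ns <- length(subj)
    nTr <- max(1L, round(ratios[1] * ns))
    nVa <- max(1L, round(ratios[2] * ns))
    if (nTr + nVa >= ns) { nTr <- ns - 2L; nVa <- 1L }
    ## count-preserving random assignment over the stratified order
    assign <- c(rep(1L, nTr), rep(2L, nVa), rep(3L, ns - nTr - nVa))
    assign <- assign[sample(ns)]
    groups <- split(subj, assign)
    list(train = subsetWindows(fw, fw@subject %in% groups[["1"]]),
         validation = subsetWindows(fw, fw@subject %in% groups[["2"]]),
         test = subsetWindows(fw, fw@subject %in% groups[["3"]]))
  })
}

#' Per-class evaluation report
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), F1 their harmonic mean,
#' per class (percent); overall accuracy; full confusion matrix
#' (rows = truth). Classes absent from the truth get \code{NA} metrics
#' rather than 0.
#'
#' @param predictions factor (or character) predictions
#' @param truth factor (or character) ground truth, same length
#' @return an \linkS4class{EvalReport}
#' @examples
#' r <- evaluateClassifier(c("A","B","B","B"), c("A","A","B","B"))
#' perClassMetrics(r)
#' @export
evaluateClassifier <- function(predictions, truth) {
  .stopIfNot(length(predictions) == length(truth),
             "predictions and truth must have equal length")
  lev <- union(levels(factor(truth)), levels(factor(predictions)))
  pr <- factor(as.character(predictions), levels = lev)
  tr <- factor(as.character(truth), levels = lev)
  cm <- table(truth = tr, predicted = pr)
  cm <- matrix(as.integer(cm), nrow(cm), ncol(cm),
               dimnames = dimnames(cm))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  support <- rowSums(cm)
  prec <- ifelse(tp + fp > 0, 100 * tp / (tp + fp), NA_real_)
  rec <- ifelse(support > 0, 100 * tp / (tp + fn), NA_real_)
  prec[support == 0] <- NA_real_       # class absent from truth
  f1 <- ifelse(!is.na(prec) & !is.na(rec) & (prec + rec) > 0,
               2 * prec * rec / (prec + rec), NA_real_)
  acc <- 100 * sum(tp) / sum(cm)
  new("EvalReport",
      perClass = data.frame(class = lev, precision = prec, recall = rec,
                            f1 = f1, support = support,
                            row.names = NULL),
      accuracy = acc, confusion = cm)
}

#' Macro F1 of an evaluation report
#'
#' @param report an \linkS4class{EvalReport}
#' @return mean per-class F1 (percent), ignoring undefined classes
#' @export
macroF1 <- function(report) {
  mean(perClassMetrics(report)$f1, na.rm = TRUE)
}

#' Subject-level k-fold cross-validation over a configuration grid
#'
#' Subjects are partitioned into k folds; each grid entry is trained on
#' k-1 folds and scored by macro F1 on the held-out fold; the
#' configuration with the best mean validation F1 wins. The full fold
#' log is retained.
#'
#' @param fw training+validation \linkS4class{FeatureWindows}
#' @param grid list of \code{\link{harConfig}} lists
#' @param k folds (>= 2)
#' @param seed integer seed
#' @param epochs,lr training settings per fold
#' @return list(best = winning config, scores = mean F1 per config,
#'   folds = data.frame log)
#' @export
crossValidate <- function(fw, grid, k = 5, seed = 1, epochs = 25,
                          lr = 0.02) {
  .stopIfNot(length(grid) >= 1, "configuration grid must be non-empty")
  .stopIfNot(k >= 2, "need k >= 2 folds")
  subj <- unique(fw@subject)
  .stopIfNot(length(subj) >= k, "need at least k subjects")
  .withSeed(seed, {
    fold <- sample(rep(seq_len(k), length.out = length(subj)))
    names(fold) <- subj
    logRows <- list()
    scores <- numeric(length(grid))
    for (gi in seq_along(grid)) {
      f1s <- numeric(k)
      for (f in seq_len(k)) {
        hold <- subj[fold == f]
        trFw <- subsetWindows(fw, !(fw@subject %in% hold))
        vaFw <- subsetWindows(fw, fw@subject %in% hold)
        mdl <- trainHarModel(trFw, config = grid[[gi]],
                             epochs = epochs, lr = lr)
        pred <- classifyWindows(mdl, vaFw)$predictions
        f1s[f] <- macroF1(evaluateClassifier(pred, windowLabels(vaFw)))
        logRows[[length(logRows) + 1L]] <-
          data.frame(config = gi, fold = f, macro_f1 = f1s[f])
      }
      scores[gi] <- mean(f1s)
    }
    list(best = grid[[which.max(scores)]], scores = scores,
         folds = do.call(rbind, logRows))
  })
}
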