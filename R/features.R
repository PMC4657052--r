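# Nearest-residue distance features and the random-forest training /
# recursive-feature-elimination protocol for oxidation-site prediction.

FEATURE_NAMES <- c(paste0("NT_", AA20), paste0("CT_", AA20))

#' Nearest-residue distance features for one methionine
#'
#' For each of the 20 amino acids X, `NT_X` is the number of residues from
#' the focal methionine to the closest X towards the N-terminus and `CT_X`
#' the analogue towards the C-terminus. When no X exists in a direction the
#' protein length is used as the default value.
#'
#' @param seq Amino-acid string (or a one-row protein record).
#' @param pos 1-based position of the methionine.
#' @return Named numeric vector of the 40 features (`NT_A` .. `CT_Y`).
#' @export
distance_features <- function(seq, pos) {
  if (!is.character(seq)) seq <- seq$seq[1]
  ch <- seq_chars(seq)
  L <- length(ch)
  if (pos < 1 || pos > L) stop_metox("position out of range: ", pos)
  if (ch[pos] != "M") {
    stop_metox("residue at position ", pos, " is ", ch[pos], ", not M")
  }
  out <- rep(as.numeric(L), 40)
  names(out) <- FEATURE_NAMES
  if (pos > 1) {
    before <- ch[seq_len(pos - 1)]
    last <- tapply(seq_len(pos - 1), before, max)
    hit <- names(last) %in% AA20
    out[paste0("NT_", names(last)[hit])] <- pos - last[hit]
  }
  if (pos < L) {
    after_idx <- (pos + 1):L
    first <- tapply(after_idx, ch[after_idx], min)
    hit <- names(first) %in% AA20
    out[paste0("CT_", names(first)[hit])] <- first[hit] - pos
  }
  out
}

#' Assemble a labelled feature table for methionine sites
#'
#' One row per distinct (protein, position) methionine with a known
#' oxidation label; duplicated sites are collapsed to one row.
#'
#' @param sites Data frame with `protein_id`, `pos`, `oxidized`.
#' @param proteins Protein set data frame or named lookup vector.
#' @return Data frame with `protein_id`, `pos`, the 40 feature columns and
#'   a factor `label` with levels `oxidized`, `resistant` (oxidized is the
#'   positive class). Attribute `class_counts` holds the per-class totals.
#' @export
assemble_benchmark <- function(sites, proteins) {
  lookup <- as_seq_lookup(proteins)
  sites <- sites[!duplicated(paste(sites$protein_id, sites$pos)), ,
                 drop = FALSE]
  feats <- t(vapply(seq_len(nrow(sites)), function(i) {
    distance_features(lookup[[sites$protein_id[i]]], sites$pos[i])
  }, numeric(40)))
  out <- data.frame(protein_id = sites$protein_id, pos = sites$pos,
                    feats, stringsAsFactors = FALSE)
  out$label <- factor(ifelse(sites$oxidized, "oxidized", "resistant"),
                      levels = c("oxidized", "resistant"))
  attr(out, "class_counts") <- table(out$label)
  out
}

feature_columns <- function(table) intersect(FEATURE_NAMES, names(table))

rf_holdout_metrics <- function(model, data, features) {
  prob <- predict(model, data[, features, drop = FALSE], type = "prob")
  pred <- factor(ifelse(prob[, "oxidized"] >= 0.5, "oxidized", "resistant"),
                 levels = levels(data$label))
  cm <- table(pred = pred, obs = data$label)
  roc <- pROC::roc(response = data$label, predictor = prob[, "oxidized"],
                   levels = c("resistant", "oxidized"), direction = "<",
                   quiet = TRUE)
  list(auc = as.numeric(pROC::auc(roc)),
       accuracy = sum(diag(cm)) / sum(cm),
       sensitivity = cm["oxidized", "oxidized"] /
         sum(cm[, "oxidized"]),
       specificity = cm["resistant", "resistant"] /
         sum(cm[, "resistant"]))
}

#' Train a random-forest oxidation-site classifier
#'
#' Stratified 75/25 train/test split; repeated k-fold cross-validation on
#' the training part (10-fold, 5 repeats at study scale, i.e. 50
#' resamplings) scoring AUC/accuracy/sensitivity/specificity with
#' `oxidized` as the positive class; a final forest refit on the full
#' training part is evaluated on the held-out test part. The forest uses
#' 1000 trees and 6 candidate predictors per split (the truncated square
#' root of 40) by default.
#'
#' @param table Feature table from [assemble_benchmark()].
#' @param seed Integer seed controlling the split, CV folds and forests.
#' @param split Training fraction (default 0.75).
#' @param features Character vector of feature columns to use (default all
#'   40 present in `table`).
#' @param ntree,mtry Forest size and candidate predictors per split.
#' @param folds,repeats Cross-validation design on the training part.
#' @return A `classifier_report`: list with `cv` (mean CV metrics), `test`
#'   (held-out metrics), `oob` (out-of-bag error of the final forest, a
#'   secondary diagnostic), `selected_features`, `n_train`, `n_test` and
#'   the fitted `model`.
#' @export
train_rf <- function(table, seed, split = 0.75, features = NULL,
                     ntree = 1000, mtry = 6, folds = 10, repeats = 5) {
  features <- features %||% feature_columns(table)
  if (length(features) == 0) stop_metox("no feature columns in table")
  if (nlevels(droplevels(table$label)) < 2) {
    stop_metox("both classes must be present to train")
  }
  mtry <- min(mtry, length(features))
  with_seed(seed, {
    idx_train <- unlist(lapply(levels(table$label), function(lv) {
      i <- which(table$label == lv)
      sample(i, round(length(i) * split))
    }))
    train <- table[sort(idx_train), , drop = FALSE]
    test <- table[-sort(idx_train), , drop = FALSE]
    ctrl <- caret::trainControl(
      method = "repeatedcv", number = folds, repeats = repeats,
      classProbs = TRUE, summaryFunction = caret::twoClassSummary,
      savePredictions = "final")
    cvfit <- caret::train(
      x = train[, features, drop = FALSE], y = train$label,
      method = "rf", metric = "ROC", ntree = ntree,
      tuneGrid = data.frame(mtry = mtry), trControl = ctrl)
    res <- cvfit$results
    cv <- list(auc = res$ROC[1],
               sensitivity = res$Sens[1],
               specificity = res$Spec[1])
    # CV accuracy from the saved fold predictions
    pr <- cvfit$pred
    cv$accuracy <- mean(pr$pred == pr$obs)
    final <- randomForest::randomForest(
      x = train[, features, drop = FALSE], y = train$label,
      ntree = ntree, mtry = mtry)
    structure(list(
      cv = cv,
      test = rf_holdout_metrics(final, test, features),
      oob = list(error = as.numeric(final$err.rate[ntree, "OOB"])),
      selected_features = features,
      n_train = nrow(train), n_test = nrow(test),
      model = final), class = "classifier_report")
  })
}

#' Recursive feature elimination over the 40 distance features
#'
#' Backward elimination scored by cross-validated AUC: candidate subset
#' sizes are evaluated with a random-forest ranking at each step, and the
#' smallest subset achieving the best AUC is selected (ties broken towards
#' fewer features).
#'
#' @param table Feature table from [assemble_benchmark()].
#' @param seed Integer seed.
#' @param sizes Subset sizes to evaluate (default `1:40` clipped to the
#'   number of available features).
#' @param folds Number of CV folds used to score each size.
#' @param ntree Trees per forest during elimination.
#' @return List with `selected` (character vector of retained features),
#'   `curve` (data frame `size`, `auc`) and `best_size`.
#' @export
rfe_select <- function(table, seed, sizes = NULL, folds = 5, ntree = 500) {
  features <- feature_columns(table)
  if (nlevels(droplevels(table$label)) < 2) {
    stop_metox("both classes must be present to train")
  }
  p <- length(features)
  sizes <- sort(unique(pmin(sizes %||% seq_len(p), p)))
  sizes <- sizes[sizes >= 1]
  with_seed(seed, {
    funcs <- caret::rfFuncs
    funcs$summary <- caret::twoClassSummary
    ctrl <- caret::rfeControl(functions = funcs, method = "cv",
                              number = folds, verbose = FALSE)
    fit <- caret::rfe(x = table[, features, drop = FALSE], y = table$label,
                      sizes = setdiff(sizes, p), metric = "ROC",
                      rfeControl = ctrl, ntree = ntree)
    curve <- data.frame(size = fit$results$Variables,
                        auc = fit$results$ROC)
    best_size <- min(curve$size[curve$auc >= max(curve$auc) - 1e-12])
    selected <- if (best_size == fit$optsize) fit$optVariables
    else {
      ranked <- fit$variables
      ranked <- ranked[ranked$Variables == best_size, , drop = FALSE]
      agg <- aggregate(list(rank = ranked$Overall), list(var = ranked$var),
                       mean)
      as.character(agg$var[order(-agg$rank)][seq_len(best_size)])
    }
    list(selected = selected, curve = curve, best_size = best_size)
  })
}
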