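# The rule classifier "S-aromatic motif implies low reactivity" and its
# benchmark machinery: per-protein median splits of empirical
# reactivities, confusion matrices and oxidation-by-motif contingency
# tables.

#' Confusion matrix for the reactivity rule
#'
#' Positive class is low reactivity: TP = observed low and motif-forming,
#' TN = observed high and motif-free, FP = observed high but motif-forming,
#' FN = observed low but motif-free.
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return A `confusion_matrix` object.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_metox("confusion counts must be non-negative integers")
  }
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 positive = "low reactivity"),
            class = "confusion_matrix")
}

#' Accuracy, sensitivity and specificity of a confusion matrix
#'
#' `accuracy = (TP+TN)/N`, `sensitivity = TP/(TP+FN)`,
#' `specificity = TN/(TN+FP)`, with low reactivity as the positive class.
#'
#' @param cm A `confusion_matrix`.
#' @return List with `accuracy`, `sensitivity`, `specificity`, `total`.
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  list(accuracy = (cm$tp + cm$tn) / total,
       sensitivity = cm$tp / (cm$tp + cm$fn),
       specificity = cm$tn / (cm$tn + cm$fp),
       total = total)
}

#' Predict methionine reactivity from motif status
#'
#' The headline rule: a methionine involved in an S-aromatic motif (SD
#' within 7 Angstrom of an aromatic ring centroid) is predicted to have low
#' reactivity towards oxidants; every other methionine is predicted high.
#'
#' @param calls A `motif_calls` object computed at the 7 Angstrom cutoff.
#' @return Data frame `chain`, `resno`, `predicted` (`"low"`/`"high"`).
#' @export
predict_reactivity <- function(calls) {
  stopifnot(inherits(calls, "motif_calls"))
  data.frame(chain = calls$calls$chain, resno = calls$calls$resno,
             predicted = ifelse(calls$calls$forms_motif, "low", "high"),
             stringsAsFactors = FALSE)
}

#' Median-split empirical reactivities into low/high classes
#'
#' Reactivities below the per-protein median are low, above it high.
#' Values equal to the median join the group whose already-assigned member
#' is closest in reactivity to the median; if one group is empty the tied
#' values go there (keeping both groups populated), and an exact tie goes
#' to the low group.
#'
#' @param reactivities Named numeric vector of empirical reactivities (one
#'   protein's methionines; at least two, not all equal).
#' @return Named character vector of `"low"`/`"high"` labels.
#' @export
median_split_labels <- function(reactivities) {
  if (length(reactivities) < 2) {
    stop_metox("median split needs at least two methionines")
  }
  if (length(unique(reactivities)) < 2) {
    stop_metox("median split needs at least two distinct reactivities")
  }
  med <- median(reactivities)
  lab <- ifelse(reactivities < med, "low",
                ifelse(reactivities > med, "high", NA))
  if (anyNA(lab)) {
    low_vals <- reactivities[which(lab == "low")]
    high_vals <- reactivities[which(lab == "high")]
    tie_to <- if (length(low_vals) == 0) "low"
    else if (length(high_vals) == 0) "high"
    else {
      d_low <- min(abs(low_vals - med))
      d_high <- min(abs(high_vals - med))
      if (d_low <= d_high) "low" else "high"
    }
    lab[is.na(lab)] <- tie_to
  }
  stats::setNames(lab, names(reactivities))
}

#' Benchmark confusion matrix from reactivity records and motif calls
#'
#' Translates each record's sequence position to structure numbering
#' through a residue map, looks up its motif status and tallies the
#' confusion counts of the S-aromatic rule (positive class = low
#' reactivity). Records that cannot be mapped, or whose methionine has no
#' motif call (unresolved in the structure), raise an error naming them.
#'
#' @param records Data frame with `met_pos` and `reactivity_class`
#'   (`"low"`/`"high"`), as from [load_table2_fixture()] (one protein).
#' @param calls A `motif_calls` object for the protein's structure.
#' @param map A `residue_map` from [map_sequence_to_structure()], or
#'   `NULL` when author numbering equals sequence numbering.
#' @return A `confusion_matrix`.
#' @export
benchmark_confusion <- function(records, calls, map = NULL) {
  stopifnot(inherits(calls, "motif_calls"))
  if (nrow(records) == 0) return(confusion_matrix(0, 0, 0, 0))
  if (!is.null(map)) {
    idx <- match(records$met_pos, map$seq_pos)
    if (anyNA(idx)) {
      stop_metox("unmapped benchmark position(s): ",
                 paste(records$met_pos[is.na(idx)], collapse = ", "))
    }
    chain <- map$chain[idx]; resno <- map$resno[idx]
  } else {
    chain <- rep(calls$calls$chain[1], nrow(records))
    resno <- records$met_pos
  }
  j <- match(paste(chain, resno),
             paste(calls$calls$chain, calls$calls$resno))
  if (anyNA(j)) {
    stop_metox("no motif call for benchmark methionine(s) at: ",
               paste(records$met_pos[is.na(j)], collapse = ", "))
  }
  motif <- calls$calls$forms_motif[j]
  low <- records$reactivity_class == "low"
  confusion_matrix(tp = sum(low & motif), tn = sum(!low & !motif),
                   fp = sum(!low & motif), fn = sum(low & !motif))
}

#' Sum confusion matrices
#'
#' @param cms List of `confusion_matrix` objects (e.g. one per protein).
#' @return Their element-wise sum as a `confusion_matrix`.
#' @export
sum_confusion <- function(cms) {
  confusion_matrix(tp = sum(vapply(cms, `[[`, numeric(1), "tp")),
                   tn = sum(vapply(cms, `[[`, numeric(1), "tn")),
                   fp = sum(vapply(cms, `[[`, numeric(1), "fp")),
                   fn = sum(vapply(cms, `[[`, numeric(1), "fn")))
}

#' Pooled confusion matrix of the packaged therapeutic benchmark
#'
#' Sums the packaged per-protein confusion counts of the S-aromatic rule
#' over the 8 therapeutic proteins (35 methionines), yielding the pooled
#' 2x2 confusion matrix without requiring the structures.
#'
#' @return A `confusion_matrix`.
#' @export
table2_confusion <- function() {
  rows <- load_table2_confusion_fixture()
  sum_confusion(lapply(seq_len(nrow(rows)), function(i) {
    confusion_matrix(rows$tp[i], rows$tn[i], rows$fp[i], rows$fn[i])
  }))
}

#' Oxidation-by-motif contingency table
#'
#' Cross-tabulates in-vivo oxidation labels against S-aromatic motif
#' status: cell `a` = oxidized and motif-forming, `b` = oxidized without
#' motif, `c` = not oxidized with motif, `d` = neither. Feed the result to
#' [fisher_exact()] to test whether motif-forming methionines are
#' depleted among oxidation-prone ones.
#'
#' @param oxidized Data frame with `chain`, `resno`, `oxidized` (logical),
#'   in structure numbering.
#' @param calls A `motif_calls` object.
#' @return A `contingency_2x2`. Methionines present in only one of the two
#'   inputs are dropped with a warning.
#' @export
oxidation_contingency <- function(oxidized, calls) {
  stopifnot(inherits(calls, "motif_calls"))
  df <- calls$calls
  ox <- oxidized$oxidized[match(paste(df$chain, df$resno),
                                paste(oxidized$chain, oxidized$resno))]
  if (anyNA(ox)) {
    warning(sum(is.na(ox)), " methionine(s) without oxidation label ",
            "dropped", call. = FALSE)
  }
  keep <- !is.na(ox)
  contingency_2x2(
    a = sum(ox[keep] & df$forms_motif[keep]),
    b = sum(ox[keep] & !df$forms_motif[keep]),
    c = sum(!ox[keep] & df$forms_motif[keep]),
    d = sum(!ox[keep] & !df$forms_motif[keep]),
    row_labels = c("oxidized", "not oxidized"),
    col_labels = c("motif", "no motif"))
}
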