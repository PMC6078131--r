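# Independent brute-force oracles. These deliberately use naive loops and
# first-principles definitions so they share no code with the package
# implementations they check.

oracle_collapse <- function(spots) {
  arrays <- sort(unique(spots$array_id))
  antigens <- sort(unique(spots$antigen_id))
  m <- matrix(NA_real_, length(arrays), length(antigens),
              dimnames = list(arrays, antigens))
  for (a in arrays) {
    for (g in antigens) {
      v <- spots$rfu[spots$array_id == a & spots$antigen_id == g]
      if (length(v) > 0) m[a, g] <- median(v)
    }
  }
  m
}

oracle_biomarker_scores <- function(intensity, cutoffs, labels) {
  out <- NULL
  for (g in colnames(intensity)) {
    cut <- cutoffs$cutoff[cutoffs$antigen_id == g]
    row <- list(antigen_id = g)
    for (coh in c("patient", "control")) {
      v <- intensity[labels == coh, g]
      pos <- v > cut
      sc <- if (any(pos)) mean(v[pos] / cut) else 0
      row[[paste0("n_pos_", coh)]] <- sum(pos)
      row[[paste0("score_", coh)]] <- sum(pos) * sc^(1 / 3)
    }
    row$score_diff <- row$score_patient - row$score_control
    out <- rbind(out, as.data.frame(row))
  }
  out$sensitivity <- out$n_pos_patient / sum(labels == "patient")
  out$specificity <- 1 - out$n_pos_control / sum(labels == "control")
  out
}

oracle_aggregate <- function(runs) {
  tally <- list()
  for (r in runs) {
    for (i in seq_len(nrow(r$top))) {
      id <- r$top$antigen_id[i]
      tally[[id]] <- c(tally[[id]], r$top$rank_score[i])
    }
  }
  out <- data.frame(
    antigen_id = names(tally),
    inclusion_proportion = vapply(tally, length, numeric(1)) / length(runs),
    average_rank_score = vapply(tally, mean, numeric(1)),
    stringsAsFactors = FALSE
  )
  out$weighted_mean_rank <- out$inclusion_proportion * out$average_rank_score
  out <- out[order(-out$weighted_mean_rank, out$antigen_id), ]
  rownames(out) <- NULL
  out
}

oracle_auc <- function(scores, is_patient) {
  sp <- scores[is_patient]
  sc <- scores[!is_patient]
  tot <- 0
  for (a in sp) {
    for (b in sc) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(sp) * length(sc))
}

oracle_any_positive_metrics <- function(positive, panel, labels) {
  tp <- fn <- tn <- fp <- 0
  for (i in seq_len(nrow(positive))) {
    hit <- FALSE
    for (g in panel) {
      if (positive[i, g]) hit <- TRUE
    }
    if (labels[i] == "patient") {
      if (hit) tp <- tp + 1 else fn <- fn + 1
    } else {
      if (hit) fp <- fp + 1 else tn <- tn + 1
    }
  }
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}
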