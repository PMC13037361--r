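# Independent brute-force oracles used to cross-check the implementation.

HOURS <- sprintf("h%02d", 0:23)

# Pairwise-enumeration AUC with half credit for ties.
oracle_auc <- function(true, scores) {
  pos <- scores[true == 1]
  neg <- scores[true == 0]
  s <- 0
  for (p in pos) {
    for (q in neg) {
      s <- s + (p > q) + 0.5 * (p == q)
    }
  }
  s / (length(pos) * length(neg))
}

# Large-sample AUC through the base-R Wilcoxon statistic (independent of
# the package's rank formula); ties handled by midranks as in the
# Mann-Whitney convention.
oracle_rank_auc <- function(true, scores) {
  w <- suppressWarnings(stats::wilcox.test(scores[true == 1],
                                           scores[true == 0],
                                           exact = FALSE))
  unname(w$statistic) / (sum(true == 1) * sum(true == 0))
}

# Direct confusion counting and derived metrics.
oracle_confusion <- function(true, pred) {
  m <- matrix(0L, 2, 2)
  for (i in seq_along(true)) {
    m[true[i] + 1L, pred[i] + 1L] <- m[true[i] + 1L, pred[i] + 1L] + 1L
  }
  m
}

oracle_accuracy <- function(true, pred) mean(true == pred)

oracle_recall <- function(true, pred, cls) {
  sum(true == cls & pred == cls) / sum(true == cls)
}

oracle_f1 <- function(true, pred, cls) {
  tp <- sum(true == cls & pred == cls)
  fp <- sum(true != cls & pred == cls)
  fn <- sum(true == cls & pred != cls)
  if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
}

# Independent per-rule eligibility filter (each rule evaluated on the full
# input, precedence applied afterwards).
oracle_filter <- function(records, anomaly_max = 1000, bmi_min = 29) {
  h <- as.matrix(records[, HOURS])
  r_missing <- apply(h, 1, function(v) any(!is.finite(v)))
  r_anom <- apply(h, 1, function(v) any(is.finite(v) & v > anomaly_max))
  r_bmi <- !is.finite(records$bmi) | records$bmi < bmi_min
  reason <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(records))) {
    if (r_missing[i]) reason[i] <- "missing_hourly"
    else if (r_anom[i]) reason[i] <- "anomalous_reading"
    else if (r_bmi[i]) reason[i] <- "low_bmi"
  }
  list(kept_ids = records$id[is.na(reason)], reason = reason)
}

# Hand-built participant records with controllable disease structure.
make_records <- function(offsets, n_healthy = 0, bmi = 32, hour_value = 30) {
  n <- length(offsets) + n_healthy
  prof <- matrix(hour_value, n, 24, dimnames = list(NULL, HOURS))
  is_case <- c(rep(TRUE, length(offsets)), rep(FALSE, n_healthy))
  data.frame(
    id = sprintf("R%04d", seq_len(n)),
    prof,
    month = rep_len(1:12, n),
    sex = factor(rep_len(c("female", "male"), n),
                 levels = c("female", "male")),
    age = seq(60, 70, length.out = n),
    weight = rep(80, n),
    bmi = rep(bmi, n),
    icd10 = ifelse(is_case, "M17.1", ""),
    diagnosis_offset_years = c(offsets, rep(NA_real_, n_healthy)),
    stringsAsFactors = FALSE
  )
}
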