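# Independent brute-force oracles used to validate the implementation.
# These are deliberately written as plain loops / direct formulas with no
# shared code path with the package.

oracle_confusion <- function(labels, calls) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(labels)) {
    if (labels[i] == 1 && calls[i] == 1) tp <- tp + 1L
    else if (labels[i] == 0 && calls[i] == 1) fp <- fp + 1L
    else if (labels[i] == 0 && calls[i] == 0) tn <- tn + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

oracle_mcc <- function(tp, fp, tn, fn) {
  d <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (d == 0) return(0)
  (tp * tn - fp * fn) / d
}

# Pairwise concordance count, ties one half.
oracle_roc_auc <- function(labels, scores) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# PR AUC by explicit evaluation at every distinct cutpoint.
oracle_pr_auc <- function(labels, scores) {
  cuts <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0
  area <- 0
  n_pos <- sum(labels == 1)
  for (c in cuts) {
    called <- scores >= c
    tp <- sum(called & labels == 1)
    p <- tp / sum(called)
    r <- tp / n_pos
    area <- area + (r - prev_r) * p
    prev_r <- r
  }
  area
}

# Brute-force pairwise shared-kmer identity (fraction of shorter sequence's
# distinct k-mers present in the other's set).
oracle_kmer_identity <- function(s1, s2, k = 5) {
  km <- function(s) {
    if (nchar(s) < k) return(character(0))
    unique(vapply(seq_len(nchar(s) - k + 1),
                  function(i) substr(s, i, i + k - 1), character(1)))
  }
  a <- km(s1); b <- km(s2)
  if (length(a) == 0 || length(b) == 0) return(0)
  length(intersect(a, b)) / min(length(a), length(b))
}

# Independent regex-based .clstr parse: returns data.frame(id, cluster, rep).
oracle_parse_clstr <- function(lines) {
  cluster <- -1L
  out <- data.frame(id = character(), cluster = integer(),
                    representative = logical())
  for (ln in lines) {
    if (grepl("^>Cluster", ln)) {
      cluster <- as.integer(sub("^>Cluster ([0-9]+)$", "\\1", ln))
    } else if (nzchar(trimws(ln))) {
      id <- sub("^.*>([^.]+)\\.\\.\\..*$", "\\1", ln)
      out <- rbind(out, data.frame(id = id, cluster = cluster,
                                   representative = grepl("\\*\\s*$", ln)))
    }
  }
  out
}
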