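# Independent brute-force oracles and small fixture builders.
# Oracles are written as explicit loops over the definitions and never share
# code with the implementation they check.

# random gene-level matrix with names
random_expr <- function(n_genes, n_samples, prefix = "g") {
  m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

# grouping assigning n_samples samples round-robin to n_groups groups
round_robin_grouping <- function(sample_names, n_groups) {
  sample_grouping(setNames(
    sprintf("grp%02d", rep_len(seq_len(n_groups), length(sample_names))),
    sample_names))
}

# --- rank-table oracle: explicit loops over sets / genes / groups ----------
oracle_rank_table <- function(raw, sets, grouping) {
  centered <- raw
  for (g in rownames(raw)) centered[g, ] <- raw[g, ] - mean(raw[g, ])
  grp <- unclass(grouping)[colnames(raw)]
  groups <- unique(unname(grp))
  scores <- matrix(NA_real_, length(groups), length(sets),
                   dimnames = list(groups, names(sets)))
  for (s in names(sets)) {
    genes <- intersect(sets[[s]], rownames(raw))
    per_sample <- numeric(ncol(raw))
    for (j in seq_len(ncol(raw))) {
      tot <- 0
      for (g in genes) tot <- tot + centered[g, j]
      per_sample[j] <- tot / length(genes)
    }
    for (grp_name in groups)
      scores[grp_name, s] <- mean(per_sample[grp == grp_name])
  }
  ranks <- scores
  for (s in colnames(scores)) {
    ord <- order(-scores[, s], seq_len(nrow(scores)))
    for (i in seq_along(ord)) ranks[ord[i], s] <- i
  }
  list(scores = scores, ranks = ranks)
}

# --- GSEA enrichment-score oracle: step-by-step running sum ---------------
oracle_es <- function(genes, metric, set, p) {
  N <- length(genes)
  hit <- genes %in% set
  Nh <- sum(hit)
  w <- abs(metric)^p
  if (sum(w[hit]) == 0) w[hit] <- 1
  denom_hit <- sum(w[hit])
  rs <- numeric(N)
  running <- 0
  for (i in seq_len(N)) {
    running <- running +
      if (hit[i]) w[i] / denom_hit else -1 / (N - Nh)
    rs[i] <- running
  }
  mx <- max(rs); mn <- min(rs)
  if (mx >= abs(mn)) mx else mn
}

# --- max-SD probe-collapse oracle -----------------------------------------
oracle_collapse <- function(m, map) {
  probes <- intersect(rownames(m), names(map))
  genes <- sort(unique(unname(map[probes])))
  out <- matrix(NA_real_, length(genes), ncol(m),
                dimnames = list(genes, colnames(m)))
  for (g in genes) {
    cand <- sort(probes[map[probes] == g])
    sds <- sapply(cand, function(p) sd(m[p, ]))
    best <- cand[which.max(sds)]  # which.max takes the first = lexicographic
    out[g, ] <- m[best, ]
  }
  out
}

# --- log-rank oracle: per-event-time 2x2 hypergeometric table -------------
oracle_logrank <- function(time, event, in_group1) {
  O1 <- E1 <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    n1 <- sum(time >= t & in_group1)
    n2 <- sum(time >= t & !in_group1)
    d1 <- sum(time == t & event == 1 & in_group1)
    d2 <- sum(time == t & event == 1 & !in_group1)
    n <- n1 + n2; dt <- d1 + d2
    O1 <- O1 + d1
    E1 <- E1 + dt * n1 / n
    if (n > 1) V <- V + dt * n1 * n2 * (n - dt) / (n^2 * (n - 1))
  }
  chisq <- if (V > 0) (O1 - E1)^2 / V else 0
  list(chisq = chisq,
       p = if (V > 0) pchisq(chisq, 1, lower.tail = FALSE) else 1)
}

# random survival cohort with binary groups
random_cohort <- function(n, hr = 1, censor = 0.3) {
  grp <- rep(c("low", "high"), length.out = n)
  rate <- ifelse(grp == "high", hr, 1) * 0.1
  te <- rexp(n, rate)
  tc <- if (censor > 0) rexp(n, 0.1 * censor / (1 - censor)) else rep(Inf, n)
  cohort <- survival_cohort(pmin(te, tc), as.integer(te <= tc),
                            score = ifelse(grp == "high", 1, -1))
  cohort$group <- factor(grp, levels = c("low", "high"))
  cohort
}
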