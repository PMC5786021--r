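# Independent brute-force oracles used to validate the package's
# implementations. Deliberately naive and kept free of package internals.

# Textbook product-moment correlation
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Direct median/MAD modified Z-score computation on a shift matrix
oracle_mad_z <- function(m, consistency = 0.6745) {
  s <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    s[i] <- sqrt(sum((x - mean(x))^2) / length(x))
  }
  med <- median(s)
  mad_s <- median(abs(s - med))
  if (mad_s == 0) rep(0, length(s)) else consistency * (s - med) / mad_s
}

# Naive agglomerative complete linkage: returns the flat partition at
# `cutoff` as a list of index vectors (merging stops when the closest pair
# of clusters is farther than the cutoff).
oracle_complete_linkage <- function(d, cutoff) {
  clusters <- as.list(seq_len(nrow(d)))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dij <- max(d[clusters[[i]], clusters[[j]]])
        if (dij < best_d) { best_d <- dij; best <- c(i, j) }
      }
    }
    if (best_d > cutoff) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  clusters
}

# Convert a list-of-index-vectors partition to a label vector
partition_labels <- function(clusters, n) {
  lab <- integer(n)
  for (k in seq_along(clusters)) lab[clusters[[k]]] <- k
  lab
}

# Two partitions identical up to relabeling?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    nrow(unique(cbind(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# Direct evaluation of the shift/dynamics classification rule table
oracle_classify <- function(rng, rp, d_eta, range_thr = 0.13, r_thr = 0.7,
                            eta_thr = 8) {
  if (rng > range_thr && !is.na(rp) && abs(rp) > r_thr) {
    if (d_eta > 0) "correlated_flexible" else "correlated_rigid"
  } else if (rng < range_thr && abs(d_eta) > eta_thr) {
    if (d_eta > 0) "uncorrelated_flexible" else "uncorrelated_rigid"
  } else "unchanged"
}

# Construct a shift_table directly from a numeric matrix (rows = methyls,
# cols = variants); identifiers are synthesised Ile residues.
matrix_shift_table <- function(m, variants = colnames(m), reference = variants[1]) {
  n <- nrow(m)
  df <- data.frame(methyl = paste0("I", seq_len(n), "-d1"),
                   residue_number = seq_len(n),
                   residue_class = "Ile", methyl_position = "d1")
  for (j in seq_along(variants)) df[[variants[j]]] <- m[, j]
  structure(df, variants = variants, reference_variant = reference,
            class = c("shift_table", "data.frame"))
}

# Random peak table for round-trip tests
random_peaks <- function(n, variant = "WT", seed = 1) {
  set.seed(seed)
  classes <- sample(c("Ile", "Leu", "Val", "Met"), n, replace = TRUE)
  pos <- vapply(classes, function(cl) switch(cl,
    Ile = "d1", Leu = sample(c("d1", "d2"), 1),
    Val = sample(c("g1", "g2"), 1), Met = "e"), character(1))
  data.frame(residue_number = sample(seq_len(500), n),
             residue_class = classes, methyl_position = pos,
             variant = variant,
             delta_C = round(runif(n, 8, 27), 3),
             delta_H = round(runif(n, 0.3, 2.2), 3))
}
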