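# Independent brute-force oracles and small data builders used across the
# suite. These deliberately avoid the package's vectorised code paths.

rand_seq <- function(len) {
  paste(sample(AA_ALPHABET20, len, replace = TRUE), collapse = "")
}

# dipeptide composition by explicit substring counting
naive_dc <- function(sequence) {
  L <- nchar(sequence)
  pairs <- paste0(rep(AA_ALPHABET20, each = 20L),
                  rep(AA_ALPHABET20, times = 20L))
  counts <- stats::setNames(numeric(400), paste0("DC_", pairs))
  for (i in seq_len(L - 1L)) {
    p <- paste0("DC_", substr(sequence, i, i + 1L))
    counts[p] <- counts[p] + 1
  }
  counts / (L - 1L)
}

# conjoint triad feature by explicit window counting
naive_ctf <- function(sequence) {
  L <- nchar(sequence)
  labs <- paste0("CTF_", rep(1:7, each = 49L), "_",
                 rep(rep(1:7, each = 7L), times = 7L), "_",
                 rep(1:7, times = 49L))
  counts <- stats::setNames(numeric(343), labs)
  for (i in seq_len(L - 2L)) {
    g <- residue_group(strsplit(substr(sequence, i, i + 2L), "")[[1]])
    key <- paste0("CTF_", g[1], "_", g[2], "_", g[3])
    counts[key] <- counts[key] + 1
  }
  counts / (L - 2L)
}

# direct metric formulas, written independently of class_metrics()
oracle_metrics <- function(tp, tn, fp, fn) {
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  den <- (tp + fp) * (tn + fn) * (tp + fn) * (tn + fp)
  list(Sn = tp / (tp + fn),
       Sp = tn / (tn + fp),
       MCC = if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den),
       Acc = (tp + tn) / (tp + tn + fp + fn))
}

# brute-force k nearest in-class neighbours by full pairwise distances
oracle_knn <- function(X, k) {
  n <- nrow(X)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(X) - X[i, ])^2))
    d[i] <- Inf
    out[i, ] <- order(d)[seq_len(k)]
  }
  out
}

# well-separated Gaussian point clouds for classifier sanity checks
gauss_classes <- function(n_per, d = 5, sep = 6, seed = 1) {
  k <- length(n_per)
  set.seed(seed)
  centers <- matrix(stats::rnorm(k * d, sd = sep), k, d)
  X <- do.call(rbind, lapply(seq_len(k), function(c)
    matrix(stats::rnorm(n_per[c] * d, sd = 1), n_per[c], d) +
      matrix(centers[c, ], n_per[c], d, byrow = TRUE)))
  list(X = X, y = factor(rep(paste0("C", seq_len(k)), n_per)))
}

# a tiny coarse grid keeping unit-test SVM fits fast
fast_model_cfg <- function(seed = 1, folds = 3) {
  model_config(c_grid = 2^c(0, 4), gamma_grid = 2^c(-5, -1),
               inner_cv_folds = folds, seed = seed)
}

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}
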