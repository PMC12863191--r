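# Evaluation suite: SNP entropy (with population bootstrap), mutual
# information, LD correlation profiles, folded allele-frequency spectra,
# intrawindow-entropy window selection, and clustering quality scores.
# All logarithms are base 2 (bits).

#' Per-SNP entropy of a haplotype panel
#'
#' Each SNP is modelled as a Bernoulli variable whose parameter is the
#' column mean; the entropy is
#' `H = -p log2 p - (1 - p) log2(1 - p)` with `0 log 0 := 0`, so values
#' lie in `[0, 1]` bits.
#'
#' @param panel a [genotype_panel()] or 0/1 matrix.
#' @return Numeric vector of per-SNP entropies (bits).
#' @export
snp_entropy <- function(panel) {
  X <- as_hap_matrix(panel)
  if (nrow(X) == 0L) stop("empty panel")
  binary_entropy(colMeans(X))
}

binary_entropy <- function(p) {
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -p[ok] * log2(p[ok]) - (1 - p[ok]) * log2(1 - p[ok])
  h
}

#' Bootstrapped per-population SNP entropy
#'
#' To remove the bias of unbalanced population sizes, each population's
#' entropy vector is the average of `reps` plug-in estimates, each
#' computed on `m` haplotypes resampled with replacement from that
#' population.
#'
#' @param panel a labelled [genotype_panel()].
#' @param m bootstrap sample size (default 32).
#' @param reps bootstrap replicates (default 50).
#' @param seed integer seed.
#' @return A list of class `entropy_report`: `per_snp` (matrix, one row
#'   per population), `per_population_mean` (named means over SNPs) and
#'   the bootstrap parameters.
#' @export
bootstrap_population_entropy <- function(panel, m = 32, reps = 50,
                                         seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (m < 1 || reps < 1) stop("'m' and 'reps' must be >= 1")
  local_rng(seed)
  pops <- sort(unique(panel$populations))
  per_snp <- t(vapply(pops, function(k) {
    idx <- which(panel$populations == k)
    acc <- numeric(ncol(panel$haplotypes))
    for (r in seq_len(reps)) {
      rows <- sample(idx, m, replace = TRUE)
      acc <- acc + binary_entropy(colMeans(panel$haplotypes[rows, ,
                                                            drop = FALSE]))
    }
    acc / reps
  }, numeric(ncol(panel$haplotypes))))
  structure(list(per_snp = per_snp,
                 per_population_mean = rowMeans(per_snp),
                 m = m, reps = reps, seed = seed),
            class = "entropy_report")
}

#' @export
print.entropy_report <- function(x, ...) {
  cat(sprintf("entropy_report (bootstrap m = %d, reps = %d):\n", x$m, x$reps))
  print(round(x$per_population_mean, 4))
  invisible(x)
}

#' Mutual information between two SNP columns
#'
#' Plug-in estimate from the empirical 2x2 joint distribution, in bits,
#' with `0 * log(0 / .) := 0`.  Satisfies `I(X; X) = H(X)`, symmetry, and
#' `0 <= I <= min(H(X_i), H(X_j))`.
#'
#' @param col_i,col_j equal-length 0/1 vectors.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(col_i, col_j) {
  if (length(col_i) != length(col_j)) stop("columns differ in length")
  n <- length(col_i)
  joint <- table(factor(col_i, levels = 0:1),
                 factor(col_j, levels = 0:1)) / n
  pi_ <- rowSums(joint); pj <- colSums(joint)
  mi <- 0
  for (a in 1:2) for (b in 1:2) {
    p <- joint[a, b]
    if (p > 0) mi <- mi + p * log2(p / (pi_[a] * pj[b]))
  }
  max(as.numeric(mi), 0)
}

#' Mutual information between a reference SNP and strided positions
#'
#' Entry `(y, x)` of the returned matrix is the mutual information between
#' the reference column and the column at offset `x * y` from it, the
#' layout used to visualise how LD-driven dependence decays with distance.
#'
#' @param panel a [genotype_panel()] or 0/1 matrix.
#' @param reference_index column index of the reference SNP.
#' @param strides integer stride lengths (rows; stride 0 gives
#'   `I(ref; ref) = H(ref)`).
#' @param offsets integer offsets (columns).
#' @return `length(strides) x length(offsets)` matrix of MI values (bits).
#' @export
mi_stride_map <- function(panel, reference_index, strides, offsets) {
  X <- as_hap_matrix(panel)
  d <- ncol(X)
  ref <- X[, reference_index]
  out <- matrix(NA_real_, length(strides), length(offsets),
                dimnames = list(paste0("stride", strides),
                                paste0("offset", offsets)))
  for (yi in seq_along(strides)) for (xi in seq_along(offsets)) {
    target <- reference_index + strides[yi] * offsets[xi]
    if (target < 1 || target > d)
      stop(sprintf("target SNP index %d out of range [1, %d]", target, d))
    out[yi, xi] <- mutual_information(ref, X[, target])
  }
  out
}

#' Linkage-disequilibrium decay profile
#'
#' Samples `n_refs` reference SNPs and, for each index offset
#' `1..max_distance`, averages the Pearson correlation between each
#' reference column and the column that many positions away.
#' Zero-variance columns are excluded from the averages (their count is
#' reported) rather than producing `NA`.
#'
#' @param panel a [genotype_panel()] or 0/1 matrix.
#' @param n_refs number of reference SNPs (default 50).
#' @param max_distance maximum index offset (default 500; must be < d).
#' @param seed integer seed for the reference draw.
#' @param absolute average `|r|` instead of signed `r` (default TRUE, so
#'   LD strength does not cancel across phase).
#' @return A list of class `ld_profile`: `distance`, `mean_correlation`,
#'   `n_pairs`, `n_excluded`, `n_reference_snps`.
#' @export
ld_profile <- function(panel, n_refs = 50, max_distance = 500, seed = 1L,
                       absolute = TRUE) {
  X <- as_hap_matrix(panel)
  d <- ncol(X)
  if (max_distance >= d) stop("'max_distance' must be smaller than d")
  local_rng(seed)
  refs <- sort(sample.int(d - max_distance, min(n_refs, d - max_distance)))
  sds <- apply(X, 2, stats::sd)
  Xc <- .addrow(X, -colMeans(X))
  n <- nrow(X)
  acc <- numeric(max_distance); cnt <- integer(max_distance)
  excluded <- 0L
  for (ref in refs) {
    j <- ref + seq_len(max_distance)
    ok <- sds[ref] > 0 & sds[j] > 0
    excluded <- excluded + sum(!ok)
    if (sds[ref] == 0) next
    r <- (crossprod(Xc[, ref], Xc[, j[ok], drop = FALSE]) / (n - 1)) /
      (sds[ref] * sds[j[ok]])
    r <- as.numeric(r)
    if (absolute) r <- abs(r)
    acc[which(ok)] <- acc[which(ok)] + r
    cnt[which(ok)] <- cnt[which(ok)] + 1L
  }
  structure(list(distance = seq_len(max_distance),
                 mean_correlation = ifelse(cnt > 0, acc / pmax(cnt, 1), NA),
                 n_pairs = cnt, n_excluded = excluded,
                 n_reference_snps = length(refs)),
            class = "ld_profile")
}

#' @export
print.ld_profile <- function(x, ...) {
  cat(sprintf("ld_profile: %d reference SNPs, offsets 1..%d\n",
              x$n_reference_snps, max(x$distance)))
  cat(sprintf("mean |r| at offsets 1, 10, %d: %.3f, %.3f, %.3f\n",
              max(x$distance), x$mean_correlation[1],
              x$mean_correlation[min(10, length(x$mean_correlation))],
              x$mean_correlation[length(x$mean_correlation)]))
  invisible(x)
}

#' @export
plot.ld_profile <- function(x, ...) {
  graphics::plot(x$distance, x$mean_correlation, type = "l",
                 xlab = "SNP-index distance", ylab = "mean correlation", ...)
  invisible(x)
}

#' Folded allele-frequency spectrum
#'
#' Histogram of minor-allele frequencies: each polymorphic SNP falls in
#' bin `ceiling(100 * min(p, 1 - p))` (percent, 1..50); monomorphic SNPs
#' are counted separately.  Bin counts plus the monomorphic count sum to
#' `d`, and the spectrum is invariant under global 0/1 relabelling.
#'
#' @param panel a [genotype_panel()] or 0/1 matrix.
#' @param bins upper percent edges of the bins (default `1:50`).
#' @return A list of class `folded_afs`: `bin_percent`, `count`,
#'   `monomorphic`.
#' @export
folded_afs <- function(panel, bins = 1:50) {
  X <- as_hap_matrix(panel)
  p <- colMeans(X)
  maf <- pmin(p, 1 - p)
  mono <- sum(maf == 0)
  idx <- ceiling(100 * maf[maf > 0])
  counts <- vapply(seq_along(bins), function(i) {
    lo <- if (i == 1) 0 else bins[i - 1]
    sum(idx > lo & idx <= bins[i])
  }, numeric(1))
  structure(list(bin_percent = bins, count = counts, monomorphic = mono),
            class = "folded_afs")
}

#' Average intrawindow entropy across candidate window sizes
#'
#' For each candidate `w`, the panel is cut into consecutive `w`-SNP
#' windows and the entropy of a window is `log2` of its number of distinct
#' row-subsequences (never exceeding `log2 N`); the candidate's score is
#' the mean over windows.  Used with [select_window_size()] to pick the
#' window size at the elbow of the size/entropy trade-off.
#'
#' @param panel a [genotype_panel()] or 0/1 matrix.
#' @param window_sizes ascending candidate sizes (>= 2 of them); the
#'   production candidate grid is
#'   `c(50, 100, 500, 1000, 2500, 5000, 7500, 10000)`.
#' @return Named numeric vector of mean intrawindow entropies (bits).
#' @export
intrawindow_entropy <- function(panel,
                                window_sizes = c(50, 100, 500, 1000, 2500,
                                                 5000, 7500, 10000)) {
  X <- as_hap_matrix(panel)
  d <- ncol(X)
  if (any(window_sizes > d))
    stop(sprintf("window size exceeds the panel width d = %d", d))
  out <- vapply(window_sizes, function(w) {
    starts <- seq(1L, d, by = w)
    mean(vapply(starts, function(s) {
      W <- X[, s:min(s + w - 1L, d), drop = FALSE]
      log2(nrow(unique(W)))
    }, numeric(1)))
  }, numeric(1))
  names(out) <- window_sizes
  out
}

#' Elbow selection of the window size
#'
#' Combines the gap in consecutive window sizes with the gap in their mean
#' intrawindow entropies via the product `dw_i * dE_i` and returns the
#' right endpoint `w[i + 1]` of the interval maximizing it — the elbow
#' beyond which widening the window no longer buys entropy.  When all
#' entropy gaps vanish (or none is positive) the smallest candidate is
#' returned.
#'
#' @param window_sizes ascending candidate sizes.
#' @param entropies mean intrawindow entropies, one per candidate (e.g.
#'   from [intrawindow_entropy()]).
#' @return The chosen window size.
#' @export
select_window_size <- function(window_sizes, entropies) {
  if (length(window_sizes) < 2 || length(entropies) != length(window_sizes))
    stop("need >= 2 candidates with one entropy each")
  if (is.unsorted(window_sizes, strictly = TRUE))
    stop("'window_sizes' must be strictly ascending")
  gain <- diff(window_sizes) * diff(entropies)
  if (max(gain) <= 0) return(window_sizes[1])
  window_sizes[which.max(gain) + 1L]
}

#' Clustering quality of a 2-D embedding against population labels
#'
#' Standardizes each coordinate (zero mean, unit variance) and scores the
#' labelled clusters with the pseudo F statistic (Calinski-Harabasz:
#' between-cluster over within-cluster dispersion scaled by degrees of
#' freedom), the Davies-Bouldin index, and the mean silhouette
#' coefficient.
#'
#' @param embedding_2d `N x 2` matrix of coordinates (any `N x q` works).
#' @param labels length-`N` cluster labels (>= 2 clusters, each with >= 2
#'   samples).
#' @return A list of class `cluster_scores`: `pseudo_f`, `dbi`,
#'   `silhouette`.
#' @export
cluster_scores <- function(embedding_2d, labels) {
  Z <- as.matrix(embedding_2d)
  labels <- as.character(labels)
  if (nrow(Z) != length(labels)) stop("rows and labels differ in length")
  sizes <- table(labels)
  if (length(sizes) < 2) stop("need at least two clusters")
  if (any(sizes < 2))
    stop(sprintf("singleton cluster: %s",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  Z <- scale(Z)
  n <- nrow(Z); k <- length(sizes)
  centroids <- apply(Z, 2, function(col) tapply(col, labels, mean))
  grand <- colMeans(Z)
  within <- 0; between <- 0
  scatter <- numeric(k); names(scatter) <- rownames(centroids)
  for (g in rownames(centroids)) {
    Zi <- Z[labels == g, , drop = FALSE]
    dif <- .addrow(Zi, -centroids[g, ])
    within <- within + sum(dif^2)
    between <- between + nrow(Zi) * sum((centroids[g, ] - grand)^2)
    scatter[g] <- mean(sqrt(rowSums(dif^2)))
  }
  pseudo_f <- (between / (k - 1)) / (within / (n - k))
  cd <- as.matrix(stats::dist(centroids))
  dbi <- mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j)
      (scatter[i] + scatter[j]) / cd[i, j], numeric(1)))
  }, numeric(1)))
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(Z))
  structure(list(pseudo_f = as.numeric(pseudo_f), dbi = dbi,
                 silhouette = mean(sil[, "sil_width"])),
            class = "cluster_scores")
}

#' @export
print.cluster_scores <- function(x, ...) {
  cat(sprintf("cluster scores: pseudo F %.2f, DBI %.3f, silhouette %.3f\n",
              x$pseudo_f, x$dbi, x$silhouette))
  invisible(x)
}
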