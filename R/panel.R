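#' Phased binary haplotype panel
#'
#' The universal data container of the package: an `N x d` matrix of phased
#' haplotypes (one row per haplotype, entries 0/1), together with strictly
#' increasing integer variant positions, unique sample identifiers and a
#' per-haplotype population label.
#'
#' @param haplotypes integer or numeric matrix with entries in `{0, 1}`;
#'   one row per haplotype, one column per SNP.
#' @param positions integer vector of base-pair coordinates, strictly
#'   increasing, one per column.  Defaults to `1:d`.
#' @param sample_ids character vector of unique identifiers, one per row.
#' @param populations character vector of population labels, one per row.
#' @return An object of class `genotype_panel` with fields `haplotypes`,
#'   `positions`, `sample_ids`, `populations`.
#' @examples
#' p <- genotype_panel(matrix(c(0, 1, 1, 0), 2, 2))
#' p
#' @export
genotype_panel <- function(haplotypes,
                           positions = NULL,
                           sample_ids = NULL,
                           populations = NULL) {
  haplotypes <- as.matrix(haplotypes)
  if (!is.numeric(haplotypes) && !is.logical(haplotypes))
    stop("'haplotypes' must be a numeric 0/1 matrix")
  storage.mode(haplotypes) <- "integer"
  if (anyNA(haplotypes) || !all(haplotypes == 0L | haplotypes == 1L))
    stop("haplotype entries must all be 0 or 1")
  n <- nrow(haplotypes)
  d <- ncol(haplotypes)
  if (is.null(positions)) positions <- seq_len(d)
  positions <- as.integer(positions)
  if (length(positions) != d)
    stop("'positions' must have one entry per SNP column")
  if (d > 1L && any(diff(positions) <= 0L))
    stop("'positions' must be strictly increasing")
  if (is.null(sample_ids)) sample_ids <- sprintf("hap%d", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) stop("'sample_ids' must have one entry per row")
  if (anyDuplicated(sample_ids)) stop("'sample_ids' must be unique")
  if (is.null(populations)) populations <- rep("pop1", n)
  populations <- as.character(populations)
  if (length(populations) != n)
    stop("'populations' must have one entry per row")
  dimnames(haplotypes) <- NULL
  structure(
    list(haplotypes = haplotypes, positions = positions,
         sample_ids = sample_ids, populations = populations),
    class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  tab <- table(x$populations)
  cat(sprintf("genotype_panel: %d haplotypes x %d SNPs\n",
              nrow(x$haplotypes), ncol(x$haplotypes)))
  cat("populations:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$haplotypes)

#' Subset a haplotype panel by row
#'
#' @param x a [genotype_panel()].
#' @param i row index (integer, logical or sample-id character vector).
#' @param ... unused.
#' @return A `genotype_panel` with the selected haplotypes.
#' @export
`[.genotype_panel` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$sample_ids)
  genotype_panel(x$haplotypes[i, , drop = FALSE], x$positions,
                 x$sample_ids[i], x$populations[i])
}

#' Split a panel into train and test subsets
#'
#' Rows are assigned at random (optionally stratified by population label so
#' both sides keep the label proportions) into disjoint, exhaustive train and
#' test panels.
#'
#' @param panel a [genotype_panel()].
#' @param fractions numeric vector of length 2 summing to 1:
#'   `(train, test)` proportions.
#' @param stratify if `TRUE` (default) split each population separately.
#' @param seed integer seed; identical seeds give identical splits.
#' @return A list with elements `train` and `test`.
#' @export
split_panel <- function(panel, fractions = c(0.8, 0.2), stratify = TRUE,
                        seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (length(fractions) != 2L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("'fractions' must be two non-negative numbers summing to 1")
  n <- nrow(panel$haplotypes)
  local_rng(seed)
  pick_train <- function(idx) {
    if (length(idx) == 0L) stop("empty stratum in split_panel()")
    n_tr <- round(fractions[1] * length(idx))
    sort(sample(idx, n_tr))
  }
  if (stratify) {
    tr <- sort(unlist(lapply(split(seq_len(n), panel$populations), pick_train),
                      use.names = FALSE))
  } else {
    tr <- pick_train(seq_len(n))
  }
  te <- setdiff(seq_len(n), tr)
  list(train = panel[tr], test = panel[te])
}

# Seeded RNG scope: seeds the RNG for the calling function and restores the
# caller's stream when that function exits.
local_rng <- function(seed, envir = parent.frame()) {
  if (!is.null(seed))
    withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(NULL)
}
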