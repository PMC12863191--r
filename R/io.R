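#' Read a haplotype panel from disk
#'
#' Two on-disk formats are supported behind one surface:
#' \describe{
#'   \item{`"vcf"`}{a phased, biallelic VCF with a `GT` field.  Each diploid
#'     sample contributes two haplotype rows, with `_1`/`_2` suffixed to the
#'     sample id.  Population labels are recovered from
#'     `##POPULATION=<ID=...,POP=...>` header lines when present (as written
#'     by [write_panel()]), otherwise every haplotype is labelled
#'     `"unknown"`.}
#'   \item{`"rds"`}{the package's serialized matrix container: a single R
#'     object holding the bit matrix plus positions, sample ids and labels;
#'     `write_panel()` followed by `read_panel()` is the identity.}
#' }
#'
#' @param path input file.
#' @param format `"vcf"` or `"rds"`; guessed from the extension by default.
#' @return A [genotype_panel()].
#' @export
read_panel <- function(path, format = c("auto", "vcf", "rds")) {
  format <- resolve_format(match.arg(format), path)
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  switch(format, vcf = read_panel_vcf(path), rds = read_panel_rds(path))
}

#' Write a haplotype panel to disk
#'
#' @param panel a [genotype_panel()].
#' @param path output file.
#' @param format `"vcf"` or `"rds"`; guessed from the extension by default.
#'   VCF output requires an even number of haplotype rows (consecutive row
#'   pairs become one phased diploid sample).
#' @return `path`, invisibly.
#' @seealso [read_panel()]
#' @export
write_panel <- function(panel, path, format = c("auto", "vcf", "rds")) {
  stopifnot(inherits(panel, "genotype_panel"))
  format <- resolve_format(match.arg(format), path)
  switch(format,
         vcf = write_panel_vcf(panel, path),
         rds = saveRDS(unclass(panel), path))
  invisible(path)
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "vcf") "vcf" else "rds"
}

read_panel_rds <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$haplotypes))
    stop(sprintf("'%s' is not a serialized genotype panel", path))
  genotype_panel(obj$haplotypes, obj$positions, obj$sample_ids,
                 obj$populations)
}

read_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  bad <- which(is.na(alt) | grepl(",", alt))
  if (length(bad))
    stop(sprintf("multiallelic or ALT-less VCF record at %s:%s",
                 fix[bad[1], "CHROM"], fix[bad[1], "POS"]))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  samples <- colnames(v@gt)[-1]
  n_site <- nrow(gt)
  haps <- vector("list", 2L * length(samples))
  ids <- character(2L * length(samples))
  for (j in seq_along(samples)) {
    g <- gt[, j]
    bad <- which(is.na(g) | !grepl("^[01]\\|[01]$", g))
    if (length(bad))
      stop(sprintf(
        "unphased, missing or non-biallelic genotype '%s' at %s:%s (sample %s)",
        g[bad[1]], fix[bad[1], "CHROM"], fix[bad[1], "POS"], samples[j]))
    al <- matrix(as.integer(unlist(strsplit(g, "|", fixed = TRUE))),
                 nrow = 2L)
    haps[[2L * j - 1L]] <- al[1L, ]
    haps[[2L * j]] <- al[2L, ]
    ids[c(2L * j - 1L, 2L * j)] <- paste0(samples[j], c("_1", "_2"))
  }
  hap <- do.call(rbind, haps)
  meta <- v@meta
  pop_lines <- grep("^##POPULATION=", meta, value = TRUE)
  pops <- rep("unknown", length(ids))
  if (length(pop_lines)) {
    m <- regmatches(pop_lines,
                    regexec("^##POPULATION=<ID=([^,>]+),POP=([^>]+)>",
                            pop_lines))
    map <- vapply(m, `[`, character(1), 3L)
    names(map) <- vapply(m, `[`, character(1), 2L)
    base <- sub("_[12]$", "", ids)
    hit <- base %in% names(map)
    pops[hit] <- unname(map[base[hit]])
  }
  genotype_panel(hap, positions = as.integer(fix[, "POS"]),
                 sample_ids = ids, populations = pops)
}

write_panel_vcf <- function(panel, path) {
  n <- nrow(panel$haplotypes)
  if (n %% 2L != 0L)
    stop("VCF output needs an even number of haplotypes (diploid pairing)")
  d <- ncol(panel$haplotypes)
  n_s <- n %/% 2L
  ids <- sub("_[12]$", "", panel$sample_ids[seq(1L, n, by = 2L)])
  if (anyDuplicated(ids))
    ids <- sprintf("S%04d", seq_len(n_s))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=genolatent",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    sprintf("##POPULATION=<ID=%s,POP=%s>", ids,
            panel$populations[seq(1L, n, by = 2L)]),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"))
  gt <- matrix(sprintf("%d|%d",
                       t(panel$haplotypes[seq(1L, n, by = 2L), , drop = FALSE]),
                       t(panel$haplotypes[seq(2L, n, by = 2L), , drop = FALSE])),
               nrow = d)
  body <- paste(
    "1", panel$positions, ".", "A", "G", ".", "PASS", ".", "GT",
    apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
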