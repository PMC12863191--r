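#' Residual between a haplotype and its reconstruction
#'
#' Elementwise XOR: `r[i] = 1` exactly where the input and the binarized
#' reconstruction disagree, so `x_hat XOR r` recovers `x` exactly.
#'
#' @param x,x_hat binary vectors (or matrices) of equal shape.
#' @return Integer 0/1 residual of the same shape.
#' @export
compute_residual <- function(x, x_hat) {
  if (length(x) != length(x_hat)) stop("'x' and 'x_hat' differ in shape")
  if (!all(x %in% c(0, 1)) || !all(x_hat %in% c(0, 1)))
    stop("residuals are defined for binary inputs only")
  r <- abs(x - x_hat)
  storage.mode(r) <- "integer"
  r
}

#' Run-length encoding of a bit vector
#'
#' Runs alternate in value starting from 0, so a vector beginning with 1
#' gets an empty (zero-length) leading run.  `rle_decode()` is the exact
#' inverse.
#'
#' @param bits 0/1 vector.
#' @return Integer vector of run lengths.
#' @examples
#' rle_encode(c(0, 0, 1, 1, 1, 0))  # 2 3 1
#' @export
rle_encode <- function(bits) {
  if (!all(bits %in% c(0, 1))) stop("'bits' must be 0/1")
  if (length(bits) == 0L) return(integer())
  r <- rle(as.integer(bits))
  if (r$values[1] == 1L) c(0L, r$lengths) else r$lengths
}

#' @rdname rle_encode
#' @param runs run lengths as produced by `rle_encode()`.
#' @param length total number of bits to reconstruct.
#' @export
rle_decode <- function(runs, length) {
  if (sum(runs) != length)
    stop(sprintf("run lengths sum to %d but %d bits were expected",
                 sum(runs), length))
  if (length == 0L) return(integer())
  vals <- rep(c(0L, 1L), length.out = base::length(runs))
  rep(vals, runs)
}

# ---- size accounting --------------------------------------------------

#' Bit-size of a payload under a storage convention
#'
#' The size function used in all compression-factor accounting: bits are 1
#' bit each, 32-bit floats are 32 bits each, fixed-width integers are their
#' declared width, and encoded byte payloads are 8 bits per byte.
#'
#' @param payload the stored object (vector or raw).
#' @param dtype `"bit"`, `"float32"`, `"raw-bytes"`, or `"int<k>"` for
#'   k-bit unsigned integers (e.g. `"int16"`).
#' @return Number of bits.
#' @export
size_of <- function(payload, dtype) {
  n <- as.numeric(length(payload))
  if (dtype == "bit") return(n)
  if (dtype == "float32") return(32 * n)
  if (dtype %in% c("raw-bytes", "raw")) return(8 * n)
  m <- regmatches(dtype, regexec("^int-?(?:width-)?([0-9]+)$", dtype))[[1]]
  if (length(m) == 2) return(as.integer(m[2]) * n)
  stop(sprintf("unknown dtype '%s'", dtype))
}

# unsigned LEB128 varints for run lengths / counters
encode_varints <- function(x) {
  out <- raw(0)
  chunks <- lapply(as.numeric(x), function(v) {
    if (v < 0) stop("varints are unsigned")
    bytes <- raw(0)
    repeat {
      b <- v %% 128
      v <- v %/% 128
      bytes <- c(bytes, as.raw(b + if (v > 0) 128 else 0))
      if (v == 0) break
    }
    bytes
  })
  do.call(c, c(list(out), chunks))
}

decode_varints <- function(bytes) {
  vals <- numeric(0)
  v <- 0; shift <- 0
  for (b in as.integer(bytes)) {
    v <- v + (b %% 128) * 2^shift
    if (b < 128) { vals <- c(vals, v); v <- 0; shift <- 0 }
    else shift <- shift + 7
  }
  if (shift != 0) stop("truncated varint payload")
  vals
}

bits_to_raw <- function(bits) packBits(c(as.integer(bits),
                                         integer((8 - length(bits) %% 8) %% 8)),
                                       "raw")
raw_to_bits <- function(r, n) as.integer(rawToBits(r))[seq_len(n)]

#' Bitstream codec backends
#'
#' Returns a lossless encoder/decoder pair over bit vectors.  Built-in
#' backends: `"rle"` (run lengths as LEB128 varints), `"gzip"` and `"xz"`
#' (bit-packed bytes through [memCompress()]).  `"zstd"` resolves to the
#' external `zstd` binary when it is on the `PATH`; any other external
#' filter is available as `"external:<command>"`, where `<command>`
#' compresses stdin to stdout and `<command> -d` inverts it.
#'
#' @param name backend name.
#' @return A list with `name`, `encode(bits) -> raw` and
#'   `decode(raw, n_bits) -> bits`.
#' @export
codec_backend <- function(name) {
  if (name == "rle") {
    return(list(name = name,
                encode = function(bits) encode_varints(rle_encode(bits)),
                decode = function(r, n) rle_decode(decode_varints(r), n)))
  }
  if (name %in% c("gzip", "xz")) {
    type <- name
    return(list(name = name,
                encode = function(bits) memCompress(bits_to_raw(bits), type),
                decode = function(r, n)
                  raw_to_bits(memDecompress(r, type), n)))
  }
  if (name == "zstd" || startsWith(name, "external:")) {
    cmd <- if (name == "zstd") "zstd -q" else sub("^external:", "", name)
    bin <- strsplit(cmd, "[[:space:]]+")[[1]][1]
    if (Sys.which(bin) == "")
      stop(sprintf(
        "external codec binary '%s' not found on PATH (codec '%s')",
        bin, name))
    pipe_through <- function(args, input) {
      fin <- tempfile(); fout <- tempfile()
      on.exit(unlink(c(fin, fout)), add = TRUE)
      writeBin(input, fin)
      status <- system2("sh", c("-c", sprintf("%s < %s > %s", args,
                                              shQuote(fin), shQuote(fout))))
      if (status != 0) stop(sprintf("external codec '%s' failed", args))
      readBin(fout, "raw", file.size(fout))
    }
    return(list(name = name,
                encode = function(bits) pipe_through(cmd, bits_to_raw(bits)),
                decode = function(r, n)
                  raw_to_bits(pipe_through(paste(cmd, "-d"), r), n)))
  }
  stop(sprintf("unknown codec '%s' (use rle, gzip, xz, zstd or external:<cmd>)",
               name))
}

# ---- compress / decompress --------------------------------------------

# smallest power-of-two byte width holding K - 1
index_byte_width <- function(K) {
  bits <- max(1, ceiling(log2(K)))
  bytes <- 2^ceiling(log2(ceiling(bits / 8)))
  as.integer(bytes)
}

indices_to_raw <- function(idx0, width) {
  # little-endian fixed-width unsigned integers
  out <- raw(length(idx0) * width)
  v <- as.numeric(idx0)
  for (b in seq_len(width)) {
    out[seq(b, length(out), by = width)] <- as.raw(v %% 256)
    v <- v %/% 256
  }
  out
}

raw_to_indices <- function(r, width) {
  n <- length(r) %/% width
  v <- numeric(n)
  for (b in rev(seq_len(width)))
    v <- v * 256 + as.integer(r[seq(b, n * width, by = width)])
  v
}

#' Losslessly compress a haplotype with a trained model
#'
#' Stores the latent representation (32-bit floats for a plain VAE or PCA
#' fit; codebook indices for a VQ model) plus the codec-encoded residual
#' needed to correct the reconstruction exactly.  The record is
#' self-describing and refuses decompression under a model whose weight
#' fingerprint does not match.
#'
#' Size accounting follows the compression-factor convention
#' `factor = l(x) / (l(z) + l(A(r)))` — with float latents counted at 32
#' bits each, and in VQ mode the index matrix also passing through the
#' codec (`l(A(z))`).  A factor above 1 means the haplotype shrank.
#'
#' @param x a single 0/1 haplotype of the model's dimension `d`.
#' @param model a fitted [snp_vae()] or [snp_pca()].
#' @param codec a [codec_backend()] name (default `"rle"`).
#' @param label population label for conditioned models.
#' @return An object of class `compressed_record` with fields `header`,
#'   `payload_latent`, `payload_residual` and `report` (a size report with
#'   `bits_original`, `bits_latent`, `bits_residual`, `factor`, `success`).
#' @seealso [decompress()], [compress_panel()], [write_record()]
#' @export
compress <- function(x, model, codec = "rle", label = NULL) {
  if (inherits(x, "genotype_panel"))
    stop("use compress_panel() for whole panels")
  x <- as.integer(x)
  if (length(x) != model_dim(model))
    stop(sprintf("haplotype has %d SNPs but the model expects d = %d",
                 length(x), model_dim(model)))
  if (!all(x %in% c(0L, 1L))) stop("haplotype must be binary")
  cdc <- codec_backend(codec)
  vq <- is_vq(model)
  if (vq) {
    enc <- vq_indices(model, x, label)
    width <- index_byte_width(nrow(enc$codebook))
    idx_raw <- indices_to_raw(enc$indices - 1L, width)
    payload_latent <- cdc$encode(as.integer(rawToBits(idx_raw)))
    xhat <- enc$xhat
    bits_latent <- size_of(payload_latent, "raw-bytes")
    latent_meta <- list(mode = "vq-indices", n_index = length(enc$indices),
                        index_width = width,
                        index_dim = dim(enc$indices))
  } else {
    z <- latent_codes(model, x, label)
    z32 <- float32_roundtrip(z)
    xhat <- reconstruct_from_latent(model, z32, label)
    payload_latent <- writeBin(z32, raw(), size = 4)
    bits_latent <- size_of(z32, "float32")
    latent_meta <- list(mode = "float32", n_latent = length(z32))
  }
  r <- compute_residual(x, xhat)
  payload_residual <- cdc$encode(r)
  bits_residual <- size_of(payload_residual, "raw-bytes")
  report <- list(bits_original = length(x), bits_latent = bits_latent,
                 bits_residual = bits_residual,
                 factor = length(x) / (bits_latent + bits_residual),
                 success = (bits_latent + bits_residual) < length(x))
  header <- c(list(magic = "GLZR", version = 1L, d = length(x),
                   codec = codec, label = label %||% NA_character_,
                   fingerprint = model_fingerprint(model)),
              latent_meta)
  structure(list(header = header, payload_latent = payload_latent,
                 payload_residual = payload_residual, report = report),
            class = "compressed_record")
}

#' @export
print.compressed_record <- function(x, ...) {
  h <- x$header; r <- x$report
  cat(sprintf(
    "compressed_record: d = %d, %s latents, codec %s\n", h$d, h$mode, h$codec))
  cat(sprintf("  %d -> %d bits (latent %d + residual %d), factor %.3f [%s]\n",
              r$bits_original, r$bits_latent + r$bits_residual, r$bits_latent,
              r$bits_residual, r$factor,
              if (r$success) "compression" else "expansion"))
  invisible(x)
}

#' Decompress a record back to the exact haplotype
#'
#' Rebuilds the reconstruction from the stored latent representation and
#' XORs the decoded residual onto it; the result equals the original input
#' bit-exactly for the model whose fingerprint matches the record header.
#'
#' @param record a `compressed_record` (from [compress()] or
#'   [read_record()]).
#' @param model the model that produced the record.
#' @return Integer 0/1 haplotype of length `d`.
#' @export
decompress <- function(record, model) {
  stopifnot(inherits(record, "compressed_record"))
  h <- record$header
  if (!identical(h$fingerprint, model_fingerprint(model)))
    stop("model fingerprint does not match the record: refusing to decode")
  cdc <- codec_backend(h$codec)
  label <- if (is.na(h$label)) NULL else h$label
  if (h$mode == "vq-indices") {
    n_bits <- h$n_index * h$index_width * 8L
    idx_raw <- packBits(as.integer(cdc$decode(record$payload_latent, n_bits)),
                        "raw")
    idx <- raw_to_indices(idx_raw, h$index_width) + 1L
    dim(idx) <- h$index_dim
    xhat <- reconstruct_from_indices(model, idx, label)
  } else {
    z32 <- readBin(record$payload_latent, "double", n = h$n_latent, size = 4)
    if (length(z32) != h$n_latent) stop("truncated latent payload")
    xhat <- reconstruct_from_latent(model, z32, label)
  }
  r <- cdc$decode(record$payload_residual, h$d)
  as.integer(xor(xhat == 1L, r == 1L))
}

#' Compress every haplotype of a panel
#'
#' @param panel a [genotype_panel()].
#' @param model a fitted [snp_vae()] or [snp_pca()].
#' @param codec a [codec_backend()] name.
#' @param label optional label override for conditioned models (defaults
#'   to the panel's population labels).
#' @return A list with `records` (one `compressed_record` per haplotype)
#'   and `report` (a data frame of per-haplotype size accounting; the mean
#'   compression factor is `mean(report$factor)`).
#' @export
compress_panel <- function(panel, model, codec = "rle", label = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  labs <- if (!is.null(label)) rep(label, length.out = nrow(panel$haplotypes))
          else if (needs_label(model)) panel$populations else NULL
  records <- lapply(seq_len(nrow(panel$haplotypes)), function(i)
    compress(panel$haplotypes[i, ], model, codec,
             label = if (is.null(labs)) NULL else labs[i]))
  report <- do.call(rbind, lapply(records, function(r)
    as.data.frame(r$report)))
  report <- cbind(sample_id = panel$sample_ids, report)
  list(records = records, report = report)
}

float32_roundtrip <- function(z) {
  readBin(writeBin(as.numeric(z), raw(), size = 4), "double",
          n = length(z), size = 4)
}

# ---- archive serialization --------------------------------------------

#' Write / read a compressed record archive
#'
#' Fixed binary layout: magic bytes `GLZR`, a format version, a
#' length-prefixed JSON header, then the two length-prefixed payloads.
#' Truncated or corrupted files raise an integrity error rather than
#' decoding silently.
#'
#' @param record a `compressed_record`.
#' @param path archive file.
#' @return `read_record()` returns the record; `write_record()` returns
#'   `path` invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "compressed_record"))
  con <- file(path, "wb")
  on.exit(close(con))
  record_to_con(record, con)
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  if (!file.exists(path)) stop(sprintf("archive not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  record_from_con(con, path)
}

record_to_con <- function(record, con) {
  writeBin(charToRaw("GLZR"), con)
  hdr <- charToRaw(jsonlite::toJSON(record$header, auto_unbox = TRUE,
                                    null = "null"))
  writeBin(length(hdr), con, size = 4)
  writeBin(hdr, con)
  for (p in list(record$payload_latent, record$payload_residual)) {
    writeBin(length(p), con, size = 4)
    writeBin(p, con)
  }
}

record_from_con <- function(con, path = "<connection>") {
  magic <- readBin(con, "raw", 4)
  if (!identical(rawToChar(magic), "GLZR"))
    stop(sprintf("'%s' is not a genolatent archive (bad magic bytes)", path))
  take <- function(n, what = "raw") {
    out <- readBin(con, what, n)
    if (length(out) != n) stop(sprintf("truncated archive: %s", path))
    out
  }
  hlen <- take(1, "integer")
  header <- jsonlite::fromJSON(rawToChar(take(hlen)))
  header$label <- if (is.null(header$label)) NA_character_ else header$label
  pl <- take(take(1, "integer"))
  pr <- take(take(1, "integer"))
  structure(list(header = header, payload_latent = pl, payload_residual = pr,
                 report = NULL),
            class = "compressed_record")
}

#' Write / read a multi-haplotype archive
#'
#' Concatenates per-haplotype records (magic `GLZP`, a count, then one
#' `GLZR` block per haplotype plus its sample id).
#'
#' @param result a [compress_panel()] result (or a list of records).
#' @param path archive file.
#' @return `read_archive()` returns a list with `records` and
#'   `sample_ids`.
#' @export
write_archive <- function(result, path) {
  records <- if (!is.null(result$records)) result$records else result
  ids <- if (!is.null(result$report)) result$report$sample_id
         else sprintf("hap%d", seq_along(records))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("GLZP"), con)
  writeBin(length(records), con, size = 4)
  for (i in seq_along(records)) {
    id <- charToRaw(ids[i])
    writeBin(length(id), con, size = 4)
    writeBin(id, con)
    record_to_con(records[[i]], con)
  }
  invisible(path)
}

#' @rdname write_archive
#' @export
read_archive <- function(path) {
  if (!file.exists(path)) stop(sprintf("archive not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  if (!identical(rawToChar(magic), "GLZP"))
    stop(sprintf("'%s' is not a genolatent panel archive", path))
  n <- readBin(con, "integer", 1)
  ids <- character(n)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    idlen <- readBin(con, "integer", 1)
    ids[i] <- rawToChar(readBin(con, "raw", idlen))
    records[[i]] <- record_from_con(con, path)
  }
  list(records = records, sample_ids = ids)
}

# ---- model-facing adapters --------------------------------------------

model_dim <- function(model) model$d
is_vq <- function(model) inherits(model, "snp_vae") && model$config$use_vq
needs_label <- function(model)
  inherits(model, "snp_vae") && model$config$conditioning != "none"

latent_codes <- function(model, x, label = NULL) {
  UseMethod("latent_codes")
}

#' @export
latent_codes.snp_vae <- function(model, x, label = NULL) {
  drop(encode(model, x, label)$mu)
}

reconstruct_from_latent <- function(model, z, label = NULL) {
  UseMethod("reconstruct_from_latent")
}

#' @export
reconstruct_from_latent.snp_vae <- function(model, z, label = NULL) {
  as.integer(decode(model, z, label)$bits)
}

# quantized path: indices (heads x windows) and the implied reconstruction
vq_indices <- function(model, x, label = NULL) {
  if (model$config$conditioning == "yvae") {
    sub <- model$bank[[label %||% stop("Y-VAE compression needs a label")]]
    out <- vq_indices(sub, x, NULL)
    return(out)
  }
  st <- encode(model, x, label)
  Z <- matrix(st$mu, nrow = 1)
  qz <- quantize_batch(Z, model$codebook, total_heads(model))
  rec <- decode(model, drop(qz$quantized), label)
  list(indices = matrix(qz$indices, nrow = model$config$heads),
       codebook = model$codebook,
       xhat = as.integer(rec$bits))
}

reconstruct_from_indices <- function(model, idx, label = NULL) {
  if (model$config$conditioning == "yvae")
    return(reconstruct_from_indices(
      model$bank[[label %||% stop("Y-VAE decompression needs a label")]],
      idx, NULL))
  qh <- ncol(model$codebook)
  heads <- model$config$heads
  z <- numeric(length(idx) * qh)
  # idx is heads x windows; latent layout is window-major with head blocks
  for (j in seq_len(ncol(idx))) for (h in seq_len(heads)) {
    pos <- ((j - 1L) * heads + (h - 1L)) * qh + seq_len(qh)
    z[pos] <- model$codebook[idx[h, j], ]
  }
  as.integer(decode(model, z, label)$bits)
}
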