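`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Coerce EBImage results back to a plain unnamed matrix.
as_raster <- function(x) {
  if (methods::is(x, "Image")) x <- EBImage::imageData(x)
  x <- as.matrix(x)
  dimnames(x) <- NULL
  x
}

assert_raster <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x) || any(dim(x) < 1L))
    stop_validation("%s must be a nonempty numeric matrix", name)
  invisible(x)
}

assert_same_shape <- function(a, b, what = "rasters") {
  if (!identical(dim(a), dim(b)))
    stop_validation("%s must have identical dimensions (%s vs %s)", what,
                    paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  invisible(NULL)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Snap an intensity raster to the 16-bit grid used by the TIFF writer, so
# written fixtures re-read bit-exactly.
quantize16 <- function(x) {
  round(pmin(pmax(x, 0), 1) * 65535) / 65535
}

# 0-based centroids (x = col - 1, y = row - 1) of each label in a raster.
label_centroids <- function(labels, n) {
  if (n == 0L) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  idx <- which(labels > 0L)
  lab <- labels[idx]
  nr <- nrow(labels)
  rows <- (idx - 1L) %% nr
  cols <- (idx - 1L) %/% nr
  cbind(x = as.numeric(tapply(cols, lab, mean)[as.character(seq_len(n))]),
        y = as.numeric(tapply(rows, lab, mean)[as.character(seq_len(n))]))
}
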