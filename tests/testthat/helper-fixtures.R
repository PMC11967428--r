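# Shared fixture builders and independent oracles.

noiseless <- list(photons = 0, read_sd = 0, shading_amplitude = 0)

# Brute-force nearest-instance Voronoi assignment: for every support pixel,
# search all site pixels; ties resolved by lower label (site columns are
# ordered by label, max.col "first" takes the earliest winner).
bf_voronoi <- function(labels, support) {
  sites <- which(labels > 0L)
  if (!length(sites)) return(matrix(0L, nrow(labels), ncol(labels)))
  nr <- nrow(labels)
  sr <- (sites - 1L) %% nr
  sc <- (sites - 1L) %/% nr
  sl <- labels[sites]
  ord <- order(sl, sites)
  sr <- sr[ord]; sc <- sc[ord]; sl <- sl[ord]
  px <- which(support)
  pr <- (px - 1L) %% nr
  pc <- (px - 1L) %/% nr
  d2 <- outer(pr, sr, "-")^2 + outer(pc, sc, "-")^2
  win <- max.col(-d2, ties.method = "first")
  out <- matrix(0L, nr, ncol(labels))
  out[px] <- sl[win]
  out
}

# Random small label/support fixture for the Voronoi oracle tests.
random_voronoi_fixture <- function() {
  nr <- sample(8:64, 1)
  nc <- sample(8:64, 1)
  n <- sample(1:10, 1)
  lab <- matrix(0L, nr, nc)
  for (k in seq_len(n)) {
    ctr <- c(sample(nr, 1), sample(nc, 1))
    r <- runif(1, 0, 3)
    rr <- max(1, ctr[1] - 3):min(nr, ctr[1] + 3)
    cc <- max(1, ctr[2] - 3):min(nc, ctr[2] + 3)
    for (a in rr) for (b in cc)
      if ((a - ctr[1])^2 + (b - ctr[2])^2 <= r^2) lab[a, b] <- k
    lab[ctr[1], ctr[2]] <- k
  }
  nl <- nuclei_labels(lab)   # canonical consecutive labels
  support <- matrix(runif(nr * nc) > 0.4, nr, nc) | nl$labels > 0L
  list(nuclei = nl, support = support)
}

# Small noiseless FFPE field with planted coverage spanning [0, 1].
small_ffpe <- function(seed, n_cells = 30L, size = 400L,
                       coverage_spec = list(fraction = 1, hi = c(0, 1),
                                            lo = c(0, 0)), ...) {
  generate_ffpe_field(synthetic_params(
    image_size_px = c(size, size), n_tumor_cells = n_cells, seed = seed,
    coverage_spec = coverage_spec, noise = noiseless, ...))
}

# Ground-truth nucleus raster as an external-segmenter label object.
gt_labels <- function(truth) {
  nuclei_labels(truth$nucleus_raster, canonicalize = FALSE)
}

# Config that measures coverage on the background-subtracted channel with a
# fixed threshold (the noiseless recovery setting).
recovery_config <- function(...) {
  pipeline_config(marker = list(use_clahe = FALSE,
                                binarize_method = "fixed:0.4"), ...)
}

# Render blurred disks as a nuclei-like channel.
render_disks <- function(nr, nc, centers, radius, intensity = 0.9,
                         blur = 1) {
  m <- matrix(0, nr, nc)
  for (i in seq_len(nrow(centers))) {
    rr <- outer((seq_len(nr) - centers[i, 1])^2,
                (seq_len(nc) - centers[i, 2])^2, "+")
    m[rr <= radius^2] <- intensity
  }
  trogoscan:::as_raster(EBImage::gblur(m, blur))
}
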