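#' Parameters for the synthetic field generator
#'
#' Defines one simulated field of view.  Nucleus centers are laid out on a
#' jittered hexagonal lattice (guaranteeing the requested cell count and a
#' minimum spacing), territories are the nearest-instance Voronoi
#' tessellation of the planted nuclei restricted to the tumor region — the
#' same territory model the pipeline uses, so planted per-cell coverage is
#' exact in the noiseless limit.  Marker coverage is planted as an exact
#' pixel subset of each territory; trogosomes are planted as hollow spheres
#' whose pixel sets realize the nearest achievable equivalent-circle
#' diameter not exceeding the nominal diameter.
#'
#' @param image_size_px integer pair (rows, cols).
#' @param pixel_size_um micrometres per pixel.
#' @param n_tumor_cells,n_stromal_cells cell counts inside/outside the tumor
#'   region.
#' @param nucleus_radius_um_mean,nucleus_radius_um_sd nucleus radius
#'   distribution (Gaussian, clipped to positive).
#' @param min_spacing_um lattice pitch between nucleus centers.
#' @param region_mode how the tumor/tissue region is laid out: `"disk"`
#'   (central disk covering `tumor_region_fraction` of the field, FFPE-like
#'   tumor nest with surrounding stroma), `"footprint"` (union of disks of
#'   radius `footprint_radius_um` around the nuclei, emulating spread
#'   adherent cells on glass), or `"all"` (whole field).
#' @param tumor_region_fraction fraction of the field covered by the tumor
#'   region for `region_mode = "disk"`.
#' @param footprint_radius_um cell-body radius for `region_mode =
#'   "footprint"`.
#' @param coverage_spec mixture for per-cell planted marker coverage:
#'   `fraction` of cells draw coverage from `Uniform(hi[1], hi[2])`
#'   (the marker-expressing class), the rest from `Uniform(lo[1], lo[2])`.
#' @param marker_intensity,nuclei_intensity,tumor_intensity rendered
#'   foreground amplitudes (fractions of full scale).
#' @param background_level camera offset added to every channel.
#' @param autofluor per-cell autofluorescence law on the marker channel:
#'   `list(meanlog, sdlog)` of a log-normal (or `NULL` for none).
#' @param trogosome_spec `NULL`, or a list with `large_fraction` (fraction
#'   of cells given one large trogosome), `large_diameter_um` (range),
#'   `small_per_cell` (integer count range per cell), `small_diameter_um`
#'   (range); alternatively `diameters_um`, a vector of one nominal diameter
#'   per cell (`NA` = none), overrides the distributions.
#' @param hollow_interior_fraction interior intensity of a trogosome as a
#'   fraction of its ring intensity.
#' @param n_debris,debris_radius_px bright specks (paraffin-like debris)
#'   planted in the nuclei channel.
#' @param noise `list(photons, read_sd, shading_amplitude)`: scaled-Poisson
#'   shot noise (expected photons at full scale; 0 disables), additive
#'   Gaussian read noise sd, and a linear additive shading gradient
#'   amplitude across the field.  Each nuisance is independently switchable.
#' @param timepoint optional timepoint label (co-culture fields).
#' @param source_id identifier stamped on the generated image.
#' @param seed RNG seed; fixes the entire sample.
#' @return A validated list of class `synthetic_params`.
#' @export
synthetic_params <- function(image_size_px = c(640L, 640L),
                             pixel_size_um = 0.25,
                             n_tumor_cells = 100L,
                             n_stromal_cells = 0L,
                             nucleus_radius_um_mean = 3,
                             nucleus_radius_um_sd = 0.3,
                             min_spacing_um = 10,
                             region_mode = c("disk", "footprint", "all"),
                             tumor_region_fraction = 0.55,
                             footprint_radius_um = 9,
                             coverage_spec = list(fraction = 0.4,
                                                  hi = c(0.55, 0.90),
                                                  lo = c(0, 0)),
                             marker_intensity = 0.8,
                             nuclei_intensity = 0.9,
                             tumor_intensity = 0.7,
                             background_level = 0.02,
                             autofluor = list(meanlog = log(0.05),
                                              sdlog = 0.25),
                             trogosome_spec = NULL,
                             hollow_interior_fraction = 0.3,
                             n_debris = 0L,
                             debris_radius_px = 3L,
                             noise = list(photons = 800, read_sd = 0.005,
                                          shading_amplitude = 0),
                             timepoint = NA_character_,
                             source_id = "synthetic",
                             seed = 1L) {
  p <- list(image_size_px = as.integer(image_size_px),
            pixel_size_um = pixel_size_um,
            n_tumor_cells = as.integer(n_tumor_cells),
            n_stromal_cells = as.integer(n_stromal_cells),
            nucleus_radius_um_mean = nucleus_radius_um_mean,
            nucleus_radius_um_sd = nucleus_radius_um_sd,
            min_spacing_um = min_spacing_um,
            region_mode = match.arg(region_mode),
            tumor_region_fraction = tumor_region_fraction,
            footprint_radius_um = footprint_radius_um,
            coverage_spec = modifyList(list(fraction = 0.4, hi = c(0.55, 0.9),
                                            lo = c(0, 0)), coverage_spec),
            marker_intensity = marker_intensity,
            nuclei_intensity = nuclei_intensity,
            tumor_intensity = tumor_intensity,
            background_level = background_level,
            autofluor = autofluor,
            trogosome_spec = trogosome_spec,
            hollow_interior_fraction = hollow_interior_fraction,
            n_debris = as.integer(n_debris),
            debris_radius_px = as.integer(debris_radius_px),
            noise = modifyList(list(photons = 0, read_sd = 0,
                                    shading_amplitude = 0), noise),
            timepoint = timepoint,
            source_id = source_id,
            seed = as.integer(seed))
  cs <- p$coverage_spec
  if (cs$fraction < 0 || cs$fraction > 1 ||
      any(c(cs$hi, cs$lo) < 0) || any(c(cs$hi, cs$lo) > 1) ||
      cs$hi[1] > cs$hi[2] || cs$lo[1] > cs$lo[2])
    stop_validation("invalid coverage_spec")
  if (p$pixel_size_um <= 0 || p$min_spacing_um <= 0 ||
      p$nucleus_radius_um_mean <= 0 || p$nucleus_radius_um_sd < 0)
    stop_validation("geometry parameters must be positive")
  if (p$tumor_region_fraction <= 0 || p$tumor_region_fraction > 1)
    stop_validation("tumor_region_fraction must lie in (0, 1]")
  if (p$footprint_radius_um <= p$nucleus_radius_um_mean &&
      p$region_mode == "footprint")
    stop_validation("footprint_radius_um must exceed the nucleus radius")
  if (p$hollow_interior_fraction < 0 || p$hollow_interior_fraction > 1)
    stop_validation("hollow_interior_fraction must lie in [0, 1]")
  if (any(unlist(p$noise) < 0)) stop_validation("noise parameters must be >= 0")
  structure(p, class = "synthetic_params")
}

#' Co-culture field parameter preset
#'
#' Convenience wrapper over [synthetic_params()] for co-culture fields:
#' well-spread adherent cells (wider spacing), no stromal compartment, no
#' planted membrane-marker coverage, and trogosomes planted per
#' `trogosome_spec`.
#'
#' @param ... overrides passed to [synthetic_params()].
#' @inheritParams synthetic_params
#' @return A `synthetic_params` object.
#' @export
coculture_params <- function(trogosome_spec = list(large_fraction = 0.3,
                                                   large_diameter_um = c(5.5, 7),
                                                   small_per_cell = c(0L, 2L),
                                                   small_diameter_um = c(1.5, 4)),
                             ...) {
  defaults <- list(image_size_px = c(840L, 840L),
                   pixel_size_um = 0.3,
                   n_tumor_cells = 100L,
                   min_spacing_um = 22,
                   nucleus_radius_um_mean = 3,
                   nucleus_radius_um_sd = 0.25,
                   region_mode = "footprint",
                   footprint_radius_um = 9.5,
                   coverage_spec = list(fraction = 0, hi = c(0, 0),
                                        lo = c(0, 0)),
                   autofluor = NULL,
                   trogosome_spec = trogosome_spec)
  args <- modifyList(defaults, list(...))
  do.call(synthetic_params, args)
}

#' Per-cell autofluorescence sampler and quantile of the generator's model
#'
#' The generator renders secondary-antibody-only control cells with a
#' per-cell autofluorescence level drawn from a log-normal law; these
#' functions expose that law (its sampler and analytic quantile) for
#' calibration checks of the control gate.
#'
#' @param n number of draws.
#' @param autofluor `list(meanlog, sdlog)` as in [synthetic_params()].
#' @export
rautofluor <- function(n, autofluor = list(meanlog = log(0.05), sdlog = 0.25)) {
  stats::rlnorm(n, autofluor$meanlog, autofluor$sdlog)
}

#' @rdname rautofluor
#' @param p probability in `[0, 1]`.
#' @export
qautofluor <- function(p, autofluor = list(meanlog = log(0.05), sdlog = 0.25)) {
  stats::qlnorm(p, autofluor$meanlog, autofluor$sdlog)
}

# ---- internal rendering helpers ---------------------------------------------

# Jittered hexagonal lattice of candidate centers (row, col), 1-based.
hex_lattice <- function(nr, nc, pitch, margin) {
  ys <- seq(margin, nr - margin, by = pitch * sqrt(3) / 2)
  if (!length(ys)) return(matrix(numeric(0), 0, 2))
  pts <- NULL
  for (i in seq_along(ys)) {
    off <- if (i %% 2 == 0) pitch / 2 else 0
    xs <- seq(margin + off, nc - margin, by = pitch)
    if (length(xs)) pts <- rbind(pts, cbind(row = ys[i], col = xs))
  }
  jit <- 0.1 * pitch
  pts + matrix(runif(2 * nrow(pts), -jit, jit), ncol = 2)
}

# Pixel set of a disk: (row, col) center, radius in px; clipped to raster.
disk_pixels <- function(nr, nc, row, col, radius) {
  r0 <- max(1L, as.integer(floor(row - radius)))
  r1 <- min(nr, as.integer(ceiling(row + radius)))
  c0 <- max(1L, as.integer(floor(col - radius)))
  c1 <- min(nc, as.integer(ceiling(col + radius)))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - row)^2, (cc - col)^2, "+")
  sel <- which(d2 <= radius^2)
  (rep(cc, each = length(rr))[sel] - 1L) * nr + rep(rr, length(cc))[sel]
}

# The N nearest pixels to a center, ties broken by raster index: a disk-like
# pixel set whose equivalent-circle diameter never exceeds the nominal one.
nearest_n_pixels <- function(nr, nc, row, col, n_px, radius_hint) {
  r <- radius_hint + 2
  repeat {
    r0 <- max(1L, as.integer(floor(row - r)))
    r1 <- min(nr, as.integer(ceiling(row + r)))
    c0 <- max(1L, as.integer(floor(col - r)))
    c1 <- min(nc, as.integer(ceiling(col + r)))
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - row)^2, (cc - col)^2, "+")
    idx <- (rep(cc, each = length(rr)) - 1L) * nr + rep(rr, length(cc))
    if (length(idx) >= n_px || (r0 == 1L && r1 == nr && c0 == 1L && c1 == nc)) {
      ord <- order(as.numeric(d2), idx)
      return(list(idx = idx[ord][seq_len(min(n_px, length(idx)))],
                  d2 = as.numeric(d2)[ord][seq_len(min(n_px, length(idx)))]))
    }
    r <- 2 * r
  }
}

apply_noise <- function(ch, noise) {
  nr <- nrow(ch); nc <- ncol(ch)
  if (noise$shading_amplitude > 0 && nc > 1)
    ch <- ch + noise$shading_amplitude *
      matrix((col(ch) - 1) / (nc - 1), nr, nc)
  if (noise$photons > 0)
    ch <- matrix(stats::rpois(length(ch), pmax(ch, 0) * noise$photons) /
                   noise$photons, nr, nc)
  if (noise$read_sd > 0)
    ch <- ch + matrix(stats::rnorm(length(ch), 0, noise$read_sd), nr, nc)
  quantize16(ch)
}

# ---- field generation -------------------------------------------------------

#' Generate a synthetic FFPE tumor field with ground truth
#'
#' Renders three channels — nuclei (blurred disks), tumor marker (sharp
#' tumor-region fill), trogocytic marker (per-cell exact pixel subsets at
#' the planted coverage over per-cell autofluorescence) — applies the noise
#' model, and returns the image together with exact pre-noise ground truth.
#' Deterministic for a fixed seed.
#'
#' @param params a [synthetic_params()] object.
#' @return `list(image, truth)`: an `mc_image` with roles
#'   `nuclei`/`tumor_marker`/`trogo_marker` and a `synthetic_truth` list
#'   (planted nuclei, territories raster, per-cell coverage and expression
#'   flags, autofluorescence levels, trogosome table, tumor-region mask).
#' @export
generate_ffpe_field <- function(params) {
  generate_field(params)
}

#' Generate a secondary-antibody-only control field
#'
#' Identical geometry and autofluorescence model, but no planted marker
#' signal: every cell's planted coverage is zero.
#'
#' @param params a [synthetic_params()] object.
#' @return As [generate_ffpe_field()].
#' @export
generate_control_field <- function(params) {
  params$coverage_spec <- list(fraction = 0, hi = c(0, 0), lo = c(0, 0))
  params$trogosome_spec <- NULL
  generate_field(params)
}

#' Generate a co-culture timecourse
#'
#' One field per timepoint, each with its own planted fraction of
#' trogosome-bearing cells and diameter distribution.
#'
#' @param params_list list of [synthetic_params()] / [coculture_params()]
#'   objects (one per timepoint, each with its own seed and `timepoint`).
#' @return Named list of `list(image, truth)` per timepoint.
#' @export
generate_coculture_timecourse <- function(params_list) {
  stopifnot(length(params_list) >= 1L)
  out <- lapply(params_list, generate_field)
  names(out) <- vapply(params_list, function(p)
    as.character(p$timepoint %||% NA_character_), character(1))
  out
}

generate_field <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  with_seed(params$seed, {
    nr <- params$image_size_px[1]; nc <- params$image_size_px[2]
    px <- params$pixel_size_um
    pitch <- params$min_spacing_um / px
    r_mean_px <- params$nucleus_radius_um_mean / px

    # tumor region (the footprint variant is built after center placement)
    region <- NULL
    reg_radius <- Inf
    if (params$region_mode == "disk") {
      reg_radius <- sqrt(params$tumor_region_fraction * nr * nc / pi)
      cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
      region <- (row(matrix(0, nr, nc)) - cy)^2 +
        (col(matrix(0, nr, nc)) - cx)^2 <= reg_radius^2
    } else if (params$region_mode == "all") {
      region <- matrix(TRUE, nr, nc)
    }

    # nucleus centers on a jittered hex lattice
    pts <- hex_lattice(nr, nc, pitch, margin = pitch / 2 + r_mean_px)
    if (is.finite(reg_radius)) {
      cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
      dreg <- sqrt((pts[, 1] - cy)^2 + (pts[, 2] - cx)^2)
      in_slots <- which(dreg < reg_radius - pitch / 2)
      out_slots <- which(dreg > reg_radius + 1.6 * r_mean_px + 2)
    } else {
      in_slots <- seq_len(nrow(pts))
      out_slots <- integer(0)
    }
    if (length(in_slots) < params$n_tumor_cells)
      stop_validation(paste0("cannot fit %d tumor cells (only %d lattice ",
                             "slots); enlarge the field, reduce the cell ",
                             "count or the spacing"),
                      params$n_tumor_cells, length(in_slots))
    if (length(out_slots) < params$n_stromal_cells)
      stop_validation("cannot fit %d stromal cells outside the tumor region",
                      params$n_stromal_cells)
    sel_in <- sort(sample(in_slots, params$n_tumor_cells))
    sel_out <- sort(sample(out_slots, params$n_stromal_cells))
    centers <- pts[c(sel_in, sel_out), , drop = FALSE]
    is_tumor_pt <- rep(c(TRUE, FALSE),
                       c(params$n_tumor_cells, params$n_stromal_cells))
    n_all <- nrow(centers)
    if (n_all == 0L)
      stop_validation("field has no cells; set n_tumor_cells >= 1")

    # radii, clipped so neighbouring disks stay disjoint
    radii <- pmax(0.3 * r_mean_px,
                  rnorm(n_all, r_mean_px, params$nucleus_radius_um_sd / px))
    if (n_all > 1L) {
      dmat <- as.matrix(stats::dist(centers))
      diag(dmat) <- Inf
      radii <- pmin(radii, apply(dmat, 1, min) / 2 - 1)
    }
    radii <- pmax(radii, 1.5)

    # planted nucleus raster, canonical labels
    raw <- matrix(0L, nr, nc)
    for (k in seq_len(n_all))
      raw[disk_pixels(nr, nc, centers[k, 1], centers[k, 2], radii[k])] <- k
    nuc_all <- nuclei_labels(raw)
    # map planted index -> canonical label via center pixel
    canon <- nuc_all$labels[cbind(round(centers[, 1]), round(centers[, 2]))]
    if (any(canon == 0L) || anyDuplicated(canon))
      stop_validation("internal: nucleus canonical relabeling failed")
    ord <- order(canon)   # planted indices in canonical order
    centers <- centers[ord, , drop = FALSE]
    radii <- radii[ord]
    is_tumor_pt <- is_tumor_pt[ord]

    if (params$region_mode == "footprint") {
      region <- matrix(FALSE, nr, nc)
      fr <- params$footprint_radius_um / px
      for (k in seq_len(n_all))
        region[disk_pixels(nr, nc, centers[k, 1], centers[k, 2], fr)] <- TRUE
    }

    nuclei_df <- data.frame(nucleus_id = seq_len(n_all),
                            centroid_x_px = centers[, 2] - 1,
                            centroid_y_px = centers[, 1] - 1,
                            radius_um = radii * px,
                            is_tumor = is_tumor_pt)

    # ground-truth territories of the tumor nuclei (pipeline's own rule)
    tumor_nuc <- keep_labels(nuc_all, which(is_tumor_pt))
    cells <- voronoi_territories(tumor_nuc, region)
    n_cells <- cells$n_cells
    terr <- cells$territories

    # planted coverage: exact pixel subsets
    cs <- params$coverage_spec
    n_hi <- round(cs$fraction * n_cells)
    hi_cells <- if (n_hi > 0) sample(n_cells, n_hi) else integer(0)
    target <- runif(n_cells, cs$lo[1], cs$lo[2])
    target[hi_cells] <- runif(n_hi, cs$hi[1], cs$hi[2])
    expressing <- seq_len(n_cells) %in% hi_cells

    marker <- matrix(0, nr, nc)
    af_level <- rep(NA_real_, n_cells)
    if (!is.null(params$autofluor)) {
      af_level <- rautofluor(n_cells, params$autofluor)
      for (k in seq_len(n_cells)) marker[terr == k] <- af_level[k]
    }
    planted_cov <- numeric(n_cells)
    terr_idx <- split(which(terr > 0L), terr[terr > 0L])
    for (k in seq_len(n_cells)) {
      pix <- terr_idx[[as.character(k)]]
      n_pos <- round(target[k] * length(pix))
      if (n_pos > 0)
        marker[sample(pix, n_pos)] <- params$marker_intensity
      planted_cov[k] <- n_pos / length(pix)
    }

    # trogosomes
    trog <- plant_trogosomes(params, terr, cells, nuclei_df, marker)
    marker <- trog$marker

    # channels
    nuc_ch <- matrix(0, nr, nc)
    nuc_ch[nuc_all$labels > 0L] <- params$nuclei_intensity
    if (params$n_debris > 0L) {
      free <- which(nuc_all$labels == 0L)
      for (d in seq_len(params$n_debris)) {
        ctr <- free[sample(length(free), 1L)]
        drow <- (ctr - 1L) %% nr + 1L; dcol <- (ctr - 1L) %/% nr + 1L
        ok <- sqrt((centers[, 1] - drow)^2 + (centers[, 2] - dcol)^2)
        if (min(ok) < max(radii) + params$debris_radius_px + 4) next
        nuc_ch[disk_pixels(nr, nc, drow, dcol, params$debris_radius_px)] <- 1
      }
    }
    nuc_ch <- as_raster(EBImage::gblur(nuc_ch, sigma = 1)) +
      params$background_level
    tum_ch <- params$background_level + params$tumor_intensity * region
    mk_ch <- params$background_level + marker

    img <- multichannel_image(
      list(apply_noise(nuc_ch, params$noise),
           apply_noise(tum_ch, params$noise),
           apply_noise(mk_ch, params$noise)),
      channel_roles = c(nuclei = 1L, tumor_marker = 2L, trogo_marker = 3L),
      pixel_size_um = px, source_id = params$source_id)

    truth <- structure(list(
      params = params,
      nuclei = nuclei_df,
      nucleus_raster = nuc_all$labels,
      tumor_region = region,
      territories = terr,
      cells = data.frame(cell_id = seq_len(n_cells),
                         planted_coverage = planted_cov,
                         planted_expressing = expressing,
                         autofluor_level = af_level,
                         area_px = cells$areas_px),
      trogosomes = trog$truth,
      planted_pct_large = trog$planted_pct_large),
      class = "synthetic_truth")
    list(image = img, truth = truth)
  })
}

# Plant trogosomes per spec; returns updated marker raster, truth table, and
# the planted percentage of cells holding a nominally large trogosome.
plant_trogosomes <- function(params, terr, cells, nuclei_df, marker) {
  spec <- params$trogosome_spec
  empty <- data.frame(cell_id = integer(0), centroid_x_px = numeric(0),
                      centroid_y_px = numeric(0),
                      nominal_diameter_um = numeric(0),
                      diameter_um = numeric(0), is_large = logical(0))
  if (is.null(spec) || cells$n_cells == 0L)
    return(list(marker = marker, truth = empty, planted_pct_large = NA_real_))
  n_cells <- cells$n_cells
  px <- params$pixel_size_um
  nr <- nrow(terr); nc <- ncol(terr)
  cutoff <- 5
  tumor_nuc <- nuclei_df[nuclei_df$is_tumor, , drop = FALSE]

  want <- vector("list", n_cells)   # nominal diameters per cell
  if (!is.null(spec$diameters_um)) {
    dv <- rep_len(spec$diameters_um, n_cells)
    for (k in seq_len(n_cells)) if (!is.na(dv[k])) want[[k]] <- dv[k]
    n_large_target <- sum(dv > cutoff, na.rm = TRUE)
  } else {
    lf <- spec$large_fraction %||% 0
    n_large <- round(lf * n_cells)
    large_cells <- if (n_large > 0) sample(n_cells, n_large) else integer(0)
    for (k in large_cells)
      want[[k]] <- runif(1, spec$large_diameter_um[1],
                         spec$large_diameter_um[2])
    spc <- spec$small_per_cell %||% c(0L, 0L)
    if (spc[2] > 0) {
      for (k in seq_len(n_cells)) {
        n_small <- sample(spc[1]:spc[2], 1L)
        if (n_small > 0)
          want[[k]] <- c(want[[k]],
                         runif(n_small, spec$small_diameter_um[1],
                               spec$small_diameter_um[2]))
      }
    }
    n_large_target <- length(large_cells)
  }

  rows <- vector("list", 0L)
  for (k in seq_len(n_cells)) {
    diams <- want[[k]]
    if (is.null(diams)) next
    diams <- sort(diams, decreasing = TRUE)   # place the large one first
    tmask <- terr == k
    rng <- which(tmask, arr.ind = TRUE)
    r0 <- max(1L, min(rng[, 1]) - 2L); r1 <- min(nr, max(rng[, 1]) + 2L)
    c0 <- max(1L, min(rng[, 2]) - 2L); c1 <- min(nc, max(rng[, 2]) + 2L)
    inner <- as_raster(EBImage::distmap(tmask[r0:r1, c0:c1] * 1L))
    nuc <- tumor_nuc[k, ]
    placed <- NULL
    for (d_nom in diams) {
      R <- d_nom / 2 / px
      crow <- (r0:r1); ccol <- (c0:c1)
      dn <- sqrt(outer((crow - (nuc$centroid_y_px + 1))^2,
                       (ccol - (nuc$centroid_x_px + 1))^2, "+"))
      # whole sphere inside the territory; centroid (not the whole sphere)
      # clear of the nucleus, as trogosomes sit beside and deform the nucleus
      elig <- inner > R + 1 & dn >= nuc$radius_um / px + 2
      if (!is.null(placed)) {
        for (j in seq_len(nrow(placed))) {
          dp <- sqrt(outer((crow - placed[j, 1])^2,
                           (ccol - placed[j, 2])^2, "+"))
          elig <- elig & dp >= R + placed[j, 3] + 2
        }
      }
      cand <- which(elig)
      if (!length(cand)) {
        if (d_nom > cutoff)
          stop_validation(paste0("cannot place a %.2f um trogosome inside ",
                                 "cell %d; enlarge spacing or reduce ",
                                 "diameters"), d_nom, k)
        next   # small trogosome silently skipped, not recorded
      }
      pick <- cand[sample(length(cand), 1L)]
      prow <- (pick - 1L) %% length(crow) + r0
      pcol <- (pick - 1L) %/% length(crow) + c0
      n_px <- max(5L, floor(pi * R^2))
      np <- nearest_n_pixels(nr, nc, prow, pcol, n_px, R)
      r_eff <- sqrt(length(np$idx) / pi)
      hollow <- np$d2 <= (0.7 * r_eff)^2
      marker[np$idx[hollow]] <- params$hollow_interior_fraction *
        params$marker_intensity
      marker[np$idx[!hollow]] <- params$marker_intensity
      d_ach <- 2 * sqrt(length(np$idx) / pi) * px
      placed <- rbind(placed, c(prow, pcol, r_eff))
      rows[[length(rows) + 1L]] <-
        data.frame(cell_id = k, centroid_x_px = pcol - 1,
                   centroid_y_px = prow - 1, nominal_diameter_um = d_nom,
                   diameter_um = d_ach, is_large = d_ach > cutoff)
    }
  }
  truth <- if (length(rows)) do.call(rbind, rows) else empty
  list(marker = marker, truth = truth,
       planted_pct_large = 100 * n_large_target / n_cells)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_truth> %d nuclei (%d tumor), %d cells, ",
                     "%d trogosome(s)\n"),
              nrow(x$nuclei), sum(x$nuclei$is_tumor), nrow(x$cells),
              nrow(x$trogosomes)))
  invisible(x)
}

#' Write a synthetic field and its ground truth to disk
#'
#' The image goes to a 16-bit multi-page TIFF (re-read bit-exactly), the
#' planted nucleus raster to a label TIFF, the per-cell and per-trogosome
#' ground truth to CSV, and the generation parameters to JSON.
#'
#' @param field a `list(image, truth)` from the generators.
#' @param dir output directory (created if needed).
#' @param stem file name stem; defaults to the image's `source_id`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_field <- function(field, dir, stem = NULL) {
  stem <- stem %||% field$image$source_id
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(image = file.path(dir, paste0(stem, ".tif")),
             labels = file.path(dir, paste0(stem, "_nuclei_labels.tif")),
             cells = file.path(dir, paste0(stem, "_cells_truth.csv")),
             trogosomes = file.path(dir, paste0(stem, "_trogosomes_truth.csv")),
             params = file.path(dir, paste0(stem, "_params.json")))
  write_multichannel(field$image, paths[["image"]])
  write_label_image(field$truth$nucleus_raster, paths[["labels"]])
  write_table(field$truth$cells, paths[["cells"]])
  write_table(field$truth$trogosomes, paths[["trogosomes"]])
  jsonlite::write_json(field$truth$params[setdiff(names(field$truth$params),
                                                  "coverage_spec")],
                       paths[["params"]], auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(paths)
}
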