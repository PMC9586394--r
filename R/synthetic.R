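# Seeded generator of thermogram-like images. The images emulate frontal
# breast thermograms: a smooth warm-body background with low-frequency
# intensity blobs, two overlapping warm elliptical regions in the lower half
# of the frame (the breast area, which is the segmentation target), and —
# for the "abnormal" class — one compact bright hotspot inside the breast
# region, mimicking the local temperature rise of vascularized lesions.

gaussian_bump <- function(H, W, cy, cx, sy, sx, amp) {
  ry <- ((seq_len(H) - cy) / sy)^2
  rx <- ((seq_len(W) - cx) / sx)^2
  amp * exp(-(outer(ry, rx, "+")) / 2)
}

ellipse_mask <- function(H, W, cy, cx, ry, rx) {
  yy <- ((seq_len(H) - cy) / ry)^2
  xx <- ((seq_len(W) - cx) / rx)^2
  outer(yy, xx, "+") <= 1
}

#' Generate one synthetic thermogram sample
#'
#' Deterministic given `(seed, label, size)`. The image is a vertical
#' thermal gradient plus five low-frequency Gaussian intensity blobs, two
#' overlapping warm ellipses in the lower image half (+0.2 over background;
#' their union is the breast mask), and for `label = "abnormal"` one compact
#' bright Gaussian hotspot (sigma 3-5 px at the default 64x64 size,
#' amplitude +0.25) centred inside the mask. Values are clipped to `[0, 1]`.
#'
#' @param seed integer seed.
#' @param label `"normal"` or `"abnormal"`.
#' @param size `c(H, W)`, each >= 32.
#' @return list of class `synthetic_sample`: `image` (H x W in `[0, 1]`),
#'   `mask` (H x W 0/1), `label`, `seed`, `metadata` (generator parameters).
#' @export
generate_sample <- function(seed, label = c("normal", "abnormal"),
                            size = c(64L, 64L)) {
  label <- match.arg(label)
  H <- as.integer(size[1]); W <- as.integer(size[2])
  if (H < 32L || W < 32L) stop_config("size must be at least 32x32")
  with_seed(seed * 2L + (label == "abnormal"), {
    img <- matrix(rep(0.20 + 0.25 * (seq_len(H) - 1) / (H - 1), W), H, W)
    blobs <- lapply(seq_len(5L), function(i) {
      list(cy = stats::runif(1, 1, H), cx = stats::runif(1, 1, W),
           s = stats::runif(1, 0.10, 0.25) * min(H, W),
           amp = stats::runif(1, 0.02, 0.07))
    })
    for (b in blobs) img <- img + gaussian_bump(H, W, b$cy, b$cx, b$s, b$s,
                                                b$amp)
    # two overlapping warm ellipses (left/right breast) in the lower half
    ell <- list(
      list(cy = stats::runif(1, 0.58, 0.66) * H,
           cx = stats::runif(1, 0.30, 0.36) * W,
           ry = stats::runif(1, 0.18, 0.24) * H,
           rx = stats::runif(1, 0.17, 0.23) * W),
      list(cy = stats::runif(1, 0.58, 0.66) * H,
           cx = stats::runif(1, 0.64, 0.70) * W,
           ry = stats::runif(1, 0.18, 0.24) * H,
           rx = stats::runif(1, 0.17, 0.23) * W))
    mask <- ellipse_mask(H, W, ell[[1]]$cy, ell[[1]]$cx, ell[[1]]$ry,
                         ell[[1]]$rx) |
      ellipse_mask(H, W, ell[[2]]$cy, ell[[2]]$cx, ell[[2]]$ry, ell[[2]]$rx)
    img <- img + 0.2 * mask
    hotspot <- NULL
    if (label == "abnormal") {
      # rejection-sample the hotspot placement so the abnormal contract holds
      # by construction: a disc of >= 20 px inside the mask whose mean
      # intensity exceeds the mask mean by >= 0.15
      for (try in seq_len(200L)) {
        e <- ell[[sample.int(2L, 1L)]]
        cand <- list(
          cy = e$cy + stats::runif(1, -0.3, 0.3) * e$ry,
          cx = e$cx + stats::runif(1, -0.3, 0.3) * e$rx,
          sigma = stats::runif(1, 2.6, 5 * max(1, min(H, W) / 64)),
          amp = 0.25)
        bump <- gaussian_bump(H, W, cand$cy, cand$cx, cand$sigma,
                              cand$sigma, cand$amp)
        trial <- pmin(pmax(img + bump, 0), 1)
        disc <- ellipse_mask(H, W, cand$cy, cand$cx, cand$sigma, cand$sigma) &
          mask
        if (sum(disc) >= 20L &&
            mean(trial[disc]) - mean(trial[mask]) >= 0.15) {
          hotspot <- cand
          img <- img + bump
          break
        }
      }
      if (is.null(hotspot))
        stop("internal error: could not place a hotspot satisfying the contract")
    }
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = img, mask = mask * 1L, label = label,
                   seed = seed,
                   metadata = list(size = c(H, W), blobs = blobs,
                                   ellipses = ell, hotspot = hotspot)),
              class = "synthetic_sample")
  })
}

#' Generate a dataset of synthetic thermograms on disk
#'
#' Writes `n_per_class` samples per class as 8-bit grayscale PNGs with 0/255
#' mask PNGs, plus a CSV manifest with columns `image, mask, label,
#' partition`. Per class, the validation and test partitions receive
#' `floor(n * ratio / 100)` samples each and the remainder goes to training;
#' assignment is randomized but seeded.
#'
#' @param n_per_class samples per class.
#' @param seed integer seed.
#' @param ratio train/val/test percentages summing to 100.
#' @param out_dir output directory (created if needed).
#' @param size image size `c(H, W)`.
#' @return data frame of class `dataset_manifest` (invisibly written to
#'   `out_dir/manifest.csv`).
#' @export
generate_dataset <- function(n_per_class, seed = 1L, ratio = c(70, 15, 15),
                             out_dir, size = c(64L, 64L)) {
  if (length(ratio) != 3L || any(ratio <= 0) || sum(ratio) != 100)
    stop_usage("ratio must be three positive percentages summing to 100")
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- list()
  for (label in c("normal", "abnormal")) {
    parts <- split_partitions(n_per_class, ratio, seed + (label == "abnormal"))
    for (i in seq_len(n_per_class)) {
      s <- generate_sample(seed * 100000L + i, label, size)
      img_path <- file.path(out_dir, sprintf("%s_%04d.png", label, i))
      mask_path <- file.path(out_dir, sprintf("%s_%04d_mask.png", label, i))
      png::writePNG(s$image, img_path)
      png::writePNG(s$mask * 1.0, mask_path)
      rows[[length(rows) + 1L]] <- data.frame(
        image = img_path, mask = mask_path, label = label,
        partition = parts[i], stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  class(manifest) <- c("dataset_manifest", class(manifest))
  manifest
}

# per-class partition labels: floor(n*r/100) for val/test, remainder to train
split_partitions <- function(n, ratio, seed) {
  n_val <- floor(n * ratio[2] / 100)
  n_test <- floor(n * ratio[3] / 100)
  n_train <- n - n_val - n_test
  parts <- c(rep("train", n_train), rep("val", n_val), rep("test", n_test))
  with_seed(seed, sample(parts))
}

#' Read a dataset manifest
#'
#' @param path manifest CSV written by [generate_dataset()].
#' @return `dataset_manifest` data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_usage("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image", "mask", "label", "partition")
  if (!all(need %in% names(m)))
    stop_data("manifest must have columns ", paste(need, collapse = ", "))
  class(m) <- c("dataset_manifest", class(m))
  m
}

#' Load manifest images into arrays
#'
#' @param manifest a `dataset_manifest` (or path to one).
#' @param partition partition to load (`NULL` for all rows).
#' @return list with `x` (`H x W x N` image array), `masks` (`H x W x N`
#'   0/1), `labels` (character vector).
#' @export
load_partition <- function(manifest, partition = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (!is.null(partition)) manifest <- manifest[manifest$partition == partition, ]
  if (nrow(manifest) == 0L) stop_usage("partition is empty")
  imgs <- lapply(manifest$image, png::readPNG)
  masks <- lapply(manifest$mask, function(p) (png::readPNG(p) > 0.5) * 1L)
  H <- nrow(imgs[[1]]); W <- ncol(imgs[[1]])
  x <- array(unlist(imgs), c(H, W, length(imgs)))
  m <- array(unlist(masks), c(H, W, length(masks)))
  list(x = x, masks = m, labels = manifest$label)
}

#' Generate max-pool collision matrices
#'
#' Builds `count` pairwise-distinct matrices that share one identical square
#' max-pool output (default 2x2 kernel, stride 2 on a 4x4 matrix): within
#' each pooling window the maximum value is fixed across the set while its
#' position and the sub-maximal cells are randomized. Rejection sampling
#' additionally guarantees that a VPB with identity 1x1 convolutions maps
#' the matrices to pairwise-distinct outputs, realizing the extra
#' discriminative power of directional pooling.
#'
#' @param count number of matrices (>= 2).
#' @param seed integer seed.
#' @param size matrix size `c(H, W)`.
#' @param pool square pooling kernel/stride (`k`; stride = k).
#' @return list of class `collision_set`: `matrices`, `pooled` (the shared
#'   square max-pool output), `vpb_outputs`.
#' @export
make_maxpool_collisions <- function(count = 3L, seed = 1L, size = c(4L, 4L),
                                    pool = 2L) {
  if (count < 2L) stop_config("count must be >= 2")
  k <- as.integer(pool)
  H <- as.integer(size[1]); W <- as.integer(size[2])
  sq <- pool_spec("max", c(k, k), c(k, k), "same_ceil")
  vp <- identity_vpb_params(1L, k, k)
  with_seed(seed, {
    Ho <- ceiling(H / k); Wo <- ceiling(W / k)
    maxima <- matrix(stats::runif(Ho * Wo, 0.6, 1.0), Ho, Wo)
    gen_one <- function() {
      m <- matrix(0, H, W)
      for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
        rs <- ((i - 1L) * k + 1L):min(i * k, H)
        cs <- ((j - 1L) * k + 1L):min(j * k, W)
        vals <- stats::runif(length(rs) * length(cs), 0, 0.9 * maxima[i, j])
        pos <- sample.int(length(vals), 1L)
        vals[pos] <- maxima[i, j]
        m[rs, cs] <- matrix(vals, length(rs), length(cs))
      }
      m
    }
    mats <- list()
    outs <- list()
    guard <- 0L
    while (length(mats) < count) {
      guard <- guard + 1L
      if (guard > 1000L) stop("collision generator failed to converge")
      m <- gen_one()
      o <- vpb_forward(m, vp)
      dup <- any(vapply(mats, function(z) identical(z, m), logical(1))) ||
        any(vapply(outs, function(z) isTRUE(all.equal(z, o, tolerance = 1e-10)),
                   logical(1)))
      if (!dup) {
        mats[[length(mats) + 1L]] <- m
        outs[[length(outs) + 1L]] <- o
      }
    }
    structure(list(matrices = mats,
                   pooled = pool_apply(mats[[1]], sq),
                   vpb_outputs = outs),
              class = "collision_set")
  })
}
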