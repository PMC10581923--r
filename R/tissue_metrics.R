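# Tissue colorimetry and histomorphometry. Operates on measurement tables
# exported from image/slide annotation software; segmentation itself is out
# of scope. Colors are mean RGB values over the segmented organ pixels,
# converted to CIELAB (sRGB companding per IEC 61966-2-1, D65 white, 2 deg
# observer); color differences use the Euclidean CIE76 delta-E.

srgb_to_xyz_matrix <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                               0.2126729, 0.7151522, 0.0721750,
                               0.0193339, 0.1191920, 0.9503041),
                             nrow = 3, byrow = TRUE)
d65_white <- c(X = 0.95047, Y = 1.00000, Z = 1.08883)

#' Convert mean RGB values to CIELAB
#'
#' Standard pipeline: 8-bit sRGB -> linear RGB (piecewise companding) ->
#' XYZ (D65, 2 degree observer) -> CIELAB.
#'
#' @param r,g,b channel values in `[0, 255]`; vectors of equal length.
#'   Alternatively pass a data frame with columns `r`, `g`, `b` as `r`.
#' @return A matrix with columns `L`, `a`, `b`.
#' @export
rgb_to_lab <- function(r, g = NULL, b = NULL) {
  if (is.data.frame(r)) {
    stop_if(!all(c("r", "g", "b") %in% names(r)),
            "data frame input needs columns r, g, b")
    g <- r$g; b <- r$b; r <- r$r
  }
  ch <- cbind(r, g, b)
  stop_if(any(ch < 0) || any(ch > 255), "RGB channels must lie in [0, 255]")
  u <- ch / 255
  lin <- ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(srgb_to_xyz_matrix)
  xyz_n <- sweep(xyz, 2, d65_white, "/")
  eps <- (6 / 29)^3
  f <- ifelse(xyz_n > eps, xyz_n^(1 / 3), xyz_n / (3 * (6 / 29)^2) + 4 / 29)
  out <- cbind(L = 116 * f[, 2] - 16,
               a = 500 * (f[, 1] - f[, 2]),
               b = 200 * (f[, 2] - f[, 3]))
  rownames(out) <- NULL
  out
}

#' CIE76 color distance
#'
#' Euclidean distance between CIELAB triples.
#'
#' @param x,y numeric length-3 CIELAB triples, or matrices of matching rows.
#' @return Delta-E value(s).
#' @export
color_distance <- function(x, y) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  sqrt(rowSums((x - y)^2))
}

#' Pairwise delta-E matrix for a set of color samples
#'
#' @param colors data frame with columns `sample_id`, `r`, `g`, `b`.
#' @return A symmetric matrix of CIE76 distances, dimnames = sample ids.
#' @export
delta_e_matrix <- function(colors) {
  lab <- rgb_to_lab(colors)
  n <- nrow(lab)
  out <- matrix(0, n, n, dimnames = list(colors$sample_id, colors$sample_id))
  for (i in seq_len(n)) {
    out[i, ] <- color_distance(matrix(lab[i, ], n, 3, byrow = TRUE), lab)
  }
  out
}

#' Lamina propria fraction of the villus
#'
#' @param lamina_propria_area,villus_area areas in the same units (um^2);
#'   `villus_area > 0`, `lamina_propria_area <= villus_area`.
#' @return Fraction in `[0, 1]`.
#' @export
lamina_propria_fraction <- function(lamina_propria_area, villus_area) {
  stop_if(any(villus_area <= 0), "villus_area must be positive")
  stop_if(any(lamina_propria_area < 0) ||
            any(lamina_propria_area > villus_area),
          "lamina propria area must lie in [0, villus_area]")
  lamina_propria_area / villus_area
}

#' Goblet-cell mucin density per villus area
#'
#' Counts per mm^2 of villus area, with the area supplied in um^2
#' (1 mm^2 = 1e6 um^2).
#'
#' @param count mucin count (acidic, neutral, mixed, or total), >= 0.
#' @param villus_area_um2 villus area in um^2, > 0.
#' @return Density in counts per mm^2.
#' @export
mucin_density <- function(count, villus_area_um2) {
  stop_if(any(villus_area_um2 <= 0), "villus_area must be positive")
  stop_if(any(count < 0), "counts must be non-negative")
  count / (villus_area_um2 / 1e6)
}

#' Summarise villus measurements
#'
#' Computes, per row of a villus-measurement table, the lamina propria
#' fraction and the per-kind mucin densities, then averages by a grouping
#' column when present.
#'
#' @param villi data frame with columns `villus_area`, `lamina_propria_area`
#'   (um^2) and count columns `acidic`, `neutral`, `mixed`; optional grouping
#'   column `group` (e.g. diet or slide).
#' @return A data frame of per-group means.
#' @export
villus_summary <- function(villi) {
  need <- c("villus_area", "lamina_propria_area", "acidic", "neutral", "mixed")
  stop_if(!all(need %in% names(villi)),
          paste("villus table needs columns:", paste(need, collapse = ", ")))
  per <- data.frame(
    lamina_propria_fraction = lamina_propria_fraction(
      villi$lamina_propria_area, villi$villus_area),
    acidic_density = mucin_density(villi$acidic, villi$villus_area),
    neutral_density = mucin_density(villi$neutral, villi$villus_area),
    mixed_density = mucin_density(villi$mixed, villi$villus_area))
  per$total_density <- per$acidic_density + per$neutral_density +
    per$mixed_density
  if ("group" %in% names(villi)) {
    out <- aggregate(per, by = list(group = villi$group), FUN = mean)
  } else {
    out <- as.data.frame(t(colMeans(per)))
  }
  out
}
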