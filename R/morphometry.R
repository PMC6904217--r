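#' Eye volume from radius
#'
#' Volume of the spherical eye, 4/3 pi r^3.
#'
#' @param r_eye Eye radius (mm), > 0.
#' @return Volume (mm^3).
#' @export
eye_volume <- function(r_eye) {
  stopifnot(all(r_eye > 0))
  4 / 3 * pi * r_eye^3
}

#' Volume of intersection of two spheres
#'
#' The sphere-sphere "lens" volume for center displacement `d`:
#' in the lens regime (`|r1 - r2| <= d <= r1 + r2`)
#' \deqn{V = \pi (r_1 + r_2 - d)^2 (d^2 + 2d(r_1 + r_2) - 3(r_1 - r_2)^2) / (12 d),}
#' the full smaller sphere when one sphere contains the other
#' (`d < |r1 - r2|`), and 0 when disjoint (`d > r1 + r2`). Symmetric in
#' `(r1, r2)` and continuous across the regime boundaries.
#'
#' @param r1,r2 Sphere radii (mm), > 0.
#' @param d Distance between centers (mm), >= 0.
#' @return Intersection volume (mm^3).
#' @export
lens_volume <- function(r1, r2, d) {
  if (any(c(r1, r2) <= 0) || any(d < 0)) stop("radii must be > 0, d >= 0")
  n <- max(length(r1), length(r2), length(d))
  r1 <- rep_len(r1, n); r2 <- rep_len(r2, n); d <- rep_len(d, n)
  out <- numeric(n)
  small <- pmin(r1, r2)
  contained <- d <= abs(r1 - r2)
  disjoint <- d >= r1 + r2
  lens <- !contained & !disjoint
  out[contained] <- 4 / 3 * pi * small[contained]^3
  out[lens] <- pi * (r1[lens] + r2[lens] - d[lens])^2 *
    (d[lens]^2 + 2 * d[lens] * (r1[lens] + r2[lens]) -
       3 * (r1[lens] - r2[lens])^2) / (12 * d[lens])
  out
}

#' Ocular geometry parameter set
#'
#' Radii and center displacements of the circles/spheres describing the
#' eye, the inner retinal surface, the choroid rete mirabile (CRM), and the
#' optic nerve (NO), as measured on mid-coronal sections.
#'
#' @param r_eye,r_retina,r_crm,r_no Radii (mm); `r_crm`/`r_no` may be `NA`
#'   when the structure is absent.
#' @param d_eye_retina,d_eye_crm,d_crm_no Center displacements (mm).
#' @return Object of class `"eye_geometry"` (named list).
#' @export
eye_geometry <- function(r_eye, r_retina, d_eye_retina,
                         r_crm = NA, r_no = NA, d_eye_crm = NA,
                         d_crm_no = NA) {
  stopifnot(r_eye > 0, r_retina > 0, d_eye_retina >= 0)
  if (r_retina >= r_eye) stop("r_retina must be smaller than r_eye")
  structure(list(r_eye = r_eye, r_retina = r_retina,
                 d_eye_retina = d_eye_retina, r_crm = r_crm, r_no = r_no,
                 d_eye_crm = d_eye_crm, d_crm_no = d_crm_no),
            class = "eye_geometry")
}

#' Retinal volume from ocular geometry
#'
#' Eye volume minus the intersection volume between the eye sphere and the
#' displaced sphere bounded by the inner retinal surface.
#'
#' @param g An [eye_geometry()].
#' @return Volume (mm^3).
#' @export
retina_volume <- function(g) {
  stopifnot(inherits(g, "eye_geometry"))
  eye_volume(g$r_eye) - lens_volume(g$r_eye, g$r_retina, g$d_eye_retina)
}

#' Choroid rete mirabile volume from ocular geometry
#'
#' Assumes a semilunar CRM: half of the CRM sphere volume after subtracting
#' its intersections with the eye sphere and with the optic-nerve sphere
#' that penetrates it.
#'
#' @param g An [eye_geometry()] with `r_crm`, `r_no`, `d_eye_crm`,
#'   `d_crm_no` set (`r_no = 0` for no optic-nerve correction).
#' @return Volume (mm^3).
#' @export
crm_volume <- function(g) {
  stopifnot(inherits(g, "eye_geometry"))
  if (is.na(g$r_crm) || g$r_crm <= 0) stop("r_crm required")
  v <- 4 / 3 * pi * g$r_crm^3 -
    lens_volume(g$r_crm, g$r_eye, g$d_eye_crm) -
    (if (!is.na(g$r_no) && g$r_no > 0)
       lens_volume(g$r_crm, g$r_no, g$d_crm_no) else 0)
  v <- v / 2
  if (v < 0) stop("inconsistent geometry: negative CRM volume")
  v
}

#' Maximal retinal thickness from angular measurement positions
#'
#' The study convention: maximal thickness is the maximum perpendicular
#' thickness over the six standard positions (20, 30, 40 degrees on each
#' side of the optic nerve).
#'
#' @param measurements Numeric vector of per-position thicknesses (um);
#'   `NA` allowed.
#' @return Maximum thickness (um).
#' @export
max_retinal_thickness <- function(measurements) {
  if (all(is.na(measurements))) return(NA_real_)
  max(measurements, na.rm = TRUE)
}

#' Absolute layer thicknesses from total thickness and relative fractions
#'
#' Absolute layer thickness is the in vivo (ultrasound) total thickness
#' multiplied by the relative layer fraction measured on histology,
#' avoiding shrinkage bias in the absolute histological values.
#'
#' @param total_um Total retinal thickness (um).
#' @param fractions Named numeric vector of relative layer fractions
#'   (normalized to sum to 1 if they do not already).
#' @return Named vector of absolute layer thicknesses (um).
#' @export
layer_thickness_absolute <- function(total_um, fractions) {
  stopifnot(total_um > 0, all(fractions >= 0), sum(fractions) > 0)
  total_um * fractions / sum(fractions)
}

#' Quadratic averaged intensity (speckle-variance angiography)
#'
#' Per-pixel temporal root-mean-square deviation from the arithmetic
#' temporal mean: D(x, y) = sqrt(mean_t (I(x, y, t) - Ibar(x, y))^2), the
#' statistic that highlights dynamic blood speckle against static tissue.
#' D is zero exactly for temporally constant pixels and is invariant to
#' adding a per-pixel temporal constant.
#'
#' @param stack Numeric array indexed (x, y, t) or (x, y, z, t); the last
#'   dimension is time with N >= 2 frames.
#' @return Array of D over the non-temporal dimensions.
#' @export
quadratic_average <- function(stack) {
  dm <- dim(stack)
  if (is.null(dm) || !(length(dm) %in% c(3L, 4L))) {
    stop("stack must be an array indexed (x, y, t) or (x, y, z, t)")
  }
  if (any(!is.finite(stack))) stop("non-finite intensities")
  N <- dm[length(dm)]
  if (N < 2L) stop("need N >= 2 frames for temporal statistics")
  spat <- prod(dm[-length(dm)])
  m <- matrix(stack, spat, N)
  mu <- rowMeans(m)
  D <- sqrt(rowMeans((m - mu)^2))
  array(D, dm[-length(dm)])
}

#' Cavalieri volume estimator
#'
#' Unbiased volume from equally spaced parallel sections carrying a
#' systematic uniform point grid: V = section spacing x area-per-point x
#' total point hits.
#'
#' @param spacing Distance between sections (mm), > 0.
#' @param a_p Area associated with each grid point (mm^2), > 0.
#' @param point_hits Integer vector of point counts per section (>= 2
#'   sections).
#' @return Volume (mm^3).
#' @export
cavalieri_volume <- function(spacing, a_p, point_hits) {
  stopifnot(spacing > 0, a_p > 0)
  if (length(point_hits) < 2L) stop("need >= 2 sections")
  if (any(point_hits < 0)) stop("negative point count")
  spacing * a_p * sum(point_hits)
}

#' Surface area from test-line intersections
#'
#' Stereological surface estimator SA = 2 x I x V / L from the number of
#' intersections I of isotropic test lines of total length L with the
#' surface, and the reference volume V.
#'
#' @param V Reference volume (mm^3), >= 0.
#' @param L Total test-line length (mm), > 0.
#' @param I_int Number of intersections, >= 0.
#' @return Surface area (mm^2).
#' @export
surface_area_estimate <- function(V, L, I_int) {
  stopifnot(L > 0, V >= 0, I_int >= 0)
  2 * I_int * V / L
}

#' Pre-retinal capillarization density
#'
#' Volume of pre-retinal capillaries per retinal surface area
#' (mm^3 per mm^2). When point-count volume densities are supplied instead
#' of an absolute capillary volume, V(PRC) is first computed as volume
#' density x retinal volume.
#'
#' @param V_prc Pre-retinal capillary volume (mm^3), or `NULL` when
#'   `density` and `V_retina` are given.
#' @param SA_retina Retinal surface area (mm^2), > 0.
#' @param density Optional capillary volume density (dimensionless) from
#'   test-point counts.
#' @param V_retina Optional retinal reference volume (mm^3).
#' @return Density (mm^3 mm^-2), with the derived `V_prc` as an attribute
#'   when computed from a volume density.
#' @export
preretinal_capillarization <- function(V_prc = NULL, SA_retina,
                                       density = NULL, V_retina = NULL) {
  if (SA_retina <= 0) stop("SA_retina must be > 0")
  if (is.null(V_prc)) {
    if (is.null(density) || is.null(V_retina)) {
      stop("supply V_prc, or density together with V_retina")
    }
    V_prc <- density * V_retina
    out <- V_prc / SA_retina
    attr(out, "V_prc") <- V_prc
    return(out)
  }
  V_prc / SA_retina
}

#' Root effect from paired absorbance spectra
#'
#' Unmixes each whole-spectrum absorbance measurement (480-700 nm) into
#' oxy-, deoxy- and met-haemoglobin fractions by non-negative least squares
#' against basis spectra, computes the functional saturation
#' S = oxy / (oxy + deoxy) per sample (metHb excluded from the functional
#' pool), and reports the Root effect as the percent desaturation at pH 5.5
#' relative to pH 8.5: 100 (S_8.5 - S_5.5) / S_8.5, clamped to [0, 100].
#' `form = "difference"` instead reports 100 (S_8.5 - S_5.5).
#'
#' @param sample_ph55,sample_ph85 Numeric absorbance vectors on the shared
#'   wavelength grid.
#' @param basis Matrix or data frame with columns `oxy`, `deoxy`, `met`
#'   (basis spectra on the same grid).
#' @param form `"ratio"` (default) or `"difference"`.
#' @return Root effect (percent), with per-sample fractions and saturations
#'   as attributes.
#' @export
root_effect <- function(sample_ph55, sample_ph85, basis,
                        form = c("ratio", "difference")) {
  form <- match.arg(form)
  B <- as.matrix(basis[, c("oxy", "deoxy", "met")])
  if (nrow(B) != length(sample_ph55) || nrow(B) != length(sample_ph85)) {
    stop("sample and basis spectra must share the wavelength grid")
  }
  if (kappa(crossprod(B)) > 1e8) stop("basis spectra are collinear")
  unmix <- function(y) {
    f <- pracma::lsqnonneg(B, as.numeric(y))$x
    stats::setNames(f, c("oxy", "deoxy", "met"))
  }
  f55 <- unmix(sample_ph55); f85 <- unmix(sample_ph85)
  sat <- function(f) {
    tot <- f["oxy"] + f["deoxy"]
    if (tot <= 0) NA_real_ else unname(f["oxy"] / tot)
  }
  s55 <- sat(f55); s85 <- sat(f85)
  if (is.na(s85) || s85 <= 0) stop("saturation at pH 8.5 is zero: Root effect undefined")
  re <- if (form == "ratio") 100 * (s85 - s55) / s85 else 100 * (s85 - s55)
  re <- min(max(re, 0), 100)
  attr(re, "fractions") <- rbind(ph5.5 = f55, ph8.5 = f85)
  attr(re, "saturation") <- c(ph5.5 = s55, ph8.5 = s85)
  re
}
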