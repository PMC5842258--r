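#' Force-displacement curve from a three-point bend test
#'
#' Constructs a validated bend-curve object. Displacement must be strictly
#' increasing; force is kept in the instrument's recorded units (no gravity
#' or probe-speed conversion is applied anywhere in the package).
#'
#' @param displacement Numeric vector of probe displacements (mm), strictly
#'   increasing, length >= 3.
#' @param force Numeric vector of recorded forces, same length.
#' @return An object of class `bend_curve`: a data.frame with columns
#'   `displacement` and `force`.
#' @export
bend_curve <- function(displacement, force) {
  displacement <- as.numeric(displacement)
  force <- as.numeric(force)
  if (length(displacement) != length(force)) {
    stop("displacement and force must have equal length")
  }
  if (length(displacement) < 3L) {
    stop("a bend curve needs at least 3 points")
  }
  if (anyNA(displacement) || anyNA(force)) {
    stop("bend curve must not contain missing values")
  }
  if (any(diff(displacement) <= 0)) {
    stop("displacement must be strictly increasing")
  }
  structure(data.frame(displacement = displacement, force = force),
            class = c("bend_curve", "data.frame"))
}

#' Stem cross-section geometry
#'
#' Holds the cross-sectional areas measured on the basal stem transverse and
#' derives the whole-stem diameter `D2` and hollow diameter `d1a` from them.
#' Diameters are always derived from areas (equivalent-circle diameter),
#' never measured directly.
#'
#' @param whole_area Whole stem cross-sectional area (mm^2).
#' @param hollow_area Central hollow area (mm^2), `0 <= hollow_area < whole_area`.
#' @param parenchyma_area Parenchyma (pith) area (mm^2), optional.
#' @param cortex_thickness Outer cortex thickness (mm), optional.
#' @return An object of class `stem_geometry` with fields `whole_area`,
#'   `hollow_area`, `parenchyma_area`, `cortex_thickness`, and derived
#'   diameters `D2` and `d1a` (mm).
#' @export
stem_geometry <- function(whole_area, hollow_area = 0,
                          parenchyma_area = NA_real_,
                          cortex_thickness = NA_real_) {
  if (!is.finite(whole_area) || whole_area < 0) stop("whole_area must be >= 0")
  if (!is.finite(hollow_area) || hollow_area < 0) stop("hollow_area must be >= 0")
  if (hollow_area >= whole_area && whole_area > 0) {
    stop("hollow_area must be strictly less than whole_area")
  }
  D2 <- diameter_from_area(whole_area)
  d1a <- diameter_from_area(hollow_area)
  structure(list(whole_area = whole_area, hollow_area = hollow_area,
                 parenchyma_area = parenchyma_area,
                 cortex_thickness = cortex_thickness,
                 D2 = D2, d1a = d1a),
            class = "stem_geometry")
}

#' Extract Fmax and the elastic slope F/V from a bend curve
#'
#' `Fmax` is the maximum recorded force (absolute breaking resistance);
#' `F/V` is the slope of the initial elastic segment of the trace (absolute
#' elastic bending resistance), obtained by least squares over the points
#' whose force lies between `window[1]` and `window[2]` of Fmax on the rising
#' limb. The default 10--40% window avoids both the toe-in region at contact
#' and post-yield curvature near the peak.
#'
#' @param curve A [bend_curve()].
#' @param window Elastic-fit window as fractions of Fmax, default `c(0.10, 0.40)`.
#' @return A list with `fmax` and `f_over_v`.
#' @export
extract_curve_features <- function(curve, window = c(0.10, 0.40)) {
  stopifnot(inherits(curve, "bend_curve"))
  if (length(window) != 2L || window[1] <= 0 || window[2] <= window[1] ||
      window[2] > 1) {
    stop("window must be increasing fractions in (0, 1]")
  }
  force <- curve$force
  disp <- curve$displacement
  fmax <- max(force)
  i_peak <- which.max(force)
  # contiguous rising segment between the first crossings of the window
  # bounds (selecting individual points by their noisy force value would
  # truncate the residuals and bias the slope)
  rising <- force[seq_len(i_peak)]
  i_lo <- which(rising >= window[1] * fmax)[1]
  below_hi <- which(rising <= window[2] * fmax)
  i_hi <- if (length(below_hi)) max(below_hi[below_hi >= i_lo], i_lo) else NA_integer_
  sel <- if (!is.na(i_lo) && !is.na(i_hi)) seq(i_lo, i_hi) else integer(0)
  if (fmax <= 0 || i_peak == 1L || length(sel) < 2L ||
      diff(range(disp[sel])) == 0) {
    stop("no elastic region: curve is flat, decreasing, or too sparse in the fit window")
  }
  fit <- stats::lm.fit(cbind(1, disp[sel]), force[sel])
  list(fmax = fmax, f_over_v = unname(fit$coefficients[2]))
}

#' Equivalent-circle diameter from a cross-sectional area
#'
#' @param area Area (mm^2), non-negative.
#' @return Diameter `2 * sqrt(area / pi)` (mm).
#' @export
diameter_from_area <- function(area) {
  if (any(!is.finite(area)) || any(area < 0)) stop("area must be >= 0")
  2 * sqrt(area / pi)
}

#' Second moment of area of an annular stem cross-section
#'
#' Geometric stiffness of a hollow beam: `I = pi * (D2^4 - d1a^4) / 64`,
#' with `D2` the whole-stem diameter and `d1a` the hollow diameter, both
#' derived from areas.
#'
#' @param D2 Whole-stem diameter (mm).
#' @param d1a Hollow diameter (mm), `0 <= d1a <= D2`.
#' @return Second moment of area (mm^4).
#' @export
second_moment_of_area <- function(D2, d1a = 0) {
  if (any(D2 < 0) || any(d1a < 0)) stop("diameters must be >= 0")
  if (any(d1a > D2)) stop("d1a must not exceed D2")
  pi * (D2^4 - d1a^4) / 64
}

#' Modulus of rupture (material breaking strength)
#'
#' `MOR = Fmax * a * D2 / I`, the absolute breaking resistance scaled by
#' section geometry. Units follow the inputs; no conversion is applied.
#'
#' @param fmax Maximum force.
#' @param a Half-span (mm), `a = L/2` in the standard setup.
#' @param D2 Whole-stem diameter (mm).
#' @param I Second moment of area (mm^4), strictly positive.
#' @return Modulus of rupture in the stress units implied by the inputs.
#' @export
modulus_of_rupture <- function(fmax, a, D2, I) {
  if (any(I <= 0)) stop("second moment of area I must be > 0")
  fmax * a * D2 / I
}

#' Modulus of elasticity (material flexural stiffness)
#'
#' `MOE = (F/V) * (a^2 / 12) * (3L - 4a) / I`. With the standard centre
#' loading `a = L/2` this reduces algebraically to the classical
#' three-point-bend form `(F/V) * L^3 / (48 I)`.
#'
#' @param f_over_v Elastic slope of the force-displacement trace.
#' @param a Half-span (mm); defaults to `L/2`.
#' @param L Support span (mm).
#' @param I Second moment of area (mm^4), strictly positive.
#' @return Modulus of elasticity in the stress units implied by the inputs.
#' @export
modulus_of_elasticity <- function(f_over_v, L, I, a = L / 2) {
  if (any(I <= 0)) stop("second moment of area I must be > 0")
  f_over_v * (a^2 / 12) * (3 * L - 4 * a) / I
}

#' Derive the full set of stem strength traits for one sample
#'
#' Chains curve-feature extraction, diameter derivation, the second moment of
#' area and the two material moduli with `a = L/2`. The default span is the
#' 70 mm support spacing of the standard rig; use `L = 12` for the
#' small-stem (Arabidopsis) rig.
#'
#' @param curve A [bend_curve()].
#' @param geometry A [stem_geometry()].
#' @param L Support span (mm), default 70.
#' @param window Elastic-fit window passed to [extract_curve_features()].
#' @return A one-row data.frame with columns `fmax`, `f_over_v`, `I`,
#'   `MOR`, `MOE`, `D2`, `d1a`, `L`, `a`.
#' @export
derive_stem_traits <- function(curve, geometry, L = 70, window = c(0.10, 0.40)) {
  stopifnot(inherits(geometry, "stem_geometry"))
  if (L <= 0) stop("span L must be > 0")
  feats <- extract_curve_features(curve, window = window)
  a <- L / 2
  I <- second_moment_of_area(geometry$D2, geometry$d1a)
  if (I <= 0) stop("degenerate cross-section: I = 0")
  data.frame(
    fmax = feats$fmax,
    f_over_v = feats$f_over_v,
    I = I,
    MOR = modulus_of_rupture(feats$fmax, a, geometry$D2, I),
    MOE = modulus_of_elasticity(feats$f_over_v, L, I, a = a),
    D2 = geometry$D2,
    d1a = geometry$d1a,
    L = L,
    a = a
  )
}

#' Batch stem-trait derivation over a sample table
#'
#' @param curves Named list of [bend_curve()] objects, names = sample ids.
#' @param geometry_table Data frame with one row per sample: columns
#'   `sample`, `accession`, `whole_area_mm2`, `hollow_area_mm2`, and
#'   optionally `parenchyma_area_mm2`, `cortex_thickness_mm`.
#' @param L Support span (mm).
#' @return A list with `samples` (per-sample trait data.frame, one row per
#'   sample) and `accession_means` (arithmetic means of each trait by
#'   accession).
#' @export
derive_stem_traits_batch <- function(curves, geometry_table, L = 70) {
  req <- c("sample", "accession", "whole_area_mm2", "hollow_area_mm2")
  if (!all(req %in% names(geometry_table))) {
    stop("geometry_table must have columns: ", paste(req, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(geometry_table)), function(i) {
    g <- geometry_table[i, ]
    id <- as.character(g$sample)
    if (is.null(curves[[id]])) stop("no curve for sample '", id, "'")
    geom <- stem_geometry(
      whole_area = g$whole_area_mm2, hollow_area = g$hollow_area_mm2,
      parenchyma_area = if ("parenchyma_area_mm2" %in% names(g)) g$parenchyma_area_mm2 else NA_real_,
      cortex_thickness = if ("cortex_thickness_mm" %in% names(g)) g$cortex_thickness_mm else NA_real_
    )
    tr <- tryCatch(derive_stem_traits(curves[[id]], geom, L = L),
                   error = function(e) stop("sample '", id, "': ", conditionMessage(e),
                                            call. = FALSE))
    cbind(data.frame(sample = id, accession = as.character(g$accession),
                     stringsAsFactors = FALSE), tr)
  })
  samples <- do.call(rbind, rows)
  num_cols <- c("fmax", "f_over_v", "I", "MOR", "MOE", "D2", "d1a")
  means <- stats::aggregate(samples[num_cols], by = list(accession = samples$accession),
                            FUN = mean)
  list(samples = samples, accession_means = means)
}
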