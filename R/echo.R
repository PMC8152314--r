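#' Left-ventricular mass from M-mode dimensions
#'
#' Cube-formula LV mass for the rat,
#' `[[(LVEDD + AWTd + PWTd)^3 - LVEDD^3] x 1.04] x 0.8 + 0.14`,
#' with linear dimensions in cm and the result in grams. 1.04 g/ml is the
#' density of myocardium; 0.8 and +0.14 g are the standard regression
#' corrections of the cube estimate.
#'
#' @param lvedd LV end-diastolic diameter, cm.
#' @param awtd,pwtd Diastolic anterior and posterior wall thickness, cm.
#' @return LV mass in grams. Vectorised.
#' @export
lv_mass <- function(lvedd, awtd, pwtd) {
  stopifnot(all(lvedd > 0))
  if (any(awtd < 0) || any(pwtd < 0))
    stop("wall thickness must be non-negative", call. = FALSE)
  ((lvedd + awtd + pwtd)^3 - lvedd^3) * 1.04 * 0.8 + 0.14
}

#' LV mass index
#'
#' LV mass standardised for body mass, in g/kg.
#'
#' @param mass LV mass, g.
#' @param bw Body weight, g.
#' @return Mass index, g per kg body weight. Vectorised.
#' @export
lv_mass_index <- function(mass, bw) {
  if (any(bw <= 0)) stop("body weight must be positive", call. = FALSE)
  mass / (bw / 1000)
}

#' Fractional shortening
#'
#' `FS = (LVEDD - LVESD) / LVEDD x 100`, percent.
#'
#' @param lvedd,lvesd End-diastolic and end-systolic LV diameter, cm.
#' @return FS in percent. Vectorised.
#' @export
fractional_shortening <- function(lvedd, lvesd) {
  stopifnot(all(lvedd > 0))
  if (any(lvesd > lvedd))
    stop("LVESD cannot exceed LVEDD", call. = FALSE)
  (lvedd - lvesd) / lvedd * 100
}

#' Teichholz left-ventricular volume
#'
#' Converts an LV internal diameter to a volume,
#' `V = 7.0 / (2.4 + D) x D^3` (D in cm, V in ml), correcting the plain
#' cube for the ellipsoidal shortening of dilated ventricles.
#'
#' @param d LV internal diameter, cm.
#' @return Volume in ml. Vectorised.
#' @export
teichholz_volume <- function(d) {
  if (any(d <= 0)) stop("diameter must be positive", call. = FALSE)
  7.0 / (2.4 + d) * d^3
}

#' Ejection fraction via Teichholz volumes
#'
#' `EF = (LVEDV - LVESV) / LVEDV x 100` with both volumes from
#' [teichholz_volume()].
#'
#' @param lvedd,lvesd End-diastolic and end-systolic LV diameter, cm.
#' @return EF in percent. Vectorised.
#' @export
ejection_fraction <- function(lvedd, lvesd) {
  stopifnot(all(lvedd > 0), all(lvesd > 0))
  if (any(lvesd > lvedd))
    stop("LVESD cannot exceed LVEDD", call. = FALSE)
  edv <- teichholz_volume(lvedd)
  esv <- teichholz_volume(lvesd)
  (edv - esv) / edv * 100
}

#' Derived echocardiographic measures for a measurement table
#'
#' Applies the mass and function formulas row-wise to a table of raw
#' M-mode measurements.
#'
#' @param echo `data.frame` with columns `lvedd_cm`, `lvesd_cm`, `awtd_cm`,
#'   `pwtd_cm`, `bw_g` (plus any id columns, which are carried through).
#' @return The input with added columns `lv_mass_g`, `lv_mass_index_g_kg`,
#'   `fs_pct`, `ef_pct`.
#' @export
echo_derive <- function(echo) {
  need <- c("lvedd_cm", "lvesd_cm", "awtd_cm", "pwtd_cm", "bw_g")
  miss <- setdiff(need, names(echo))
  if (length(miss) > 0)
    stop("echo table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  echo$lv_mass_g <- lv_mass(echo$lvedd_cm, echo$awtd_cm, echo$pwtd_cm)
  echo$lv_mass_index_g_kg <- lv_mass_index(echo$lv_mass_g, echo$bw_g)
  echo$fs_pct <- fractional_shortening(echo$lvedd_cm, echo$lvesd_cm)
  echo$ef_pct <- ejection_fraction(echo$lvedd_cm, echo$lvesd_cm)
  echo
}
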