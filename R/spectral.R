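#' @title Spectral index registry
#' @description
#' Vegetation indices (VI), color-space indices (CSI) and red-edge
#' wavelength values (WV) computed from 5-band reflectance
#' (blue, green, red, red-edge, NIR). Each index is a documented closed
#' form frozen in `FORMULAS.md` at the repository root; indices divide
#' safely, returning `NA` (nodata) for zero denominators or missing bands
#' rather than infinities, so downstream zonal means stay finite.
#' @name spectral
NULL

# Sensor band centers (nm) of the 5-band multispectral camera emulated
# throughout: midpoints of blue 459-491, green 546.5-573.5, red 661-675,
# red-edge 711-723, NIR 813.5-870.5.
BAND_CENTERS <- c(blue = 475, green = 560, red = 668, rededge = 717,
                  nir = 842)

safe_div <- function(num, den, eps = 0) {
  out <- num / den
  out[!is.na(den) & abs(den) <= eps] <- NA_real_
  out[is.infinite(out) | is.nan(out)] <- NA_real_
  out
}

as_band_list <- function(bands) {
  need <- c("blue", "green", "red", "rededge", "nir")
  if (is.matrix(bands) || is.data.frame(bands)) bands <- as.list(as.data.frame(bands))
  missing <- setdiff(need, names(bands))
  for (nm in missing) bands[[nm]] <- NA_real_
  n <- max(vapply(bands[need], length, 1L))
  lapply(bands[need], function(v) {
    v <- as.numeric(v)
    if (length(v) == 1L && n > 1L) rep(v, n) else v
  })
}

#' Hue / saturation / intensity transform of RGB reflectance
#'
#' Hue is the arccos chromatic angle of the HSI color space, measured in
#' degrees from the red axis; because the arccos alone cannot exceed 180
#' degrees, the standard completion `hue = 360 - theta` is applied when
#' `blue > green`. Saturation is `1 - 3 min(R,G,B)/(R+G+B)` and intensity
#' the RGB mean. Achromatic pixels (`R = G = B > 0`) have hue 0 and
#' saturation 0; an all-zero RGB triple is nodata.
#'
#' @param bands List/data frame with components `red`, `green`, `blue`
#'   (reflectance in `[0, 1]`), vectors of equal length.
#' @return List with numeric vectors `hue` (degrees, `[0, 360)`),
#'   `saturation` and `intensity` (fractions).
#' @export
hsi_transform <- function(bands) {
  b <- as_band_list(bands)
  r <- b$red; g <- b$green; bl <- b$blue
  total <- r + g + bl
  num <- 0.5 * ((r - g) + (r - bl))
  den <- sqrt((r - g)^2 + (r - bl) * (g - bl))
  theta <- acos(pmin(1, pmax(-1, safe_div(num, den))))
  hue <- ifelse(bl > g, 360 - theta * 180 / pi, theta * 180 / pi)
  hue[hue >= 360] <- 0
  achrom <- !is.na(den) & den == 0 & !is.na(total) & total > 0
  hue[achrom] <- 0
  sat <- 1 - 3 * safe_div(pmin(r, g, bl), total)
  sat[achrom] <- 0
  int <- total / 3
  zero <- !is.na(total) & total == 0
  hue[zero] <- NA_real_; sat[zero] <- NA_real_; int[zero] <- NA_real_
  list(hue = hue, saturation = sat, intensity = int)
}

# Linear interpolation of reflectance at wavelength wl between two band
# centers.
interp_band <- function(wl, wl1, wl2, r1, r2) {
  r1 + (wl - wl1) / (wl2 - wl1) * (r2 - r1)
}

#' Red-edge position and inflection-point wavelength
#'
#' Four-band linear-interpolation estimate of the wavelength (nm) at which
#' reflectance crosses the red-edge inflection level, in the style of the
#' classic Guyot-Baret method adapted to the sensor's band centers:
#' `REP = 700 + 40 * (R_infl - R700) / (R740 - R700)`, where `R700` and
#' `R740` are interpolated from the red/red-edge and red-edge/NIR band
#' pairs and the inflection level is `R_infl = (Red + NIR)/2`. `REIP` uses
#' the alternative inflection estimate `(Red + 2*RedEdge + NIR)/4`, which
#' weights the measured red-edge band into the level. Both are clamped to
#' `[690, 750]` nm; a flat spectrum (`R740 = R700`) is nodata.
#'
#' @param bands List with `red`, `rededge`, `nir` reflectance vectors.
#' @param inflection `"rep"` (default) or `"reip"`.
#' @return Numeric vector of wavelengths in nm (or `NA`).
#' @export
red_edge_position <- function(bands, inflection = c("rep", "reip")) {
  inflection <- match.arg(inflection)
  b <- as_band_list(bands)
  bc <- BAND_CENTERS
  r700 <- interp_band(700, bc["red"], bc["rededge"], b$red, b$rededge)
  r740 <- interp_band(740, bc["rededge"], bc["nir"], b$rededge, b$nir)
  r_infl <- if (inflection == "rep") (b$red + b$nir) / 2 else
    (b$red + 2 * b$rededge + b$nir) / 4
  wl <- 700 + 40 * safe_div(r_infl - r700, r740 - r700)
  pmin(750, pmax(690, wl))
}

# ---- formula registry ------------------------------------------------------

index_registry <- local({
  VI <- "VI"; CSI <- "CSI"; WV <- "WV"
  def <- function(acronym, full_name, category, source, fn) {
    list(acronym = acronym, full_name = full_name, category = category,
         source = source, fn = fn)
  }
  entries <- list(
    def("EVI", "Enhanced Vegetation Index", VI, "core", function(b)
      safe_div(2.5 * (b$nir - b$red), b$nir + 6 * b$red - 7.5 * b$blue + 1)),
    def("SAVI", "Soil-Adjusted Vegetation Index", VI, "core", function(b)
      safe_div(1.5 * (b$nir - b$red), b$nir + b$red + 0.5)),
    def("BGI", "Blue Green Pigment Index", VI, "core", function(b)
      safe_div(b$blue, b$green)),
    def("TVI", "Triangular Vegetation Index", VI, "core", function(b)
      0.5 * (120 * (b$nir - b$green) - 200 * (b$red - b$green))),
    def("MCARI", "Modified Chlorophyll Absorption in Reflectance Index (red)",
        VI, "core", function(b)
      ((b$rededge - b$red) - 0.2 * (b$rededge - b$green)) *
        safe_div(b$rededge, b$red)),
    def("CREI", "Chlorophyll Red-Edge Index", VI, "core", function(b)
      safe_div(b$nir, b$rededge) - 1),
    def("PPR", "Plant Pigment Ratio", VI, "core", function(b)
      safe_div(b$green - b$blue, b$green + b$blue)),
    def("GCI", "Green Chlorophyll Index", VI, "core", function(b)
      safe_div(b$nir, b$green) - 1),
    def("GNDRE", "Green Normalized Difference Red Edge Index", VI, "core",
        function(b) safe_div(b$rededge - b$green, b$rededge + b$green)),
    def("ARI", "Anthocyanin Reflectance Index", VI, "core", function(b)
      safe_div(1, b$green) - safe_div(1, b$rededge)),
    def("CCCI", "Canopy Chlorophyll Content Index", VI, "core", function(b)
      safe_div(safe_div(b$nir - b$rededge, b$nir + b$rededge),
               safe_div(b$nir - b$red, b$nir + b$red))),
    def("MCCI", "Modified Chlorophyll Content Index", VI, "core",
        function(b)
      safe_div(b$rededge - b$red, b$rededge + b$red) -
        safe_div(b$rededge - b$green, b$rededge + b$green)),
    def("SR", "Simple Ratio", VI, "core", function(b)
      safe_div(b$nir, b$red)),
    def("NPPR", "Normalized Plant Pigment Ratio", VI, "core", function(b)
      safe_div(b$green, b$blue + b$red)),
    def("GARI", "Green Atmospherically Resistant Vegetation Index", VI,
        "core", function(b) {
      gg <- b$green - (b$blue - b$red)
      safe_div(b$nir - gg, b$nir + gg)
    }),
    def("NPCI", "Normalized Pigment Chlorophyll Index", VI, "core",
        function(b) safe_div(b$red - b$blue, b$red + b$blue)),
    def("VARIg", "Visible Atmospherically Resistant Index Green", VI,
        "core", function(b)
      safe_div(b$green - b$red, b$green + b$red - b$blue)),
    def("EVIre", "Enhanced Vegetation Index (red-edge)", VI, "core",
        function(b)
      safe_div(2.5 * (b$rededge - b$red),
               b$rededge + 6 * b$red - 7.5 * b$blue + 1)),
    def("SAVIre", "Soil-Adjusted Vegetation Index (red-edge)", VI, "core",
        function(b)
      safe_div(1.5 * (b$rededge - b$red), b$rededge + b$red + 0.5)),
    def("SIPI", "Structure Insensitive Pigment Index", VI, "core",
        function(b) safe_div(b$nir - b$blue, b$nir - b$red)),
    def("MRESR", "Modified Red Edge Simple Ratio", VI, "core", function(b)
      safe_div(b$nir - b$blue, b$rededge - b$blue)),
    def("RRI", "Red-Edge Ratio Index", VI, "core", function(b)
      safe_div(b$rededge, b$red)),
    def("NDVIre", "Normalized Difference Vegetation Index Red Edge", VI,
        "core", function(b)
      safe_div(b$rededge - b$red, b$rededge + b$red)),
    def("MCARI2",
        "Modified Chlorophyll Absorption in Reflectance Index (red-edge)",
        VI, "core", function(b)
      ((b$nir - b$rededge) - 0.2 * (b$nir - b$green)) *
        safe_div(b$nir, b$rededge)),
    def("TGI", "Triangular Greenness Index", VI, "core", function(b)
      -0.5 * (190 * (b$red - b$green) - 120 * (b$red - b$blue))),
    def("HUE", "Hue", CSI, "core", function(b) hsi_transform(b)$hue),
    # standard-literature extensions named in the running text
    def("NDVI", "Normalized Difference Vegetation Index", VI, "text-named",
        function(b) safe_div(b$nir - b$red, b$nir + b$red)),
    def("NDRE", "Normalized Difference Red Edge Index", VI, "text-named",
        function(b) safe_div(b$nir - b$rededge, b$nir + b$rededge)),
    def("GNDVI", "Green Normalized Difference Vegetation Index", VI,
        "text-named", function(b)
      safe_div(b$nir - b$green, b$nir + b$green)),
    def("WDRVI", "Wide Dynamic Range Vegetation Index (alpha = 0.2)", VI,
        "text-named", function(b)
      safe_div(0.2 * b$nir - b$red, 0.2 * b$nir + b$red)),
    def("TrVI", "Transformed Vegetation Index", VI, "text-named",
        function(b) {
      ndvi <- safe_div(b$nir - b$red, b$nir + b$red)
      out <- suppressWarnings(sqrt(ndvi + 0.5))
      out[!is.na(ndvi) & ndvi < -0.5] <- NA_real_
      out
    }),
    def("SAT", "Saturation", CSI, "text-named", function(b)
      hsi_transform(b)$saturation),
    def("INT", "Intensity", CSI, "text-named", function(b)
      hsi_transform(b)$intensity),
    def("REP", "Red Edge Position", WV, "text-named", function(b)
      red_edge_position(b, "rep")),
    def("REIP", "Red Edge Inflection Point", WV, "text-named", function(b)
      red_edge_position(b, "reip"))
  )
  names(entries) <- vapply(entries, `[[`, "", "acronym")
  entries
})

#' List all registered spectral indices
#'
#' @return A data frame with one row per index: `acronym`, `full_name`,
#'   `category` (`VI`, `CSI` or `WV`) and `source` (`core` for the core
#'   registry, `text-named` for the standard-literature extension set).
#' @export
#' @examples
#' head(list_indices())
list_indices <- function() {
  data.frame(
    acronym = vapply(index_registry, `[[`, "", "acronym"),
    full_name = vapply(index_registry, `[[`, "", "full_name"),
    category = vapply(index_registry, `[[`, "", "category"),
    source = vapply(index_registry, `[[`, "", "source"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Compute a spectral index from 5-band reflectance
#'
#' Applies the registered formula element-wise; inputs may be scalars,
#' vectors or co-registered raster values flattened to vectors. Any nodata
#' band or zero denominator yields `NA` for that element.
#'
#' @param acronym Registered index acronym (see [list_indices()]).
#' @param bands Named list / data frame with `blue`, `green`, `red`,
#'   `rededge`, `nir` reflectance (not all indices use all bands).
#' @return Numeric vector of index values (dimensionless; degrees for HUE,
#'   nm for REP/REIP).
#' @export
#' @examples
#' compute_index("GNDRE", list(rededge = 0.3, green = 0.1))  # 0.5
compute_index <- function(acronym, bands) {
  entry <- index_registry[[acronym]]
  if (is.null(entry)) {
    stop(sprintf("unknown-index: '%s' is not registered", acronym),
         call. = FALSE)
  }
  entry$fn(as_band_list(bands))
}

#' Compute many indices into a data frame
#'
#' @param bands As in [compute_index()].
#' @param acronyms Character vector of acronyms; default all registered.
#' @return Data frame, one column per index.
#' @export
compute_indices <- function(bands, acronyms = list_indices()$acronym) {
  b <- as_band_list(bands)
  out <- lapply(acronyms, function(a) compute_index(a, b))
  names(out) <- acronyms
  as.data.frame(out, optional = TRUE)
}
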