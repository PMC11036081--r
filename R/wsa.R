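#' Load a WSA power-law coefficient table
#'
#' Hull Wetted Surface Area for large vessel categories follows the
#' power-law family `WSA = a * dim^b`, with the regression pair (a, b)
#' specific to a vessel category and predictor dimension (DWT primarily;
#' B_OA or L_OA as fallbacks for categories where DWT is often missing).
#' The packaged default table (`wsa_coefficients_synthetic.csv`) carries
#' illustrative synthetic values in the published structure, NOT the
#' published regression estimates; substitute your own calibrated CSV for
#' real analyses. Schema: category, input_dim in {DWT, BOA, LOA}, a, b.
#'
#' @param path CSV path; default is the packaged synthetic table.
#' @return Tibble of coefficients (a > 0 enforced).
#' @export
wsa_coefficients <- function(path = system.file("extdata",
                                                "wsa_coefficients_synthetic.csv",
                                                package = "voyagenet")) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    category = readr::col_character(), input_dim = readr::col_character(),
    a = readr::col_double(), b = readr::col_double()))
  stopifnot(all(tab$a > 0), all(tab$input_dim %in% c("DWT", "BOA", "LOA")))
  tab
}

#' Tender hull constant (m^2)
#'
#' All individual tenders are assigned a fixed 9.9 m^2 WSA, the
#' small-craft value for vessels of 4-6 m length, regardless of recorded
#' dimensions.
#' @export
TENDER_WSA_M2 <- 9.9

# AIS class -> regression category + dimension fallback chain
WSA_CATEGORY_MAP <- tibble::tribble(
  ~vessel_type, ~category,          ~fallback_dim,
  "Bulk",       "Bulk carriers",    NA_character_,
  "Cargo",      "Cargo",            NA_character_,
  "Fishing",    "Fishing vessels",  "BOA",
  "Offshore",   "Other",            "LOA",
  "Passenger",  "Passenger ships",  "BOA",
  "Pilot",      "Tugs and supply",  "BOA",
  "Tanker",     "Tanker",           NA_character_
)

#' Map a vessel profile to its WSA category and method
#'
#' Class-to-category rules: Offshore (research) vessels follow the "Other"
#' category; Pleasure craft under 26 m length overall use the
#' Denny-Mumford small-craft formula, larger pleasure vessels the
#' "Fishing vessels" regression; Tenders take the fixed small-craft
#' constant; the remaining classes map to their standard regression
#' category (Pilot vessels to "Tugs and supply").
#'
#' @param profile One-row vessel profile (vessel_type, L_OA, ...).
#' @return List with `category` and `method` hint (one of "power_law",
#'   "denny_mumford", "tender_constant") and `fallback_dim`.
#' @export
map_category <- function(profile) {
  vt <- profile$vessel_type
  if (!vt %in% VESSEL_CLASSES) stop("unknown vessel class: ", vt)
  if (vt == "Tender")
    return(list(category = "Tender", method = "tender_constant",
                fallback_dim = NA_character_))
  if (vt == "Pleasure") {
    if (!is.na(profile$L_OA) && profile$L_OA < 26)
      return(list(category = "Pleasure (small craft)",
                  method = "denny_mumford", fallback_dim = NA_character_))
    return(list(category = "Fishing vessels", method = "power_law",
                fallback_dim = "BOA"))
  }
  row <- WSA_CATEGORY_MAP[WSA_CATEGORY_MAP$vessel_type == vt, ]
  list(category = row$category, method = "power_law",
       fallback_dim = row$fallback_dim)
}

#' Power-law WSA
#'
#' `WSA = a * dim^b` with regression coefficient `a` and exponent `b`.
#' @param dim_value Predictor value (> 0): DWT (t), B_OA (m) or L_OA (m).
#' @param a,b Regression coefficient and exponent.
#' @return WSA in m^2.
#' @export
wsa_power_law <- function(dim_value, a, b) {
  if (any(dim_value <= 0)) stop("dimension must be positive")
  a * dim_value^b
}

#' Denny-Mumford small-craft WSA
#'
#' `WSA = 1.7 * L_OA * T + V / T`, the empirical small-craft estimate used
#' for pleasure vessels under 26 m.
#' @param L_OA Length overall (m), > 0.
#' @param T_draft Draft (m), > 0.
#' @param V Gross tonnage, >= 0.
#' @return WSA in m^2.
#' @examples
#' wsa_denny_mumford(20, 2, 40) # 88
#' @export
wsa_denny_mumford <- function(L_OA, T_draft, V) {
  if (any(L_OA <= 0)) stop("L_OA must be positive")
  if (any(T_draft <= 0)) stop("draft must be positive (division by T)")
  if (any(V < 0)) stop("V must be non-negative")
  1.7 * L_OA * T_draft + V / T_draft
}

#' Wetted surface area for one vessel
#'
#' Dispatch order: tenders take the 9.9 m^2 constant; small pleasure craft
#' the Denny-Mumford formula; otherwise the category power law on DWT; if
#' DWT is missing and the category has a fallback dimension (B_OA for
#' fishing / tugs-and-supply / passenger, L_OA for "Other"), that
#' regression is used. A vessel with no usable dimension raises an error
#' naming what was absent — dispatch is total, with no silent defaults.
#'
#' @param profile One-row vessel profile.
#' @param coefficients Coefficient table from [wsa_coefficients()].
#' @return Tibble row: mmsi, vessel_type, category_used, method, wsa_m2.
#' @export
vessel_wsa <- function(profile, coefficients = wsa_coefficients()) {
  mc <- map_category(profile)
  res <- function(method, category, wsa) tibble(
    mmsi = profile$mmsi, vessel_type = profile$vessel_type,
    category_used = category, method = method, wsa_m2 = wsa)
  if (mc$method == "tender_constant")
    return(res("tender_constant", "Tender", TENDER_WSA_M2))
  if (mc$method == "denny_mumford") {
    if (is.na(profile$L_OA) || is.na(profile$T) || is.na(profile$V))
      stop("missing dimension(s) for Denny-Mumford: need L_OA, T, V (mmsi ",
           profile$mmsi, ")")
    return(res("denny_mumford", mc$category,
               wsa_denny_mumford(profile$L_OA, profile$T, profile$V)))
  }
  cf <- function(dim) coefficients[coefficients$category == mc$category &
                                     coefficients$input_dim == dim, ]
  if (!is.na(profile$DWT)) {
    row <- cf("DWT")
    if (!nrow(row)) stop("no DWT coefficients for category ", mc$category)
    return(res("power_law_DWT", mc$category,
               wsa_power_law(profile$DWT, row$a, row$b)))
  }
  if (!is.na(mc$fallback_dim)) {
    dimval <- switch(mc$fallback_dim, BOA = profile$B_OA, LOA = profile$L_OA)
    if (!is.na(dimval)) {
      row <- cf(mc$fallback_dim)
      if (!nrow(row)) stop("no ", mc$fallback_dim, " coefficients for category ",
                           mc$category)
      return(res(paste0("power_law_", mc$fallback_dim), mc$category,
                 wsa_power_law(dimval, row$a, row$b)))
    }
  }
  stop("no usable dimension for mmsi ", profile$mmsi, " (", profile$vessel_type,
       "): DWT missing",
       if (!is.na(mc$fallback_dim)) paste0(" and ", mc$fallback_dim, " missing"))
}

#' Wetted surface area for a whole fleet
#'
#' @param profiles Vessel profile tibble.
#' @param coefficients Coefficient table.
#' @return Tibble with one row per vessel (mmsi, vessel_type,
#'   category_used, method, wsa_m2); every result is positive.
#' @export
fleet_wsa <- function(profiles, coefficients = wsa_coefficients()) {
  out <- dplyr::bind_rows(lapply(seq_len(nrow(profiles)), function(i) {
    vessel_wsa(profiles[i, ], coefficients)
  }))
  stopifnot(all(out$wsa_m2 > 0))
  out
}
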