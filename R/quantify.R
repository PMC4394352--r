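# Ratiometric quantification of Phos-Tag gel lanes.
#
# Each lane carries two bands: the phosphorylated substrate and the
# dephosphorylated product. Because both species derive from the same
# loaded material, the fraction dephosphorylated is a ratio of band
# intensities and is invariant to per-lane loading differences.

#' Column schema of a lane-intensity table
#'
#' One row per gel lane. Intensities are net (background-subtracted)
#' arbitrary fluorescence units; concentrations in micromolar; time in
#' minutes.
#'
#' @return Character vector of required column names.
#' @export
lane_schema <- function() {
  c(
    "condition_label", "replicate_id", "time_min", "substrate_total_uM",
    "enzyme_uM", "effector_uM", "intensity_phospho", "intensity_dephospho"
  )
}

#' Read a lane-intensity table from CSV
#'
#' Comma-separated, header row, UTF-8, `.` decimal; columns as in
#' [lane_schema()].
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per lane.
#' @export
read_lane_table <- function(path) {
  lanes <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(lanes, lane_schema(), sprintf("lane table '%s'", path))
  lanes
}

#' Fraction of substrate dephosphorylated in a lane
#'
#' The ratiometric observable: product-band intensity over total lane
#' intensity. Multiplying both bands by any positive per-lane loading
#' factor leaves the result bit-identical.
#'
#' @param intensity_phospho,intensity_dephospho Net band intensities
#'   (arbitrary units, >= 0; the per-lane sum must be positive).
#' @param lane_id Optional identifier(s) used in error messages.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
#' @examples
#' fraction_dephosphorylated(7, 7)   # 0.5
#' fraction_dephosphorylated(3, 1)   # 0.25
fraction_dephosphorylated <- function(intensity_phospho, intensity_dephospho,
                                      lane_id = NULL) {
  ip <- intensity_phospho
  id <- intensity_dephospho
  lane_id <- lane_id %||% seq_along(ip)
  neg <- which(ip < 0 | id < 0)
  if (length(neg) > 0) {
    abort(
      sprintf(
        "negative band intensity in lane(s): %s (background subtraction is an upstream responsibility; intensities must arrive net and non-negative)",
        paste(lane_id[neg], collapse = ", ")
      ),
      class = "holophos_input_error"
    )
  }
  zero <- which(ip + id <= 0)
  if (length(zero) > 0) {
    abort(
      sprintf("zero total intensity in lane(s): %s",
              paste(lane_id[zero], collapse = ", ")),
      class = "holophos_input_error"
    )
  }
  id / (ip + id)
}

#' Convert lane intensities to substrate and product concentrations
#'
#' Applies [fraction_dephosphorylated()] to every lane and partitions the
#' known total substrate concentration into remaining substrate and
#' product. The two always sum exactly to the total.
#'
#' @param lanes Data frame in the [lane_schema()] layout.
#' @param min_total_intensity Lanes whose band-intensity sum falls below
#'   this floor are dropped (weak lanes dominate ratio noise). Default 0,
#'   i.e. disabled; zero-total lanes are always an error.
#' @return A tibble: the input rows (minus any excluded weak lanes) with
#'   `fraction`, `substrate_uM` and `product_uM` columns appended. Rows
#'   dropped by the floor are recorded in the `"excluded"` attribute.
#' @export
quantify_lanes <- function(lanes, min_total_intensity = 0) {
  check_columns(lanes, lane_schema(), "lane table")
  check_positive(lanes$substrate_total_uM, "substrate_total_uM")
  lanes <- tibble::as_tibble(lanes)

  total <- lanes$intensity_phospho + lanes$intensity_dephospho
  weak <- total < min_total_intensity & min_total_intensity > 0
  excluded <- lanes[weak, , drop = FALSE]
  kept <- lanes[!weak, , drop = FALSE]

  lane_id <- paste0(kept$condition_label, "/", kept$replicate_id,
                    "/t=", kept$time_min)
  frac <- fraction_dephosphorylated(
    kept$intensity_phospho, kept$intensity_dephospho, lane_id = lane_id
  )
  out <- dplyr::mutate(
    kept,
    fraction = frac,
    substrate_uM = (1 - frac) * .data$substrate_total_uM,
    product_uM = frac * .data$substrate_total_uM
  )
  attr(out, "excluded") <- excluded
  out
}
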