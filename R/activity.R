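#' Community-averaged per-cell carbon oxidation rate
#'
#' Divides the oxidized carbon by the oxidation window and by the total cell
#' count in the surrounding water volume:
#' `rate = (carbon_mol / duration_days) / (cells_per_ml * water_volume_l * 1000)`
#' expressed in femtomoles of carbon per cell per day. Linear in `carbon_mol`
#' and inversely linear in each of the other inputs.
#'
#' @param carbon_mol carbon oxidized, mol (>= 0).
#' @param duration_days oxidation window, days (> 0); see
#'   [scenario_duration()].
#' @param cells_per_ml planktonic cell density (> 0; default 4.1e6, the
#'   measured count at the amendment depth).
#' @param water_volume_l water volume housing those cells, litres (> 0;
#'   default 10.6).
#' @return fmol C per cell per day.
#' @export
#' @examples
#' per_cell_rate(1.6e-4, 177) # ~0.02 fmol C/cell/day
#' per_cell_rate(3.01e-3, 120) # ~0.577 fmol C/cell/day
per_cell_rate <- function(carbon_mol, duration_days,
                          cells_per_ml = 4.1e6, water_volume_l = 10.6) {
  check_that(carbon_mol >= 0, "`carbon_mol` must be non-negative.")
  check_that(duration_days > 0, "`duration_days` must be positive.")
  check_that(cells_per_ml > 0, "`cells_per_ml` must be positive.")
  check_that(water_volume_l > 0, "`water_volume_l` must be positive.")
  total_cells <- cells_per_ml * water_volume_l * 1000
  (carbon_mol / duration_days) / total_cells * 1e15
}
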