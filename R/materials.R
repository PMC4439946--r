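#' Material names, density thresholds and stopping powers
#'
#' Voxels are classified into five materials by mass density. The interval
#' boundaries are half-open and closed at the lower bound, so every
#' nonnegative density maps to exactly one material:
#' Air < 0.207, Adipose `[0.207, 0.979)`, Water `[0.979, 1.0)`,
#' Muscle `[1.0, 1.109)`, DenseBone >= 1.109 (g/cm^3).
#'
#' `rsp` is the relative proton stopping power of each material at its
#' nominal density; a voxel's stopping power is scaled by the ratio of its
#' density to the nominal density. The soft-tissue nominal densities are
#' chosen so that RSP equals density for soft tissue (in particular,
#' water-density tissue has RSP exactly 1), while dense bone stops protons
#' at about 86% of its density.
#'
#' @return named list with `names`, `breaks`, `rsp`, `nominal_density`.
#' @export
material_table <- function() {
  list(
    names = c("Air", "Adipose", "Water", "Muscle", "DenseBone"),
    breaks = c(0.207, 0.979, 1.0, 1.109),
    rsp = c(Air = 0.0012, Adipose = 0.96, Water = 1.0, Muscle = 1.04,
            DenseBone = 1.6),
    nominal_density = c(Air = 0.0012, Adipose = 0.96, Water = 1.0,
                        Muscle = 1.04, DenseBone = 1.85)
  )
}

#' Assign a material to every voxel by density thresholds
#'
#' @param dv a [density_volume()].
#' @return object of class `material_map`: integer label array (1 = Air ...
#'   5 = DenseBone) plus the lookup tables from [material_table()].
#' @export
assign_materials <- function(dv) {
  tab <- material_table()
  lab <- findInterval(dv$data, tab$breaks, left.open = FALSE) + 1L
  structure(list(labels = array(lab, dim(dv$data)),
                 materials = tab$names,
                 rsp = tab$rsp,
                 nominal_density = tab$nominal_density),
            class = "material_map")
}

#' @method print material_map
#' @export
print.material_map <- function(x, ...) {
  tb <- table(factor(x$materials[x$labels], levels = x$materials))
  cat("material_map:\n")
  print(tb)
  invisible(x)
}

#' Relative stopping power volume
#'
#' Per-voxel relative proton stopping power: the material RSP scaled by the
#' voxel's density relative to the material's nominal density. This is the
#' quantity integrated along rays to obtain water-equivalent path length and
#' is also how dose is expressed as dose-to-water.
#'
#' @param dv a [density_volume()].
#' @param mm the matching [assign_materials()] map.
#' @return 3D numeric array of RSP values.
#' @export
rsp_volume <- function(dv, mm) {
  if (!identical(dim(dv$data), dim(mm$labels))) {
    stop("density volume and material map have different grids")
  }
  scale <- mm$rsp / mm$nominal_density
  array(dv$data * scale[mm$labels], dim(dv$data))
}
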