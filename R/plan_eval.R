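#' Accumulate normalized total dose (NTD) over fractions
#'
#' Per voxel, `NTD = sum_i d_i * (ab + d_i) / (ab + dref)` with `ab` the
#' linear-quadratic alpha/beta ratio and `dref` the reference fraction size
#' (2 Gy). When every fraction delivers exactly `dref`, NTD equals the
#' physical total dose; fractions above `dref` are weighted up, more
#' strongly for low alpha/beta (normal tissue).
#'
#' @param fractions a `fraction_dose_set` from [simulate_course()] /
#'   internal course delivery, a list of [dose_grid()]s, or a matrix of
#'   per-fraction doses (voxels x fractions).
#' @param alpha_beta alpha/beta ratio in Gy (> 0); 10 for the CTV, 1.5 for
#'   the ring in this pipeline.
#' @param dref reference fraction dose in Gy.
#' @return for a `fraction_dose_set`, a list of class `ntd_grid` with
#'   `values` (NTD at the set's voxels), `idx`, `dims`, `alpha_beta`,
#'   `dref`, `n_fractions`; for a matrix or list input, the NTD vector.
#' @export
ntd_accumulate <- function(fractions, alpha_beta, dref = 2) {
  if (alpha_beta <= 0) stop("alpha_beta must be positive")
  ntd_of <- function(dmat) {
    rowSums(dmat * (alpha_beta + dmat) / (alpha_beta + dref))
  }
  if (inherits(fractions, "fraction_dose_set")) {
    structure(list(values = ntd_of(fractions$doses), idx = fractions$idx,
                   dims = fractions$dims, spacing = fractions$spacing,
                   origin = fractions$origin, alpha_beta = alpha_beta,
                   dref = dref, n_fractions = fractions$n_fractions),
              class = "ntd_grid")
  } else if (is.list(fractions)) {
    dmat <- do.call(cbind, lapply(fractions, function(f) {
      as.numeric(if (inherits(f, "dose_grid")) f$data else f)
    }))
    ntd_of(dmat)
  } else {
    ntd_of(as.matrix(fractions))
  }
}

# dose values of a structure from any supported dose container
structure_doses <- function(dose, mask = NULL) {
  if (inherits(dose, c("dose_grid", "density_volume"))) {
    d <- dose$data
    if (is.null(mask)) as.numeric(d) else d[mask]
  } else if (inherits(dose, "ntd_grid")) {
    if (is.null(mask)) return(dose$values)
    keep <- mask[dose$idx]
    if (sum(keep) != sum(mask)) {
      stop("mask voxels missing from the NTD grid's evaluated voxels")
    }
    dose$values[keep]
  } else if (is.array(dose) && !is.null(mask)) {
    dose[mask]
  } else {
    as.numeric(dose)[if (is.null(mask)) TRUE else mask]
  }
}

#' Cumulative dose-volume histogram
#'
#' Volume fraction (percent) of the structure receiving at least each dose
#' level, evaluated at bin edges `0, bin_width, 2 bin_width, ...` up to just
#' above the maximum dose. Starts at 100% and falls to 0% above the maximum.
#'
#' @param dose a [dose_grid()], `ntd_grid`, array, or numeric vector.
#' @param mask logical array/vector selecting the structure (nonempty);
#'   may be omitted when `dose` is already the structure's dose vector.
#' @param bin_width histogram bin width in Gy.
#' @return data.frame of class `dvh_curve` with columns `dose` (Gy) and
#'   `volume` (%).
#' @export
compute_dvh <- function(dose, mask = NULL, bin_width = 0.1) {
  d <- sort(structure_doses(dose, mask))
  if (!length(d)) stop("structure mask is empty")
  edges <- seq(0, max(d) + 2 * bin_width, by = bin_width)
  # findInterval with left.open counts doses strictly below each edge
  vol <- 100 * (length(d) - findInterval(edges, d, left.open = TRUE)) /
    length(d)
  out <- data.frame(dose = edges, volume = vol)
  class(out) <- c("dvh_curve", "data.frame")
  out
}

#' Dose at a DVH volume point (Dx%)
#'
#' The minimum dose received by the hottest `volume_pct` percent of the
#' structure: the largest dose level at which the cumulative volume still
#' reaches `volume_pct`, read from the DVH with linear interpolation
#' between bins.
#'
#' @param curve a [compute_dvh()] curve.
#' @param volume_pct volume percentage in (0, 100].
#' @return dose in Gy.
#' @export
dvh_metric <- function(curve, volume_pct) {
  if (volume_pct <= 0 || volume_pct > 100) {
    stop("volume percentage must be in (0, 100]")
  }
  v <- curve$volume
  d <- curve$dose
  ok <- which(v >= volume_pct)
  if (!length(ok)) return(d[1])
  k <- max(ok)
  if (k == length(v)) return(d[k])
  # interpolate toward the next bin as the volume falls through volume_pct
  v1 <- v[k]; v2 <- v[k + 1L]
  if (v1 == v2) return(d[k])
  d[k] + (d[k + 1L] - d[k]) * (v1 - volume_pct) / (v1 - v2)
}

#' Planned-versus-delivered dose-volume variation report
#'
#' For the CTV (NTD with alpha/beta = 10 Gy) the D98, D95, D50 and D2
#' points and for the ring (alpha/beta = 1.5 Gy) the D2, D20 and D50 points
#' are compared between the planned dose and the delivered NTD. Variation
#' is `(delivered - planned) / prescription * 100`, so an underdose is
#' negative.
#'
#' @param planned a [dose_grid()] of the planned (zero-shift) dose.
#' @param delivered a `fraction_dose_set` from the course simulation, or a
#'   list with precomputed `ntd_grid`s named `ctv` and `ring`.
#' @param structures a [structure_set()].
#' @param prescription prescription dose in Gy (default 60).
#' @param alpha_beta named alpha/beta values (Gy) for `ctv` and `ring`.
#' @param dref reference fraction dose (Gy).
#' @param bin_width DVH bin width (Gy).
#' @return data.frame of class `variation_report`: `structure`, `metric`,
#'   `planned` (Gy), `delivered` (Gy), `variation_pct`.
#' @export
variation_report <- function(planned, delivered, structures,
                             prescription = 60,
                             alpha_beta = c(ctv = 10, ring = 1.5),
                             dref = 2, bin_width = 0.1) {
  if (prescription <= 0) stop("prescription must be positive")
  msk <- structures$masks
  if (inherits(planned, "dose_grid") &&
      !identical(dim(planned$data), dim(msk$CTV))) {
    stop("planned dose and structure grids do not match")
  }
  if (inherits(delivered, "fraction_dose_set")) {
    ntd <- list(ctv = ntd_accumulate(delivered, alpha_beta[["ctv"]], dref),
                ring = ntd_accumulate(delivered, alpha_beta[["ring"]], dref))
  } else {
    ntd <- delivered
  }
  specs <- list(ctv = list(mask = msk$CTV, metrics = c(98, 95, 50, 2)),
                ring = list(mask = msk$ring, metrics = c(2, 20, 50)))
  rows <- lapply(names(specs), function(s) {
    pl_curve <- compute_dvh(planned, specs[[s]]$mask, bin_width)
    de_curve <- compute_dvh(ntd[[s]], specs[[s]]$mask, bin_width)
    data.frame(
      structure = if (s == "ctv") "CTV" else "ring",
      metric = paste0("D", specs[[s]]$metrics),
      planned = vapply(specs[[s]]$metrics,
                       function(p) dvh_metric(pl_curve, p), 0),
      delivered = vapply(specs[[s]]$metrics,
                         function(p) dvh_metric(de_curve, p), 0)
    )
  })
  out <- do.call(rbind, rows)
  out$variation_pct <- (out$delivered - out$planned) / prescription * 100
  class(out) <- c("variation_report", "data.frame")
  out
}
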