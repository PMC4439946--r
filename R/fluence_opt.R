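#' Plan objectives
#'
#' Dose-volume objectives of the optimization: PTV minimum 58 Gy, PTV and
#' ring maximum 60 Gy, and a ring dose-volume constraint allowing no more
#' than 3% of the ring volume above 54 Gy. Penalty weights are quadratic
#' one-sided penalties per structure, averaged over the structure's sampled
#' voxels.
#'
#' @param ptv_min,ptv_max PTV dose window (Gy).
#' @param ring_max ring maximum dose (Gy).
#' @param ring_dvh_dose,ring_dvh_frac ring DVH constraint: at most
#'   `ring_dvh_frac` of the ring volume above `ring_dvh_dose` Gy.
#' @param weights named penalty weights (`ptv_min`, `ptv_max`, `ring_max`,
#'   `ring_dvh`).
#' @return list of class `plan_objectives`.
#' @export
plan_objectives <- function(ptv_min = 58, ptv_max = 60, ring_max = 60,
                            ring_dvh_dose = 54, ring_dvh_frac = 0.03,
                            weights = c(ptv_min = 100, ptv_max = 10,
                                        ring_max = 10, ring_dvh = 10)) {
  if (ptv_min > ptv_max) stop("ptv_min must not exceed ptv_max")
  if (ring_dvh_frac <= 0 || ring_dvh_frac > 1) {
    stop("ring_dvh_frac must be in (0, 1]")
  }
  structure(list(ptv_min = ptv_min, ptv_max = ptv_max, ring_max = ring_max,
                 ring_dvh_dose = ring_dvh_dose,
                 ring_dvh_frac = ring_dvh_frac, weights = weights),
            class = "plan_objectives")
}

#' Build the influence (dose-deposition) matrix
#'
#' Column j holds the dose per unit weight of spot j at the sampled voxels:
#' all PTV and ring voxels plus a regular subsample of the remaining body
#' voxels. Entries below `threshold` times the column maximum are zeroed
#' for sparsity.
#'
#' @param dv a [density_volume()].
#' @param mm matching [assign_materials()] map.
#' @param plan a `spot_plan` from [build_det_plan()] (nonempty).
#' @param structures a [structure_set()].
#' @param energy `"E0"` (ORG plan) or `"E1"` (EM plan).
#' @param body_fraction fraction of non-PTV, non-ring body voxels sampled.
#' @param threshold per-column sparsification threshold (fraction of the
#'   column maximum).
#' @param model a [beam_model()]; defaults to the plan's model.
#' @return list of class `influence`: sparse matrix `A` (voxels x spots),
#'   voxel linear indices `idx`, structure `tag` factor, sampled voxel
#'   positions `pts`, the `energy` used, and the voxel volume `voxel_mm3`.
#' @export
build_influence <- function(dv, mm, plan, structures,
                            energy = c("E0", "E1"), body_fraction = 0.1,
                            threshold = 1e-3, model = NULL) {
  energy <- match.arg(energy)
  if (!nrow(plan)) stop("spot plan is empty")
  if (is.null(model)) model <- attr(plan, "model")
  if (is.null(model)) model <- beam_model()
  iso <- attr(plan, "iso")
  if (is.null(iso)) iso <- grid_center(dv)
  msk <- structures$masks
  idx_ptv <- which(msk$PTV)
  idx_ring <- which(msk$ring)
  idx_body <- which(msk$body & !msk$PTV & !msk$ring)
  if (body_fraction < 1 && length(idx_body)) {
    step <- max(1L, round(1 / max(body_fraction, 1e-6)))
    idx_body <- idx_body[seq(1L, length(idx_body), by = step)]
  }
  idx <- c(idx_ptv, idx_ring, idx_body)
  tag <- factor(rep(c("ptv", "ring", "body"),
                    c(length(idx_ptv), length(idx_ring), length(idx_body))),
                levels = c("ptv", "ring", "body"))
  pts <- voxel_centers(dim(dv$data), dv$spacing, dv$origin, idx)
  rsp <- rsp_volume(dv, mm)
  en <- plan[[energy]]
  et <- energy_tables(en, model)
  ti <- list(); tj <- list(); tx <- list()
  for (ang in unique(plan$beam_angle)) {
    sel <- which(plan$beam_angle == ang)
    tr <- cpp_influence_angle(
      as.numeric(rsp), dim(dv$data), dv$spacing, dv$origin, pts,
      as.numeric(iso), ang, plan$u[sel], plan$v[sel], et$eid[sel], et$tabs,
      model$sigma_air, model$mcs_frac, model$cutoff_sigma)
    ti[[length(ti) + 1L]] <- tr$i
    tj[[length(tj) + 1L]] <- sel[tr$j]
    tx[[length(tx) + 1L]] <- tr$x
  }
  A <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(length(idx), nrow(plan)))
  if (threshold > 0) {
    cmax <- apply_colmax(A)
    drop <- A@x < threshold * rep(cmax, diff(A@p))
    if (any(drop)) {
      A@x[drop] <- 0
      A <- Matrix::drop0(A)
    }
  }
  cov <- Matrix::rowSums(A[seq_along(idx_ptv), , drop = FALSE]) > 0
  if (!all(cov)) {
    warning(sum(!cov), " PTV voxel(s) receive no dose from any spot")
  }
  structure(list(A = A, idx = idx, tag = tag, pts = pts, energy = energy,
                 voxel_mm3 = prod(dv$spacing)),
            class = "influence")
}

# maximum of each column of a dgCMatrix (0 for empty columns)
apply_colmax <- function(A) {
  p <- A@p
  n <- ncol(A)
  out <- numeric(n)
  for (j in seq_len(n)) {
    if (p[j + 1L] > p[j]) out[j] <- max(A@x[(p[j] + 1L):p[j + 1L]])
  }
  out
}

# objective value and dose-space gradient for a dose vector `d`.
# `tighten` shifts the solver's internal one-sided targets inward (PTV
# minimum up, ring DVH dose down) so that voxels settle strictly on the
# feasible side of the clinical constraint instead of asymptotically on it.
objective_terms <- function(d, tag, obj, weights = obj$weights,
                            tighten = 0, allowance = 1) {
  ip <- tag == "ptv"; ir <- tag == "ring"
  np <- sum(ip); nr <- sum(ir)
  dp <- d[ip]; dr <- d[ir]
  pmin_t <- obj$ptv_min + tighten
  rdvh_t <- obj$ring_dvh_dose - tighten
  g <- numeric(length(d))
  under <- pmax(pmin_t - dp, 0)
  over <- pmax(dp - obj$ptv_max, 0)
  f <- (weights[["ptv_min"]] * sum(under^2) +
          weights[["ptv_max"]] * sum(over^2)) / np
  g[ip] <- 2 * (weights[["ptv_max"]] * over -
                  weights[["ptv_min"]] * under) / np
  rover <- pmax(dr - obj$ring_max, 0)
  f <- f + weights[["ring_max"]] * sum(rover^2) / nr
  gr <- 2 * weights[["ring_max"]] * rover / nr
  # DVH penalty: the hottest `ring_dvh_frac` of ring voxels are left to the
  # ring-max term; every other ring voxel above the (tightened) DVH dose is
  # driven back toward it
  k <- floor(obj$ring_dvh_frac * allowance * nr)
  hot <- which(dr > rdvh_t)
  if (length(hot) > k) {
    allow <- hot[order(dr[hot], decreasing = TRUE)][seq_len(k)]
    pen <- setdiff(hot, allow)
    exc <- dr[pen] - rdvh_t
    f <- f + weights[["ring_dvh"]] * sum(exc^2) / nr
    gr[pen] <- gr[pen] + 2 * weights[["ring_dvh"]] * exc / nr
  }
  g[ir] <- gr
  list(f = as.numeric(f), g = g)
}

# one round of monotone accelerated projected gradient (FISTA with adaptive
# restart and an incumbent-keeping step, so the recorded objective sequence
# is nonincreasing by construction)
fista_round <- function(A, tag, obj, weights, tighten, allowance, iters,
                        tol, x) {
  fval <- function(w) {
    d <- as.numeric(A %*% w)
    ot <- objective_terms(d, tag, obj, weights, tighten, allowance)
    list(d = d, f = ot$f, g = ot$g)
  }
  ox <- fval(x)
  y <- x
  tk <- 1
  L <- NULL
  hist <- ox$f
  stall <- 0L
  for (it in seq_len(iters)) {
    oy <- if (identical(y, x)) ox else fval(y)
    grad <- as.numeric(Matrix::crossprod(A, oy$g))
    if (all(grad == 0)) break  # stationary: all objectives satisfied
    if (is.null(L)) L <- max(sum(grad^2) / max(oy$f, 1e-12), 1e-12)
    # backtrack L until the quadratic majorization at y holds
    repeat {
      z <- pmax(y - grad / L, 0)
      dz <- z - y
      oz <- fval(z)
      if (oz$f <= oy$f + sum(grad * dz) + L / 2 * sum(dz^2) + 1e-12) break
      L <- 2 * L
      if (L > 1e30) break
    }
    fprev <- ox$f
    if (oz$f <= ox$f) {
      tnew <- (1 + sqrt(1 + 4 * tk^2)) / 2
      y <- z + ((tk - 1) / tnew) * (z - x)
      x <- z
      ox <- oz
      tk <- tnew
      L <- L * 0.9
    } else {
      # overshoot: restart the momentum from the incumbent
      tk <- 1
      y <- x
    }
    hist <- c(hist, ox$f)
    stall <- if (fprev - ox$f <= tol * max(fprev, 1e-12)) stall + 1L else 0L
    if (stall >= 10L) break
  }
  list(x = x, d = ox$d, hist = hist)
}

#' Optimize nonnegative spot weights
#'
#' Iterative linear least squares on the structure-weighted quadratic
#' one-sided penalties of [plan_objectives()], solved by a monotone
#' accelerated projected-gradient scheme (FISTA with adaptive restart and
#' backtracking estimation of the gradient Lipschitz constant). Weights
#' stay nonnegative at every iterate and the objective sequence recorded
#' for each round is nonincreasing by construction.
#'
#' Three standard treatment-planning devices improve constraint
#' satisfaction. First, the solver's internal one-sided targets are
#' tightened by `tighten` Gy (PTV minimum raised, ring DVH dose lowered) so
#' voxels settle strictly on the feasible side of the clinical values
#' rather than asymptotically on them. Second, the internal dose-volume
#' allowance (the fraction of ring voxels left unpenalized above the DVH
#' dose) is `allowance` times the clinical fraction, leaving headroom for
#' influence-matrix sparsification and DVH binning. Third, up to `rounds`
#' solver rounds are run; after each round the penalty weight of any
#' still-violated PTV-minimum or ring-DVH objective (checked against the
#' *clinical* values) is multiplied by `escalate` and the solve continues
#' from the incumbent weights (constraint-driven priority rescaling).
#'
#' @param infl an [build_influence()] result.
#' @param obj a [plan_objectives()].
#' @param iters maximum iterations per round.
#' @param tol relative objective-change stopping tolerance.
#' @param w0 optional starting weights; default scales uniform weights to a
#'   mean PTV dose midway between the PTV objectives.
#' @param rounds maximum escalation rounds (1 = plain single solve).
#' @param escalate penalty-weight multiplier for violated objectives.
#' @param tighten internal target-tightening margin (Gy).
#' @param allowance internal fraction of the clinical DVH allowance.
#' @return list of class `fluence_fit`: `weights`, `objective` (final
#'   round's per-iterate values, nonincreasing), `rounds` (list of each
#'   round's objective history), `penalty_weights` (final), `iterations`
#'   (total), `dose` (at the sampled voxels).
#' @export
optimize_weights <- function(infl, obj = plan_objectives(), iters = 250,
                             tol = 1e-6, w0 = NULL, rounds = 5,
                             escalate = 5, tighten = 0.5, allowance = 0.9) {
  A <- infl$A
  if (length(A@x) == 0L || all(A@x == 0)) stop("influence matrix is zero")
  nsp <- ncol(A)
  if (is.null(w0)) {
    dsum <- as.numeric(A %*% rep(1, nsp))
    mptv <- mean(dsum[infl$tag == "ptv"])
    if (mptv <= 0) stop("no PTV voxel receives dose; cannot initialize")
    w0 <- rep((obj$ptv_min + obj$ptv_max) / 2 / mptv, nsp)
  }
  x <- pmax(w0, 0)
  wts <- obj$weights
  histories <- list()
  total_it <- 0L
  d <- NULL
  for (rd in seq_len(max(rounds, 1))) {
    res <- fista_round(A, infl$tag, obj, wts, tighten, allowance, iters,
                       tol, x)
    x <- res$x
    d <- res$d
    histories[[rd]] <- res$hist
    total_it <- total_it + length(res$hist) - 1L
    dp <- d[infl$tag == "ptv"]
    dr <- d[infl$tag == "ring"]
    viol_min <- min(dp) < obj$ptv_min
    viol_dvh <- mean(dr > obj$ring_dvh_dose) > obj$ring_dvh_frac
    if (!viol_min && !viol_dvh) break
    if (rd == max(rounds, 1)) break
    if (viol_min) wts[["ptv_min"]] <- wts[["ptv_min"]] * escalate
    if (viol_dvh) wts[["ring_dvh"]] <- wts[["ring_dvh"]] * escalate
  }
  structure(list(weights = x,
                 objective = histories[[length(histories)]],
                 rounds = histories, penalty_weights = wts,
                 iterations = total_it, dose = d),
            class = "fluence_fit")
}

#' Store optimized weights in a plan
#'
#' @param plan a `spot_plan`.
#' @param weights nonnegative weights, one per spot.
#' @param energy which energy column this plan delivers (`"E0"` = ORG,
#'   `"E1"` = EM).
#' @return the plan with `weight` filled and attribute `energy` set.
#' @export
set_weights <- function(plan, weights, energy = c("E0", "E1")) {
  energy <- match.arg(energy)
  if (length(weights) != nrow(plan)) {
    stop("weights length must match the spot count")
  }
  if (any(weights < 0)) stop("weights must be nonnegative")
  plan$weight <- weights
  attr(plan, "energy") <- energy
  plan
}

#' Planned dose distribution of a weighted spot plan
#'
#' Full-grid weighted superposition of unit-spot doses: the "planned" dose.
#'
#' @param dv a [density_volume()].
#' @param mm matching [assign_materials()] map.
#' @param plan a `spot_plan`.
#' @param weights weights; default the plan's `weight` column.
#' @param energy `"E0"` or `"E1"`; default the plan's `energy` attribute.
#' @param mask optional logical array restricting evaluated voxels.
#' @param model a [beam_model()]; defaults to the plan's model.
#' @return a [dose_grid()].
#' @export
plan_dose <- function(dv, mm, plan, weights = NULL, energy = NULL,
                      mask = NULL, model = NULL) {
  if (is.null(weights)) weights <- plan$weight
  if (length(weights) != nrow(plan)) {
    stop("weights length must match the spot count")
  }
  if (anyNA(weights)) stop("plan has no optimized weights")
  if (is.null(energy)) energy <- attr(plan, "energy")
  if (is.null(energy)) energy <- "E0"
  if (is.null(model)) model <- attr(plan, "model")
  if (is.null(model)) model <- beam_model()
  iso <- attr(plan, "iso")
  if (is.null(iso)) iso <- grid_center(dv)
  dims <- dim(dv$data)
  idx <- if (is.null(mask)) NULL else which(mask)
  pts <- voxel_centers(dims, dv$spacing, dv$origin, idx)
  rsp <- rsp_volume(dv, mm)
  spots <- data.frame(beam_angle = plan$beam_angle, u = plan$u, v = plan$v,
                      energy = plan[[energy]])
  d <- dose_at_points(rsp, dims, dv$spacing, dv$origin, pts, iso, spots,
                      weights, model)
  out <- array(0, dims)
  if (is.null(idx)) out[] <- d else out[idx] <- d
  dose_grid(out, dv$spacing, dv$origin)
}
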