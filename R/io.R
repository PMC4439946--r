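#' Write a spot plan as CSV table plus JSON header
#'
#' One CSV row per spot (`beam_angle, u, v, E0, E1, weight`) and a JSON
#' sidecar holding the plan metadata (isocenter, spot spacing, margin `d`,
#' arrangement, delivered energy column).
#'
#' @param plan a `spot_plan`.
#' @param basename output path without extension; writes `basename.csv` and
#'   `basename.json`.
#' @return invisibly, the CSV path.
#' @export
write_spot_plan <- function(plan, basename) {
  tab <- as.data.frame(plan)[, c("beam_angle", "u", "v", "E0", "E1",
                                 "weight")]
  write.csv(tab, paste0(basename, ".csv"), row.names = FALSE)
  meta <- list(iso = attr(plan, "iso"), spacing = attr(plan, "spacing"),
               d = attr(plan, "d"), arrangement = attr(plan, "arrangement"),
               energy = attr(plan, "energy"))
  jsonlite::write_json(meta, paste0(basename, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(basename, ".csv"))
}

#' Read a spot plan written by [write_spot_plan()]
#'
#' @param basename path without extension.
#' @return a `spot_plan` data.frame with metadata attributes restored.
#' @export
read_spot_plan <- function(basename) {
  tab <- read.csv(paste0(basename, ".csv"))
  meta <- jsonlite::read_json(paste0(basename, ".json"),
                              simplifyVector = TRUE)
  attr(tab, "iso") <- as.numeric(meta$iso)
  attr(tab, "spacing") <- meta$spacing
  attr(tab, "d") <- meta$d
  attr(tab, "arrangement") <- meta$arrangement
  if (!is.null(meta$energy)) attr(tab, "energy") <- meta$energy
  class(tab) <- c("spot_plan", "data.frame")
  tab
}

#' Write a shift set as CSV
#'
#' Columns `fraction, dx, dy, dz` with the sampling parameters in `#`
#' comment lines at the top.
#'
#' @param shifts a [sample_shifts()] matrix.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_shifts <- function(shifts, path) {
  hdr <- sprintf("# sigma=%g cutoff=%g max_3d=%g seed=%s",
                 attr(shifts, "sigma"), attr(shifts, "cutoff"),
                 attr(shifts, "max_3d"), attr(shifts, "seed"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("fraction,dx,dy,dz", con)
  for (i in seq_len(nrow(shifts))) {
    writeLines(paste(c(i, format(shifts[i, ], digits = 17)),
                     collapse = ","), con)
  }
  invisible(path)
}

#' Read a shift set written by [write_shifts()]
#'
#' @param path CSV path.
#' @return a `shift_set` matrix.
#' @export
read_shifts <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  tab <- read.csv(text = lines[!startsWith(lines, "#")])
  s <- as.matrix(tab[, c("dx", "dy", "dz")])
  dimnames(s) <- list(NULL, c("dx", "dy", "dz"))
  get_num <- function(key) {
    m <- regmatches(meta, regexpr(paste0(key, "=[^ ]+"), meta))
    if (length(m)) suppressWarnings(as.numeric(sub(".*=", "", m[1])))
    else NA_real_
  }
  structure(s, class = c("shift_set", "matrix"), sigma = get_num("sigma"),
            cutoff = get_num("cutoff"), max_3d = get_num("max_3d"),
            seed = get_num("seed"))
}

#' Write a DVH curve as CSV
#'
#' @param curve a [compute_dvh()] curve.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_dvh <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Write a variation report as CSV and JSON
#'
#' @param report a [variation_report()].
#' @param basename output path without extension.
#' @return invisibly, the CSV path.
#' @export
write_report <- function(report, basename) {
  write.csv(as.data.frame(report), paste0(basename, ".csv"),
            row.names = FALSE)
  jsonlite::write_json(as.data.frame(report), paste0(basename, ".json"),
                       digits = NA)
  invisible(paste0(basename, ".csv"))
}
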