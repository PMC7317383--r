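# Acquisition schedules: the list of (offset ppm, saturation flip angle)
# points, with reference (unsaturated, S0) volumes identified by the
# |offset| >= 800 ppm convention.

#' Build an acquisition schedule
#'
#' @param offset_ppm Saturation offsets relative to water, ppm.
#' @param sat_flip_deg Per-pulse saturation flip angle for each point,
#'   degrees; recycled.
#' @param ref_threshold_ppm Offsets with `|offset| >= ref_threshold_ppm` are
#'   treated as unsaturated reference (S0) points, one per saturation power.
#' @return A data frame of class `acq_schedule` with columns `offset_ppm`,
#'   `sat_flip_deg`, `is_ref`.
#' @export
acq_schedule <- function(offset_ppm, sat_flip_deg = 184,
                         ref_threshold_ppm = 800) {
  if (!length(offset_ppm)) stop("schedule must be non-empty")
  if (any(!is.finite(offset_ppm))) stop("offsets must be finite")
  sch <- data.frame(offset_ppm = offset_ppm,
                    sat_flip_deg = rep_len(sat_flip_deg, length(offset_ppm)))
  sch$is_ref <- abs(sch$offset_ppm) >= ref_threshold_ppm
  if (!any(sch$is_ref))
    sch <- rbind(sch,
                 data.frame(offset_ppm = 800,
                            sat_flip_deg = unique(sch$sat_flip_deg),
                            is_ref = TRUE))
  class(sch) <- c("acq_schedule", "data.frame")
  sch
}

#' Simulation schedule: 36 CEST offsets and dual-power MT offsets
#'
#' 36 uniformly spaced offsets between -5 and +5 ppm at one saturation flip
#' angle, plus MT offsets at 7.5, 15, 30, 60 and 100 ppm at two flip angles,
#' plus one 800-ppm reference per power.
#'
#' @param cest_flip_deg CEST saturation flip angle, degrees.
#' @param mt_flip_deg MT saturation flip angles, degrees.
#' @return An [acq_schedule()].
#' @export
schedule_simulation <- function(cest_flip_deg = 180,
                                mt_flip_deg = c(180, 540)) {
  cest <- seq(-5, 5, length.out = 36)
  mt <- c(7.5, 15, 30, 60, 100)
  acq_schedule(
    offset_ppm = c(cest, rep(mt, length(mt_flip_deg)),
                   rep(800, length(unique(c(cest_flip_deg, mt_flip_deg))))),
    sat_flip_deg = c(rep(cest_flip_deg, length(cest)),
                     rep(mt_flip_deg, each = length(mt)),
                     unique(c(cest_flip_deg, mt_flip_deg))))
}

#' In-vivo-style schedule: 41 CEST offsets and dual-power MT offsets
#'
#' 41 offsets between -4.5 and +4.5 ppm, sampled more densely around the
#' amide (+3.5 ppm) and NOE (-3.5 ppm) resonances, plus MT offsets at 7.5,
#' 15, 30, 60 and 100 ppm at two powers and one 800-ppm reference per power.
#'
#' @param cest_flip_deg CEST saturation flip angle, degrees.
#' @param mt_flip_deg MT saturation flip angles, degrees.
#' @return An [acq_schedule()].
#' @export
schedule_invivo <- function(cest_flip_deg = 184, mt_flip_deg = c(184, 540)) {
  cest <- sort(unique(c(seq(-4.5, 4.5, by = 0.5),
                        seq(-4.25, -2.75, by = 0.5),
                        seq(2.75, 4.25, by = 0.5),
                        c(-3.9, -3.6, -3.4, -3.1, 3.1, 3.4, 3.6, 3.9),
                        c(-1.25, -1.75, -2.25, 1.25, 1.75, 2.25))))
  stopifnot(length(cest) == 41L)
  mt <- c(7.5, 15, 30, 60, 100)
  acq_schedule(
    offset_ppm = c(cest, rep(mt, length(mt_flip_deg)),
                   rep(800, length(unique(c(cest_flip_deg, mt_flip_deg))))),
    sat_flip_deg = c(rep(cest_flip_deg, length(cest)),
                     rep(mt_flip_deg, each = length(mt)),
                     unique(c(cest_flip_deg, mt_flip_deg))))
}

#' Partition a schedule into CEST and qMT regions
#'
#' CEST points are non-reference points with `|offset| <= boundary_ppm`; qMT
#' points are non-reference points beyond the boundary.
#'
#' @param schedule An [acq_schedule()].
#' @param boundary_ppm The CEST/qMT boundary (5 ppm).
#' @return List with logical vectors `cest`, `qmt`, `ref`.
#' @export
schedule_partition <- function(schedule, boundary_ppm = 5) {
  ref <- schedule$is_ref
  cest <- !ref & abs(schedule$offset_ppm) <= boundary_ppm
  qmt <- !ref & abs(schedule$offset_ppm) > boundary_ppm
  list(cest = cest, qmt = qmt, ref = ref)
}

#' Read / write a two-column schedule file
#'
#' Plain-text schedule files have two columns, `offset_ppm` and
#' `sat_flip_deg`; reference volumes are recognized by the
#' `|offset| >= 800 ppm` convention.
#'
#' @param path File path.
#' @return [read_schedule()] returns an [acq_schedule()].
#' @export
read_schedule <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names =
                             c("offset_ppm", "sat_flip_deg"))
  acq_schedule(tab$offset_ppm, tab$sat_flip_deg)
}

#' @rdname read_schedule
#' @param schedule An [acq_schedule()] to write.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(schedule[, c("offset_ppm", "sat_flip_deg")], path,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
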