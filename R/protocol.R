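#' Build the event timing of one fMRI data segment
#'
#' The study design uses three acquisitions (breath-hold + rest, cued deep
#' breathing + rest, rest only), cut into five data segments of equal length:
#' `"BH+REST"`, `"CDB+REST"`, `"REST"`, `"REST_BH"` and `"REST_CDB"`. The
#' three `REST*` segments contain free breathing only; the two task segments
#' start with a breathing task (after a short free-breathing lead-in covering
#' the discarded volumes) and are padded with rest to the common segment
#' length. The first `n_discard` volumes of every segment are excluded from
#' analysis so all segments have the same analyzed length (390 volumes under
#' the defaults: 8 min at TR 1.2 s minus 10 volumes).
#'
#' @param segment One of `"REST"`, `"BH+REST"`, `"CDB+REST"`, `"REST_BH"`,
#'   `"REST_CDB"`.
#' @param tr_s Repetition time in seconds (default 1.2).
#' @param rest_duration_s Length of the rest-only segment in seconds
#'   (default 480 = 8 min); this also fixes the common segment duration.
#' @param n_discard Number of initial volumes excluded from analysis
#'   (default 10).
#' @param bh_cycles Number of breath-hold cycles (default 3, hypercapnic).
#' @param bh_paced_s Duration of the paced-breathing countdown before each
#'   hold (default 24 s; IN/OUT cues of `bh_cue_s` each).
#' @param bh_cue_s Duration of each paced IN or OUT cue (default 3 s).
#' @param bh_hold_s Breath-hold duration (default 15 s).
#' @param bh_recover_s Free-breathing recovery after each hold (default 18 s).
#' @param cdb_cycles Number of cued-deep-breathing blocks (default 2,
#'   hypocapnic).
#' @param cdb_breaths Number of deep breaths per block (default 4).
#' @param cdb_cue_s Duration of each deep IN or OUT cue (default 2 s).
#' @param cdb_recover_s Recovery after each deep-breathing block
#'   (default 30 s).
#'
#' @return An object of class `task_protocol`: a list with `segment`,
#'   `events` (data frame of `onset_s`, `duration_s`, `kind`), `tr_s`,
#'   `n_volumes_total`, `n_discard` and `duration_s`.
#' @examples
#' p <- make_protocol("REST")
#' n_analyzed(p) # 390
#' @export
make_protocol <- function(segment = c("REST", "BH+REST", "CDB+REST",
                                      "REST_BH", "REST_CDB"),
                          tr_s = 1.2, rest_duration_s = 480, n_discard = 10,
                          bh_cycles = 3, bh_paced_s = 24, bh_cue_s = 3,
                          bh_hold_s = 15, bh_recover_s = 18,
                          cdb_cycles = 2, cdb_breaths = 4, cdb_cue_s = 2,
                          cdb_recover_s = 30) {
  segment <- match.arg(segment)
  durs <- c(tr_s, rest_duration_s, bh_paced_s, bh_cue_s, bh_hold_s,
            bh_recover_s, cdb_cue_s, cdb_recover_s)
  if (any(!is.finite(durs)) || any(durs < 0) || tr_s <= 0)
    stop("durations must be non-negative and TR positive")
  n_total <- as.integer(round(rest_duration_s / tr_s))
  if (n_total <= 0) stop("segment contains no volumes")
  if (n_discard < 0 || n_discard >= n_total)
    stop("'n_discard' must be in [0, n_volumes_total): no analyzable volumes")
  duration_s <- n_total * tr_s
  lead_in_s <- n_discard * tr_s

  ev <- function(onset, duration, kind)
    data.frame(onset_s = onset, duration_s = duration, kind = kind,
               stringsAsFactors = FALSE)
  events <- NULL
  t <- 0
  if (segment %in% c("REST", "REST_BH", "REST_CDB")) {
    events <- ev(0, duration_s, "rest")
  } else if (segment == "BH+REST") {
    events <- ev(0, lead_in_s, "rest"); t <- lead_in_s
    n_pairs <- max(1L, as.integer(round(bh_paced_s / (2 * bh_cue_s))))
    for (cyc in seq_len(bh_cycles)) {
      for (k in seq_len(n_pairs)) {
        events <- rbind(events, ev(t, bh_cue_s, "paced_in")); t <- t + bh_cue_s
        events <- rbind(events, ev(t, bh_cue_s, "paced_out")); t <- t + bh_cue_s
      }
      events <- rbind(events, ev(t, bh_hold_s, "hold")); t <- t + bh_hold_s
      events <- rbind(events, ev(t, bh_recover_s, "recover")); t <- t + bh_recover_s
    }
    if (t >= duration_s) stop("breathing task does not fit in the segment")
    events <- rbind(events, ev(t, duration_s - t, "rest"))
  } else { # CDB+REST
    events <- ev(0, lead_in_s, "rest"); t <- lead_in_s
    for (cyc in seq_len(cdb_cycles)) {
      for (k in seq_len(cdb_breaths)) {
        events <- rbind(events, ev(t, cdb_cue_s, "deep_in")); t <- t + cdb_cue_s
        events <- rbind(events, ev(t, cdb_cue_s, "deep_out")); t <- t + cdb_cue_s
      }
      events <- rbind(events, ev(t, cdb_recover_s, "recover")); t <- t + cdb_recover_s
    }
    if (t >= duration_s) stop("breathing task does not fit in the segment")
    events <- rbind(events, ev(t, duration_s - t, "rest"))
  }
  events <- events[events$duration_s > 0, , drop = FALSE]
  rownames(events) <- NULL
  stopifnot(all(diff(events$onset_s) >= 0),
            all(events$onset_s[-1] - (events$onset_s + events$duration_s)[-nrow(events)] > -1e-9))

  structure(list(segment = segment, events = events, tr_s = tr_s,
                 n_volumes_total = n_total, n_discard = as.integer(n_discard),
                 duration_s = duration_s),
            class = "task_protocol")
}

#' Number of analyzed volumes in a segment
#' @param protocol A `task_protocol`.
#' @return Integer count of volumes retained for analysis.
#' @export
n_analyzed <- function(protocol) {
  stopifnot(inherits(protocol, "task_protocol"))
  protocol$n_volumes_total - protocol$n_discard
}

#' Acquisition times of the analyzed volumes
#' @param protocol A `task_protocol`.
#' @return Numeric vector of volume onset times in seconds (segment clock).
#' @export
volume_times <- function(protocol) {
  stopifnot(inherits(protocol, "task_protocol"))
  seq(protocol$n_discard, protocol$n_volumes_total - 1L) * protocol$tr_s
}

#' @export
print.task_protocol <- function(x, ...) {
  cat(sprintf("Task protocol '%s': %d volumes at TR %.3g s (%d discarded, %d analyzed)\n",
              x$segment, x$n_volumes_total, x$tr_s, x$n_discard, n_analyzed(x)))
  tab <- table(x$events$kind)
  cat("  events:", paste(sprintf("%s x%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
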