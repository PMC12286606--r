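#' Fusion detection parameters
#'
#' An event is scored once two objects can no longer be resolved
#' separately and stay together for the length of the remaining timelapse,
#' or at least 5 minutes. "Not resolved separately" is operationalized as
#' inter-centroid distance below `d_res_um`.
#'
#' @param d_res_um resolution distance (um), default 0.3 (just under the
#'   ribbon detection diameter of 0.427 um).
#' @param t_min_s minimum co-persistence (s), default 300 (5 min).
#' @param dt frame interval (s).
#' @return A `fusion_params` object.
#' @export
fusion_params <- function(d_res_um = 0.3, t_min_s = 300, dt = NULL) {
  if (d_res_um <= 0) rm_stop("d_res_um must be > 0")
  if (t_min_s < 0) rm_stop("t_min_s must be >= 0")
  structure(list(d_res_um = d_res_um, t_min_s = t_min_s, dt = dt),
            class = "fusion_params")
}

#' Detect fusion events between tracked objects
#'
#' For every unordered pair of tracks the detector looks for a terminal
#' coincident run: a first frame `f` such that the pair is within
#' `d_res_um` at `f` and at every later frame where both tracks exist.
#' The merged object is then carried by whichever track survives longer,
#' so both topologies are found - two tracks that continue coincident, and
#' one track terminating at the meeting with the survivor continuing. The
#' event is kept when the merged state persists at least `t_min_s`, or to
#' the end of the timelapse.
#'
#' @param tracks track table (`track_id, frame, t_s, x_um, y_um, z_um`)
#'   on a common time base.
#' @param params a [fusion_params()]; `dt` must be set (or present in the
#'   track table via `t_s`).
#' @param timelapse_end_s end of the recording (s); defaults to the last
#'   time point present in the table.
#' @return data.frame `track_id_a, track_id_b, merge_frame, merge_time_s,
#'   co_persistence_s, reaches_end` (0 rows when nothing is found).
#' @export
detect_fusions <- function(tracks, params = fusion_params(),
                           timelapse_end_s = NULL) {
  if (is.null(params$dt)) {
    tt <- sort(unique(tracks$t_s))
    if (length(tt) < 2) rm_stop("dt missing and not inferable")
    params$dt <- min(diff(tt))
  }
  dt <- params$dt
  if (is.null(timelapse_end_s)) timelapse_end_s <- max(tracks$t_s)
  ids <- sort(unique(tracks$track_id))
  by_id <- split(tracks, tracks$track_id)
  events <- list()
  if (length(ids) < 2) return(empty_fusion_events())
  for (i in seq_len(length(ids) - 1)) {
    for (j in (i + 1):length(ids)) {
      ev <- pair_fusion(by_id[[as.character(ids[i])]],
                        by_id[[as.character(ids[j])]],
                        params, timelapse_end_s)
      if (!is.null(ev)) events[[length(events) + 1]] <- ev
    }
  }
  if (length(events) == 0) return(empty_fusion_events())
  do.call(rbind, events)
}

empty_fusion_events <- function() {
  data.frame(track_id_a = integer(0), track_id_b = integer(0),
             merge_frame = integer(0), merge_time_s = numeric(0),
             co_persistence_s = numeric(0), reaches_end = logical(0))
}

pair_fusion <- function(ta, tb, params, timelapse_end_s) {
  ta <- ta[order(ta$frame), , drop = FALSE]
  tb <- tb[order(tb$frame), , drop = FALSE]
  common <- intersect(ta$frame, tb$frame)
  if (length(common) < 1) return(NULL)
  common <- sort(common)
  pa <- as.matrix(ta[match(common, ta$frame), c("x_um", "y_um", "z_um")])
  pb <- as.matrix(tb[match(common, tb$frame), c("x_um", "y_um", "z_um")])
  dist <- sqrt(rowSums((pa - pb)^2))
  close <- dist < params$d_res_um
  if (!close[length(close)]) return(NULL) # pair resolved at last co-frame
  # start of the terminal coincident run
  run_start <- length(close)
  while (run_start > 1 && close[run_start - 1]) run_start <- run_start - 1
  if (run_start == 1 && length(close) > 1 && all(close)) {
    # never resolved separately while co-existing: not a fusion, a duplicate
    return(NULL)
  }
  merge_frame <- common[run_start]
  merge_time <- ta$t_s[match(merge_frame, ta$frame)]
  # the merged object survives as the longer-lived of the two tracks
  end_time <- max(ta$t_s[nrow(ta)], tb$t_s[nrow(tb)])
  co_persistence <- end_time - merge_time
  reaches_end <- end_time >= timelapse_end_s - params$dt / 2
  if (co_persistence >= params$t_min_s || reaches_end) {
    data.frame(track_id_a = ta$track_id[1], track_id_b = tb$track_id[1],
               merge_frame = merge_frame, merge_time_s = merge_time,
               co_persistence_s = co_persistence, reaches_end = reaches_end)
  } else NULL
}

#' Fusion rate across samples
#'
#' Mean and maximum number of fusion events per sample (per neuromast in
#' the live-imaging assay).
#'
#' @param events_per_sample integer vector: events counted in each sample;
#'   alternatively a list of event tables, one per sample.
#' @param n_samples optional; defaults to `length(events_per_sample)`.
#' @return list with `mean`, `max`, `n_samples`, `total_events`.
#' @export
fusion_rate <- function(events_per_sample, n_samples = NULL) {
  if (is.list(events_per_sample) && !is.data.frame(events_per_sample))
    events_per_sample <- vapply(events_per_sample, NROW, numeric(1))
  if (is.null(n_samples)) n_samples <- length(events_per_sample)
  if (n_samples < 1) rm_stop("n_samples must be >= 1")
  total <- sum(events_per_sample)
  list(mean = total / n_samples,
       max = if (length(events_per_sample)) max(events_per_sample) else 0,
       n_samples = n_samples, total_events = total)
}
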