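#' Locate the putative centromere as the linguistic-complexity trough
#'
#' Each chromosome of a satellite-rich genome carries a single highly
#' repetitive region, megabases long, that shows up as a deep trough in the
#' linguistic-complexity track. The caller median-smooths the track, marks
#' trough windows, merges them, filters merged regions by length, and
#' returns the deepest one.
#'
#' Marking uses a half-height rule: windows are marked when their smoothed
#' value falls below `q + relax * (median - q)`, where `q` is the
#' `trough_quantile` quantile of the chromosome's values. A bare quantile
#' cutoff marks only the deepest fraction of a broad trough and truncates
#' its plateau; interpolating halfway toward the chromosome median keeps
#' the whole plateau marked while still rejecting ordinary background.
#' After selecting the best region, boundaries are refined by half a window
#' (minus a step) per side: a window is marked when roughly half of it
#' overlaps repetitive sequence, so the marked span overhangs the true
#' feature by about half a window at each end.
#'
#' @param lc_track A window track from [linguistic_complexity_track()].
#' @param min_len,max_len Acceptable centromere lengths in bp. Defaults
#'   suit ~100-Mb chromosomes with 1-10 Mb centromeres; scale them down in
#'   proportion for smaller synthetic chromosomes.
#' @param smooth_windows Running-median width (windows).
#' @param trough_quantile Quantile anchoring the trough threshold.
#' @param relax Interpolation weight toward the median (0 = bare quantile).
#' @param min_depth Minimum depth (chromosome median minus region mean) for
#'   a confident call.
#' @param merge_gap_windows Marked windows separated by at most this many
#'   windows are merged.
#' @return A list of class `centromere_call`: `chrom`, `start`, `end`,
#'   `mean_lc`, `depth`, `confidence` (`"called"` or `"none"`).
#' @export
find_centromere <- function(lc_track, min_len = 5e5, max_len = 1.2e7,
                            smooth_windows = 5L, trough_quantile = 0.05,
                            relax = 0.5, min_depth = 0.1,
                            merge_gap_windows = 10L) {
  if (is.null(lc_track) || nrow(lc_track) == 0L) stop("empty track")
  if (nrow(lc_track) < 2L * smooth_windows) {
    stop("track too short for smoothing")
  }
  chrom <- lc_track$chrom[1]
  v <- lc_track$value
  med_all <- stats::median(v, na.rm = TRUE)
  v_filled <- ifelse(is.na(v), med_all, v)
  k <- smooth_windows
  if (k %% 2L == 0L) k <- k + 1L
  sm <- as.numeric(stats::runmed(v_filled, k))

  q <- stats::quantile(sm, trough_quantile, na.rm = TRUE, names = FALSE)
  thr <- q + relax * (med_all - q)
  marked <- which(sm <= thr)

  none <- function() {
    structure(list(chrom = chrom, start = NA_integer_, end = NA_integer_,
                   mean_lc = NA_real_, depth = NA_real_,
                   confidence = "none"),
              class = "centromere_call")
  }
  if (length(marked) == 0L) return(none())

  # merge marked windows with index gaps <= merge_gap_windows
  brk <- c(0L, which(diff(marked) > merge_gap_windows + 1L), length(marked))
  regions <- lapply(seq_len(length(brk) - 1L), function(i) {
    idx <- marked[(brk[i] + 1L):brk[i + 1L]]
    c(first = idx[1], last = idx[length(idx)])
  })

  window_bp <- attr(lc_track, "window_bp")
  step_bp <- attr(lc_track, "step_bp")
  shrink <- max(0L, as.integer((window_bp - step_bp) %/% 2L))

  best <- NULL
  for (r in regions) {
    s <- lc_track$start[r["first"]] + shrink
    e <- lc_track$end[r["last"]] - shrink
    if (e - s < min_len || e - s > max_len) next
    mean_lc <- mean(v[r["first"]:r["last"]], na.rm = TRUE)
    len <- e - s
    if (is.null(best) || mean_lc < best$mean_lc ||
        (mean_lc == best$mean_lc &&
         (len > best$len || (len == best$len && s < best$start)))) {
      best <- list(first = unname(r["first"]), last = unname(r["last"]),
                   start = s, end = e, mean_lc = mean_lc, len = len)
    }
  }
  if (is.null(best)) return(none())
  depth <- med_all - best$mean_lc
  if (!is.finite(depth) || depth < min_depth) return(none())

  # floor-level boundary refinement: inside the trough the track sits on
  # a flat floor, and any background entering a window lifts its value
  # measurably, so the outermost windows still at floor level (region
  # median plus a small fraction of the depth) start/end within a few
  # hundred bp of the true feature edges
  idx <- best$first:best$last
  floor_med <- stats::median(sm[idx], na.rm = TRUE)
  thr_floor <- floor_med + 0.05 * depth
  at_floor <- idx[sm[idx] <= thr_floor]
  if (length(at_floor) == 0L) at_floor <- idx
  i0 <- at_floor[1L]
  j0 <- at_floor[length(at_floor)]
  s_ref <- lc_track$start[i0]
  e_ref <- lc_track$end[j0]
  if (e_ref <= s_ref || e_ref - s_ref < min_len ||
      e_ref - s_ref > max_len) return(none())
  structure(list(chrom = chrom, start = as.integer(round(s_ref)),
                 end = as.integer(round(e_ref)), mean_lc = best$mean_lc,
                 depth = depth, confidence = "called"),
            class = "centromere_call")
}

#' @export
print.centromere_call <- function(x, ...) {
  if (x$confidence == "none") {
    cat(sprintf("<centromere_call> %s: none\n", x$chrom))
  } else {
    cat(sprintf(
      "<centromere_call> %s:%d-%d (%.2f Mb) mean LC %.3f depth %.3f\n",
      x$chrom, x$start, x$end, (x$end - x$start) / 1e6, x$mean_lc,
      x$depth))
  }
  invisible(x)
}
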