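# Turning mined phosphopeptide candidates into deduplicated, time-segmented
# m/z inclusion lists for targeted LC-MS/MS acquisition.

#' Parameters for inclusion-list generation
#'
#' Defaults mirror the targeted pTyr acquisition setup: elution range 10-60
#' minutes split into 10 equal segments, 1.5 min extra retention-time
#' tolerance per window, m/z rounded to 2 decimals.
#'
#' @param t_start,t_end Elution range (minutes).
#' @param n_segments Number of equal time segments.
#' @param extra_rt_tol Extra retention-time tolerance added on both sides of
#'   each window (minutes).
#' @param round_decimals Decimals used to round (and deduplicate) m/z.
#' @param window_mode `"candidate_extent"` (window spans the observed RTs of
#'   the merged candidate, padded by `extra_rt_tol`) or `"segment"` (window
#'   is the assigned segment padded by `extra_rt_tol`).
#' @param rounding `"half_away"` (spreadsheet convention, default) or
#'   `"half_even"` (banker's rounding via [round()]).
#' @param max_per_segment Optional per-segment capacity limit honouring
#'   instrument inclusion-list size limits; `Inf` keeps everything.
#' @return An object of class `inclusion_params`.
#' @export
inclusion_params <- function(t_start = 10, t_end = 60, n_segments = 10L,
                             extra_rt_tol = 1.5, round_decimals = 2L,
                             window_mode = c("candidate_extent", "segment"),
                             rounding = c("half_away", "half_even"),
                             max_per_segment = Inf) {
  window_mode <- match.arg(window_mode)
  rounding <- match.arg(rounding)
  stopifnot(t_start < t_end, n_segments >= 1, round_decimals >= 0,
            extra_rt_tol >= 0)
  structure(list(t_start = t_start, t_end = t_end,
                 n_segments = as.integer(n_segments),
                 extra_rt_tol = extra_rt_tol,
                 round_decimals = as.integer(round_decimals),
                 window_mode = window_mode, rounding = rounding,
                 max_per_segment = max_per_segment),
            class = "inclusion_params")
}

#' Round an m/z value to a fixed number of decimals
#'
#' Default mode rounds half away from zero (the spreadsheet convention, e.g.
#' 812.8579 -> 812.86 and 1.005 -> 1.01); a small relative epsilon guards
#' against decimal literals that sit just below a half boundary in binary
#' floating point. `"half_even"` delegates to base [round()].
#'
#' @param mz m/z value(s) in Thomson.
#' @param decimals Non-negative number of decimals.
#' @param mode `"half_away"` or `"half_even"`.
#' @return Rounded value(s).
#' @export
round_mz <- function(mz, decimals = 2L, mode = c("half_away", "half_even")) {
  mode <- match.arg(mode)
  if (decimals < 0) stop("decimals must be >= 0", call. = FALSE)
  if (mode == "half_even") return(round(mz, decimals))
  p <- 10^decimals
  scaled <- mz * p
  eps <- abs(scaled) * .Machine$double.eps * 4
  sign(mz) * floor(abs(scaled) + 0.5 + eps) / p
}

#' Deduplicate candidates by rounded untreated m/z
#'
#' Candidates whose untreated m/z values collide after rounding (for example
#' the same signal observed in different biological replicates or conditions)
#' are merged into one inclusion-list precursor. The merged precursor keeps
#' the union of member retention times (extent and full list), the union of
#' source condition labels, and the set of phosphate counts observed.
#'
#' @param candidates A `shift_candidates` / candidate set (or a list of them,
#'   which is combined first), carrying at least `untreated_mz`,
#'   `untreated_rt`, `n_mods`; optional `rt_min`/`rt_max`/`member_rts` from
#'   [merge_replicates()] and `condition`.
#' @param decimals Rounding decimals.
#' @param rounding Rounding mode, see [round_mz()].
#' @return A data frame of class `inclusion_precursors` with columns
#'   `mz_rounded`, `rt_min`, `rt_max`, `rt_median`, `member_rts`,
#'   `n_members`, `n_mods`, `source_conditions`.
#' @export
deduplicate <- function(candidates, decimals = 2L, rounding = "half_away") {
  if (is.list(candidates) && !is.data.frame(candidates))
    candidates <- combine_conditions(candidates)
  df <- as.data.frame(candidates)
  empty <- data.frame(mz_rounded = numeric(), rt_min = numeric(),
                      rt_max = numeric(), rt_median = numeric(),
                      member_rts = character(), n_members = integer(),
                      n_mods = character(), source_conditions = character(),
                      stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    return(structure(empty, class = c("inclusion_precursors", "data.frame")))
  if (inherits(candidates, "inclusion_precursors")) {
    key_mz <- df$mz_rounded
    rts <- strsplit(df$member_rts, ";", fixed = TRUE)
    conds <- strsplit(df$source_conditions, ";", fixed = TRUE)
    mods <- strsplit(df$n_mods, ";", fixed = TRUE)
    members <- df$n_members
  } else {
    key_mz <- df$untreated_mz
    rts <- if ("member_rts" %in% names(df))
      strsplit(df$member_rts, ";", fixed = TRUE)
    else as.list(df$untreated_rt)
    conds <- as.list(if ("condition" %in% names(df)) df$condition
                     else rep("unlabelled", nrow(df)))
    mods <- as.list(df$n_mods)
    members <- rep(1L, nrow(df))
  }
  rounded <- round_mz(as.numeric(key_mz), decimals, rounding)
  key <- format(rounded, nsmall = decimals, trim = TRUE, scientific = FALSE)
  groups <- split(seq_len(nrow(df)), key)
  rows <- lapply(groups, function(idx) {
    rt_all <- sort(as.numeric(unlist(rts[idx])))
    data.frame(
      mz_rounded = rounded[idx[1]],
      rt_min = min(rt_all), rt_max = max(rt_all),
      rt_median = stats::median(rt_all),
      member_rts = paste(rt_all, collapse = ";"),
      n_members = sum(members[idx]),
      n_mods = paste(sort(unique(as.integer(unlist(mods[idx])))),
                     collapse = ";"),
      source_conditions = paste(sort(unique(unlist(conds[idx]))),
                                collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mz_rounded), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("inclusion_precursors", "data.frame"))
}

#' Combine candidate sets from different sample conditions
#'
#' Takes the union of candidates mined from different experimental conditions
#' (e.g. control and drug treatment), preserving each candidate's condition
#' label so that downstream deduplication records which conditions
#' contributed a given precursor.
#'
#' @param sets A list of `shift_candidates` / candidate sets.
#' @return A single `shift_candidates` with a `condition` column.
#' @export
combine_conditions <- function(sets) {
  if (inherits(sets, "shift_candidates")) sets <- list(sets)
  dfs <- lapply(sets, function(s) {
    df <- as.data.frame(s)
    if (!"condition" %in% names(df))
      df$condition <- rep(attr(s, "condition") %||% "unlabelled",
                          length.out = nrow(df))
    df
  })
  cols <- Reduce(union, lapply(dfs, names))
  dfs <- lapply(dfs, function(df) {
    for (cc in setdiff(cols, names(df))) df[[cc]] <- NA
    df[, cols, drop = FALSE]
  })
  out <- do.call(rbind, dfs)
  rownames(out) <- NULL
  new_shift_candidates(out, NA_integer_, "combined")
}

#' Build a time-segmented inclusion list
#'
#' Splits `[t_start, t_end]` into `n_segments` equal half-open segments
#' (the last segment closed) and assigns each precursor to the segment
#' containing its representative retention time (the median of its member
#' RTs); precursors eluting outside the range are clamped to the nearest
#' segment. The acquisition window of each entry is either its segment padded
#' by `extra_rt_tol` (`window_mode = "segment"`) or the min-max extent of its
#' member RTs padded by `extra_rt_tol` (`"candidate_extent"`, the default).
#'
#' @param precursors An `inclusion_precursors` table from [deduplicate()], or
#'   candidates acceptable to it.
#' @param params An [inclusion_params()].
#' @return An `inclusion_list`: data frame with columns `mz_rounded`,
#'   `window_start`, `window_end`, `segment_index`, `rt_median`, `n_mods`,
#'   `source_conditions`, sorted by segment then m/z.
#' @export
build_inclusion_list <- function(precursors, params = inclusion_params()) {
  if (!inherits(precursors, "inclusion_precursors"))
    precursors <- deduplicate(precursors, params$round_decimals,
                              params$rounding)
  df <- as.data.frame(precursors)
  width <- (params$t_end - params$t_start) / params$n_segments
  bounds <- params$t_start + width * (0:params$n_segments)
  if (nrow(df) == 0L) {
    out <- data.frame(mz_rounded = numeric(), window_start = numeric(),
                      window_end = numeric(), segment_index = integer(),
                      rt_median = numeric(), n_mods = character(),
                      source_conditions = character(),
                      stringsAsFactors = FALSE)
    return(structure(out, params = params, segment_bounds = bounds,
                     class = c("inclusion_list", "data.frame")))
  }
  seg <- findInterval(df$rt_median, bounds, rightmost.closed = TRUE)
  clamped <- seg < 1L | seg > params$n_segments
  if (any(clamped))
    message(sum(clamped), " precursor(s) outside [", params$t_start, ", ",
            params$t_end, "] min clamped to the nearest segment")
  seg <- pmin(pmax(seg, 1L), params$n_segments)
  if (params$window_mode == "segment") {
    ws <- bounds[seg] - params$extra_rt_tol
    we <- bounds[seg + 1L] + params$extra_rt_tol
  } else {
    ws <- df$rt_min - params$extra_rt_tol
    we <- df$rt_max + params$extra_rt_tol
  }
  out <- data.frame(mz_rounded = df$mz_rounded, window_start = ws,
                    window_end = we, segment_index = seg,
                    rt_median = df$rt_median, n_mods = df$n_mods,
                    source_conditions = df$source_conditions,
                    stringsAsFactors = FALSE)
  out <- out[order(out$segment_index, out$mz_rounded), , drop = FALSE]
  if (is.finite(params$max_per_segment)) {
    keep <- unlist(lapply(split(seq_len(nrow(out)), out$segment_index),
                          function(idx) idx[seq_len(min(length(idx),
                                            params$max_per_segment))]))
    out <- out[sort(keep), , drop = FALSE]
  }
  rownames(out) <- NULL
  structure(out, params = params, segment_bounds = bounds,
            class = c("inclusion_list", "data.frame"))
}

#' Write an inclusion list as instrument-style CSV
#'
#' Writes the common instrument inclusion format — columns `Mass [m/z]`,
#' `Formula`, `Species`, `CS [z]`, `Polarity`, `Start [min]`, `End [min]` —
#' or a plain 3-column variant (`mz, start, end`). `split_segments = TRUE`
#' writes one file per time segment, suffixed `_segNN`.
#'
#' @param x An `inclusion_list`.
#' @param path Output CSV path.
#' @param format `"instrument"` or `"plain"`.
#' @param split_segments Write one file per segment.
#' @param polarity Polarity string for the instrument format.
#' @return The path(s) written, invisibly.
#' @export
write_inclusion_csv <- function(x, path,
                                format = c("instrument", "plain"),
                                split_segments = FALSE,
                                polarity = "Positive") {
  format <- match.arg(format)
  render <- function(df) {
    if (format == "plain")
      data.frame(mz = df$mz_rounded, start = df$window_start,
                 end = df$window_end, check.names = FALSE)
    else
      data.frame(`Mass [m/z]` = df$mz_rounded, Formula = "", Species = "",
                 `CS [z]` = "", Polarity = polarity,
                 `Start [min]` = df$window_start,
                 `End [min]` = df$window_end, check.names = FALSE)
  }
  df <- as.data.frame(x)
  if (!split_segments) {
    utils::write.csv(render(df), path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  paths <- vapply(split(df, df$segment_index), function(d) {
    p <- sub("(\\.[^.]+)?$",
             sprintf("_seg%02d\\1", d$segment_index[1]), path)
    utils::write.csv(render(d), p, row.names = FALSE, quote = FALSE)
    p
  }, character(1))
  invisible(unname(paths))
}

#' @export
print.inclusion_list <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "<inclusion_list> %d target(s), %d segment(s) over %.1f-%.1f min (%s windows)\n",
    nrow(x), p$n_segments, p$t_start, p$t_end, p$window_mode))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 6), ...)
  invisible(x)
}

#' @export
summary.inclusion_list <- function(object, ...) {
  p <- attr(object, "params")
  cat(sprintf("Inclusion list: %d target(s)\n", nrow(object)))
  cat(sprintf("  segment width %.3f min; extra tolerance %.2f min\n",
              (p$t_end - p$t_start) / p$n_segments, p$extra_rt_tol))
  if (nrow(object) > 0) {
    tb <- table(factor(object$segment_index, levels = 1:p$n_segments))
    cat("  targets per segment: ", paste(tb, collapse = " "), "\n")
  }
  invisible(object)
}
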