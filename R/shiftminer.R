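# Mining candidate phosphopeptide signals: peak pairs whose neutral masses
# differ by n multiples of the phosphate-group mass, within mass and
# retention-time tolerances, between an untreated run and its
# alkaline-phosphatase-treated counterpart.

#' Parameters for phosphopeptide signal mining
#'
#' Defaults follow a published pTyr cell-lysate configuration: top 3000
#' peaks per run, 79.966 Da shift per
#' phosphate, 0.05 Da mass tolerance, 5 min retention-time shift tolerance,
#' up to 5 phosphate groups, charge state at least 2.
#'
#' @param delta_mass Mass lost per dephosphorylation event (Da). The default
#'   is the phosphate-group (HPO3) monoisotopic mass; other values let the
#'   miner target other post-translational modifications.
#' @param mass_tol Mass-shift tolerance (Da).
#' @param rt_tol Retention-time shift tolerance (minutes).
#' @param max_mods Maximum number of phosphate groups per peptide.
#' @param min_charge Minimum charge state; peaks lacking a charge are dropped
#'   when `min_charge > 1`.
#' @param top_n Intensity-rank cut-off, or `"auto"` to use the
#'   [intensity_knee()] suggestion.
#' @param intensity_floor Minimum peak intensity retained.
#' @param same_charge Require untreated/treated partners to share charge
#'   state. Off by default: matching is on neutral mass, so partners may be
#'   observed at different charge states.
#' @return An object of class `miner_params`.
#' @export
miner_params <- function(delta_mass = PHOSPHO_MASS, mass_tol = 0.05,
                         rt_tol = 5, max_mods = 5L, min_charge = 2L,
                         top_n = 3000L, intensity_floor = 0,
                         same_charge = FALSE) {
  stopifnot(delta_mass > 0, mass_tol > 0, rt_tol >= 0, max_mods >= 1,
            min_charge >= 1)
  if (!identical(top_n, "auto")) top_n <- as.integer(top_n)
  structure(list(delta_mass = delta_mass, mass_tol = mass_tol,
                 rt_tol = rt_tol, max_mods = as.integer(max_mods),
                 min_charge = as.integer(min_charge), top_n = top_n,
                 intensity_floor = intensity_floor,
                 same_charge = isTRUE(same_charge)),
            class = "miner_params")
}

#' Suggest a top-N cut-off from the intensity-rank curve
#'
#' Sorts intensities in descending order and returns the rank immediately
#' before the largest drop between consecutive sorted intensities — the
#' "greatest slope change" of the intensity-rank chart. Ties are broken
#' toward the smaller N. A series with no drop (constant intensities)
#' retains every peak.
#'
#' @param peaks A `peaklist` or numeric vector of intensities.
#' @return Suggested cut-off N (1-based count).
#' @export
intensity_knee <- function(peaks) {
  intens <- if (is.data.frame(peaks)) peaks$intensity else as.numeric(peaks)
  n <- length(intens)
  if (n < 3L) {
    warning("fewer than 3 peaks; retaining all", call. = FALSE)
    return(n)
  }
  s <- sort(intens, decreasing = TRUE)
  drops <- s[-n] - s[-1]
  if (max(drops) <= 0) return(n)
  which.max(drops) # which.max already ties toward the smaller index
}

#' Intensity-rank series for cut-off inspection
#'
#' Pure data behind the visual chart used to pick the intensity cut-off:
#' the descending-sorted intensity series indexed by rank.
#'
#' @param peaks A `peaklist` or numeric vector of intensities.
#' @return A data frame with columns `rank` and `intensity`, non-increasing.
#' @export
intensity_chart_data <- function(peaks) {
  intens <- if (is.data.frame(peaks)) peaks$intensity else as.numeric(peaks)
  s <- sort(intens, decreasing = TRUE)
  data.frame(rank = seq_along(s), intensity = s)
}

#' Filter a peak list by charge, intensity floor, and top-N truncation
#'
#' Retains peaks with charge >= `min_charge` (peaks without a charge are
#' dropped when `min_charge > 1`) and intensity >= `intensity_floor`, then
#' truncates to the `top_n` most intense survivors. Equal intensities are
#' broken deterministically by ascending m/z.
#'
#' @param peaks A `peaklist`.
#' @param params A [miner_params()].
#' @return The filtered `peaklist`.
#' @export
filter_peaks <- function(peaks, params = miner_params()) {
  df <- as.data.frame(peaks)
  if (nrow(df) > 0) {
    keep <- df$intensity >= params$intensity_floor
    if (params$min_charge > 1L)
      keep <- keep & !is.na(df$charge) & df$charge >= params$min_charge
    else
      keep <- keep & (is.na(df$charge) | df$charge >= params$min_charge)
    df <- df[keep, , drop = FALSE]
    top_n <- if (identical(params$top_n, "auto")) intensity_knee(df) else
      params$top_n
    if (nrow(df) > top_n) {
      ord <- order(-df$intensity, df$mz)
      df <- df[ord[seq_len(top_n)], , drop = FALSE]
      df <- df[order(df$mz), , drop = FALSE]
    }
    rownames(df) <- NULL
  }
  new_peaklist(df, attr(peaks, "run_id"), attr(peaks, "condition"),
               attr(peaks, "replicate"), attr(peaks, "skipped"))
}

new_shift_candidates <- function(df, replicate = NA_integer_,
                                 condition = NA_character_) {
  structure(df, replicate = replicate, condition = condition,
            class = c("shift_candidates", "data.frame"))
}

empty_candidates <- function() {
  data.frame(untreated_mz = numeric(), untreated_charge = integer(),
             untreated_mass = numeric(), untreated_rt = numeric(),
             untreated_intensity = numeric(), treated_mz = numeric(),
             treated_mass = numeric(), treated_rt = numeric(),
             treated_intensity = numeric(), n_mods = integer(),
             mass_error = numeric(), rt_diff = numeric(),
             replicate = integer(), stringsAsFactors = FALSE)
}

#' Mine phosphate-loss peak pairs from one untreated/treated run pair
#'
#' For every untreated peak u and every phosphate count n in `1..max_mods`,
#' emits a candidate for the treated peak t satisfying
#' `|(mass_u - mass_t) - n * delta_mass| <= mass_tol` and
#' `|rt_u - rt_t| <= rt_tol`. When one u matches several t for the same n,
#' the match with the smallest absolute mass error (then smallest absolute
#' retention-time difference) is kept; a u may still appear with several
#' distinct n values (multiply phosphorylated forms are real). Matching is
#' on neutral monoisotopic mass, so partners may differ in charge state
#' unless `params$same_charge` is set.
#'
#' The search sorts the treated list by mass and scans tolerance windows via
#' binary search; its output is contractually identical to the exhaustive
#' all-pairs enumeration.
#'
#' @param untreated,treated `peaklist` objects; apply [filter_peaks()] first.
#' @param params A [miner_params()].
#' @param prefiltered Set `FALSE` to have the function apply
#'   [filter_peaks()] itself.
#' @return A `shift_candidates` data frame with one row per (u, n) match:
#'   untreated/treated peak coordinates, `n_mods`, signed `mass_error`
#'   (observed shift minus `n * delta_mass`), signed `rt_diff`, `replicate`.
#' @export
mine_pair <- function(untreated, treated, params = miner_params(),
                      prefiltered = TRUE) {
  if (!prefiltered) {
    untreated <- filter_peaks(untreated, params)
    treated <- filter_peaks(treated, params)
  }
  u <- as.data.frame(untreated)
  t_ <- as.data.frame(treated)
  u <- u[!is.na(u$mass), , drop = FALSE]
  t_ <- t_[!is.na(t_$mass), , drop = FALSE]
  rep_id <- attr(untreated, "replicate")
  if (nrow(u) == 0L || nrow(t_) == 0L)
    return(new_shift_candidates(empty_candidates(), rep_id,
                                attr(untreated, "condition")))
  ord <- order(t_$mass)
  t_ <- t_[ord, , drop = FALSE]
  tmass <- t_$mass
  out <- vector("list", nrow(u) * params$max_mods)
  k <- 0L
  for (i in seq_len(nrow(u))) {
    for (n in seq_len(params$max_mods)) {
      target <- u$mass[i] - n * params$delta_mass
      lo <- findInterval(target - params$mass_tol, tmass) + 1L
      hi <- findInterval(target + params$mass_tol, tmass)
      if (hi < lo) next
      j <- lo:hi
      rt_ok <- abs(u$rt[i] - t_$rt[j]) <= params$rt_tol
      if (params$same_charge)
        rt_ok <- rt_ok & !is.na(u$charge[i]) & !is.na(t_$charge[j]) &
          u$charge[i] == t_$charge[j]
      j <- j[rt_ok]
      if (length(j) == 0L) next
      merr <- (u$mass[i] - tmass[j]) - n * params$delta_mass
      rdiff <- u$rt[i] - t_$rt[j]
      best <- j[order(abs(merr), abs(rdiff))[1L]]
      k <- k + 1L
      out[[k]] <- data.frame(
        untreated_mz = u$mz[i], untreated_charge = u$charge[i],
        untreated_mass = u$mass[i], untreated_rt = u$rt[i],
        untreated_intensity = u$intensity[i],
        treated_mz = t_$mz[best], treated_mass = t_$mass[best],
        treated_rt = t_$rt[best], treated_intensity = t_$intensity[best],
        n_mods = n,
        mass_error = (u$mass[i] - t_$mass[best]) - n * params$delta_mass,
        rt_diff = u$rt[i] - t_$rt[best],
        replicate = rep_id, stringsAsFactors = FALSE)
    }
  }
  df <- if (k == 0L) empty_candidates() else do.call(rbind, out[seq_len(k)])
  rownames(df) <- NULL
  new_shift_candidates(df, rep_id, attr(untreated, "condition"))
}

#' Merge mined candidates across replicate run pairs
#'
#' Clusters candidates from several replicates by their untreated-peak
#' coordinates (m/z, retention time) with greedy single-linkage: candidates
#' are visited in descending untreated intensity; each unassigned candidate
#' seeds a cluster that is grown transitively with every unassigned candidate
#' within `cluster_mz_tol` and `cluster_rt_tol` of a member. Each cluster is
#' represented by its most intense member, annotated with `support` (the
#' number of distinct replicates contributing) and the RT extent of its
#' members; clusters with `support < min_support` are discarded.
#'
#' @param per_replicate A list of `shift_candidates` (one per replicate pair)
#'   or a single `shift_candidates`.
#' @param cluster_mz_tol m/z tolerance for clustering (Th).
#' @param cluster_rt_tol Retention-time tolerance for clustering (minutes).
#' @param min_support Minimum number of replicates a merged candidate must
#'   appear in.
#' @param condition Condition label stored on the result.
#' @return A `candidate_set`: a `shift_candidates` data frame with extra
#'   columns `support`, `rt_min`, `rt_max`, `member_rts` (semicolon-joined
#'   untreated RTs of all members), and `condition`.
#' @export
merge_replicates <- function(per_replicate, cluster_mz_tol = 0.01,
                             cluster_rt_tol = 2, min_support = 1L,
                             condition = NULL) {
  if (inherits(per_replicate, "shift_candidates"))
    per_replicate <- list(per_replicate)
  if (is.null(condition)) {
    conds <- unique(stats::na.omit(
      vapply(per_replicate, function(x) attr(x, "condition") %||%
               NA_character_, character(1))))
    condition <- if (length(conds) == 1) conds else "combined"
  }
  all_df <- do.call(rbind, lapply(per_replicate, as.data.frame))
  if (is.null(all_df) || nrow(all_df) == 0L) {
    out <- cbind(empty_candidates(),
                 data.frame(support = integer(), rt_min = numeric(),
                            rt_max = numeric(), member_rts = character(),
                            condition = character()))
    return(new_shift_candidates(out, NA_integer_, condition))
  }
  n_reps <- length(unique(all_df$replicate))
  if (min_support > n_reps) {
    warning("min_support (", min_support, ") exceeds the number of ",
            "replicate pairs (", n_reps, "); no candidate can qualify",
            call. = FALSE)
  }
  ord <- order(-all_df$untreated_intensity)
  assigned <- rep(FALSE, nrow(all_df))
  clusters <- list()
  for (i in ord) {
    if (assigned[i]) next
    members <- i
    assigned[i] <- TRUE
    repeat {
      cand <- which(!assigned)
      if (length(cand) == 0L) break
      near <- cand[vapply(cand, function(j) {
        any(abs(all_df$untreated_mz[j] - all_df$untreated_mz[members]) <=
              cluster_mz_tol &
            abs(all_df$untreated_rt[j] - all_df$untreated_rt[members]) <=
              cluster_rt_tol)
      }, logical(1))]
      if (length(near) == 0L) break
      assigned[near] <- TRUE
      members <- c(members, near)
    }
    clusters[[length(clusters) + 1L]] <- members
  }
  rows <- lapply(clusters, function(m) {
    rep_row <- m[which.max(all_df$untreated_intensity[m])]
    row <- all_df[rep_row, , drop = FALSE]
    row$support <- length(unique(all_df$replicate[m]))
    row$rt_min <- min(all_df$untreated_rt[m])
    row$rt_max <- max(all_df$untreated_rt[m])
    row$member_rts <- paste(sort(all_df$untreated_rt[m]), collapse = ";")
    row
  })
  out <- do.call(rbind, rows)
  out <- out[out$support >= min_support, , drop = FALSE]
  out$condition <- rep(condition, nrow(out))
  rownames(out) <- NULL
  new_shift_candidates(out, NA_integer_, condition)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read the candidate table dialect (TSV)
#'
#' @param x A `shift_candidates`.
#' @param path Output/input path.
#' @return `path` (writer) or a `shift_candidates` (reader).
#' @export
write_candidates <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if ("member_rts" %in% names(df)) df$member_rts <- as.character(df$member_rts)
  cond <- if ("condition" %in% names(df) && nrow(df) > 0)
    df$condition[1] else NA_character_
  new_shift_candidates(df, NA_integer_, cond)
}

#' @export
print.shift_candidates <- function(x, ...) {
  cat(sprintf("<shift_candidates> %d candidate pair(s)", nrow(x)))
  if (!is.na(attr(x, "condition") %||% NA))
    cat(sprintf(" [condition: %s]", attr(x, "condition")))
  cat("\n")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 6), ...)
  invisible(x)
}

#' @export
summary.shift_candidates <- function(object, ...) {
  cat(sprintf("%d candidate phosphopeptide signal(s)\n", nrow(object)))
  if (nrow(object) > 0) {
    cat("  by phosphate count: ")
    tb <- table(object$n_mods)
    cat(paste0("n=", names(tb), ": ", tb, collapse = ", "), "\n")
    cat(sprintf("  |mass error| median %.4f Da, max %.4f Da\n",
                stats::median(abs(object$mass_error)),
                max(abs(object$mass_error))))
  }
  invisible(object)
}

#' Plot the intensity-rank chart with the knee cut-off
#'
#' @param x A `peaklist`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.peaklist <- function(x, ...) {
  d <- intensity_chart_data(x)
  graphics::plot(d$rank, d$intensity, type = "l", log = "y",
                 xlab = "intensity rank", ylab = "intensity", ...)
  if (nrow(d) >= 3) graphics::abline(v = intensity_knee(x), lty = 2)
  invisible(x)
}
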