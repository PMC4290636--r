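# Joining search-engine phosphopeptide identifications to pattern-based
# label-free quantification features: phospho-type and score filtering,
# m/z-RT-charge matching, abundance ratios, ANOVA, and Mascot delta scores
# for site-localization confidence.

#' Parameters for identification-quantification linking
#'
#' Defaults follow the targeted pTyr analysis: Mascot ion score above 25,
#' 0.2 Da m/z tolerance, 2 min retention-time tolerance, pTyr modification.
#'
#' @param mz_tol m/z matching tolerance (Th).
#' @param rt_tol Retention-time matching tolerance (minutes).
#' @param min_score Minimum search-engine ion score.
#' @param phospho_filter Residue types to keep; subset of
#'   `c("pSer", "pThr", "pTyr")` (or single letters S/T/Y). An identification
#'   is kept when at least one of its phosphosites is of a requested type.
#' @param require_charge_match Require identical charge state between an
#'   identification and its linked feature.
#' @param keep_all_matches Link every qualifying feature instead of the
#'   single best match.
#' @return An object of class `link_params`.
#' @export
link_params <- function(mz_tol = 0.2, rt_tol = 2, min_score = 25,
                        phospho_filter = "pTyr",
                        require_charge_match = TRUE,
                        keep_all_matches = FALSE) {
  stopifnot(mz_tol > 0, rt_tol > 0)
  letters_map <- c(pSer = "S", pThr = "T", pTyr = "Y",
                   S = "S", T = "T", Y = "Y")
  residues <- unname(letters_map[phospho_filter])
  if (any(is.na(residues)))
    stop("phospho_filter must be among pSer/pThr/pTyr (or S/T/Y)",
         call. = FALSE)
  structure(list(mz_tol = mz_tol, rt_tol = rt_tol, min_score = min_score,
                 phospho_residues = unique(residues),
                 require_charge_match = isTRUE(require_charge_match),
                 keep_all_matches = isTRUE(keep_all_matches)),
            class = "link_params")
}

#' Parse phosphosite annotations from a modification string
#'
#' Extracts phosphorylated residues and positions from a search-engine
#' modification string. The `mascot_csv` dialect accepts site tokens of the
#' form `pY10` (residue letter + 1-based position) or `Phospho (Y10)`,
#' separated arbitrarily; non-phospho modifications (e.g.
#' `Oxidation (M3)`, `Carbamidomethyl (C)`, `Deamidated (N)`) are ignored.
#' A site whose position lies outside the sequence or whose residue letter
#' disagrees with the sequence is reported as invalid.
#'
#' @param sequence Amino-acid sequence.
#' @param mod_string Modification annotation text.
#' @param dialect Currently only `"mascot_csv"`.
#' @return A data frame with columns `residue`, `position`, and `valid`
#'   (logical); zero rows for an empty or phospho-free string.
#' @export
parse_mod_string <- function(sequence, mod_string,
                             dialect = c("mascot_csv")) {
  dialect <- match.arg(dialect)
  empty <- data.frame(residue = character(), position = integer(),
                      valid = logical(), stringsAsFactors = FALSE)
  if (is.na(mod_string) || !nzchar(trimws(mod_string))) return(empty)
  pat <- "p([STY])(\\d+)|Phospho\\s*\\(([STY])(\\d+)\\)"
  m <- gregexpr(pat, mod_string, perl = TRUE)
  toks <- regmatches(mod_string, m)[[1]]
  if (length(toks) == 0L) return(empty)
  residue <- sub(pat, "\\1\\3", toks, perl = TRUE)
  position <- as.integer(sub(pat, "\\2\\4", toks, perl = TRUE))
  seq_chars <- strsplit(sequence, "")[[1]]
  valid <- position >= 1L & position <= length(seq_chars)
  valid[valid] <- seq_chars[position[valid]] == residue[valid]
  out <- unique(data.frame(residue = residue, position = position,
                           valid = valid, stringsAsFactors = FALSE))
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a Mascot-style identification CSV
#'
#' Expects (remappable) columns `sequence, mod_string, mz, charge, rt, score,
#' accession`. Phosphosites are parsed with [parse_mod_string()];
#' identifications with an invalid site annotation are excluded with a
#' message.
#'
#' @param path CSV path.
#' @param columns Named character vector remapping canonical field names to
#'   the file's headers.
#' @return A data frame of class `peptide_ids` with an extra `phospho_sites`
#'   column (semicolon-joined `pX<pos>` tokens) and `n_sites`.
#' @export
read_peptide_ids <- function(path, columns = c(
    sequence = "sequence", mod_string = "mod_string", mz = "mz",
    charge = "charge", rt = "rt", score = "score",
    accession = "accession")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unname(columns), names(raw))
  if (length(missing))
    stop("identification file lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- data.frame(sequence = raw[[columns["sequence"]]],
                   mod_string = raw[[columns["mod_string"]]],
                   mz = as.numeric(raw[[columns["mz"]]]),
                   charge = as.integer(raw[[columns["charge"]]]),
                   rt = as.numeric(raw[[columns["rt"]]]),
                   score = as.numeric(raw[[columns["score"]]]),
                   accession = raw[[columns["accession"]]],
                   stringsAsFactors = FALSE)
  annotate_peptide_ids(df)
}

#' Annotate an identification table with parsed phosphosites
#'
#' @param df Data frame with `sequence` and `mod_string` columns.
#' @return The table with `phospho_sites` / `n_sites` columns, class
#'   `peptide_ids`; rows with invalid site annotations dropped.
#' @export
annotate_peptide_ids <- function(df) {
  sites <- mapply(parse_mod_string, df$sequence, df$mod_string,
                  SIMPLIFY = FALSE, USE.NAMES = FALSE)
  invalid <- vapply(sites, function(s) nrow(s) > 0 && any(!s$valid),
                    logical(1))
  if (any(invalid))
    message(sum(invalid),
            " identification(s) with inconsistent site annotation excluded")
  df$phospho_sites <- vapply(sites, function(s) {
    s <- s[s$valid, , drop = FALSE]
    paste0("p", s$residue, s$position, collapse = ";")
  }, character(1))
  df$phospho_sites[df$phospho_sites == "p"] <- ""
  df$n_sites <- vapply(sites, function(s) sum(s$valid), integer(1))
  df <- df[!invalid, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("peptide_ids", "data.frame"))
}

site_residues <- function(phospho_sites) {
  lapply(strsplit(phospho_sites, ";", fixed = TRUE),
         function(tok) sub("^p([STY]).*$", "\\1", tok[nzchar(tok)]))
}

#' Read a label-free quantification feature CSV
#'
#' Expects columns `feature_id, mz, charge, rt` plus one abundance column per
#' LC-MS run; `run_groups` maps run column names to condition labels
#' (e.g. `c(ctrl_1 = "control", drug_1 = "treatment")`).
#'
#' @param path CSV path.
#' @param run_groups Named character vector: names are abundance column
#'   headers, values are condition labels. Must contain at least two distinct
#'   conditions with at least one run each.
#' @return A data frame of class `quant_features`, with attribute
#'   `run_groups`.
#' @export
read_quant_features <- function(path, run_groups) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("feature_id", "mz", "charge", "rt")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("quantification file lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  missing_runs <- setdiff(names(run_groups), names(raw))
  if (length(missing_runs))
    stop("run column(s) absent from quantification file: ",
         paste(missing_runs, collapse = ", "), call. = FALSE)
  quant_features(raw, run_groups)
}

#' @rdname read_quant_features
#' @param df In-memory feature table with the same columns.
#' @export
quant_features <- function(df, run_groups) {
  if (length(unique(run_groups)) < 2)
    stop("run_groups must define at least two conditions", call. = FALSE)
  for (rc in names(run_groups)) {
    df[[rc]] <- as.numeric(df[[rc]])
    if (any(df[[rc]] < 0, na.rm = TRUE))
      stop("abundances must be non-negative (column ", rc, ")",
           call. = FALSE)
  }
  df$mz <- as.numeric(df$mz); df$rt <- as.numeric(df$rt)
  df$charge <- as.integer(df$charge)
  structure(df, run_groups = run_groups,
            class = c("quant_features", "data.frame"))
}

#' Link peptide identifications to quantified LC-MS features
#'
#' Drops identifications below `min_score` or without a phosphosite of a
#' requested type, then links each survivor to the quantified feature
#' minimizing the absolute m/z difference (ties broken by absolute RT
#' difference) among features within `mz_tol`, `rt_tol`, and — when
#' `require_charge_match` — of equal charge. For each linked record the
#' control/treatment abundance ratio (`Inf` when the treatment mean is zero)
#' and a one-way ANOVA p-value across condition groups are computed.
#'
#' @param ids A `peptide_ids` table.
#' @param features A `quant_features` table.
#' @param params A [link_params()].
#' @param control,treatment Condition labels used for the ratio numerator and
#'   denominator; default the first and second condition in `run_groups`.
#' @return A `linked_records` data frame: identification fields, linked
#'   feature fields, signed `mz_diff` / `rt_diff`, per-condition mean
#'   abundances, `ratio`, `p_value`, and `linked` flag (unlinked surviving
#'   identifications are reported with NA feature fields).
#' @export
link <- function(ids, features, params = link_params(),
                 control = NULL, treatment = NULL) {
  run_groups <- attr(features, "run_groups")
  if (is.null(run_groups))
    stop("features must carry run_groups (see quant_features())",
         call. = FALSE)
  conds <- unique(unname(run_groups))
  if (is.null(control)) control <- conds[1]
  if (is.null(treatment)) treatment <- conds[2]
  if (!all(c(control, treatment) %in% conds))
    stop("control/treatment labels not found among run conditions",
         call. = FALSE)
  idf <- as.data.frame(ids)
  keep <- idf$score >= params$min_score
  res <- site_residues(idf$phospho_sites)
  keep <- keep & vapply(res, function(r)
    any(r %in% params$phospho_residues), logical(1))
  idf <- idf[keep, , drop = FALSE]
  fdf <- as.data.frame(features)
  ctrl_cols <- names(run_groups)[run_groups == control]
  trt_cols <- names(run_groups)[run_groups == treatment]
  link_one <- function(i) {
    ok <- abs(idf$mz[i] - fdf$mz) <= params$mz_tol &
      abs(idf$rt[i] - fdf$rt) <= params$rt_tol
    if (params$require_charge_match)
      ok <- ok & !is.na(fdf$charge) & !is.na(idf$charge[i]) &
        fdf$charge == idf$charge[i]
    j <- which(ok)
    if (length(j) == 0L) return(integer(0))
    ordd <- j[order(abs(idf$mz[i] - fdf$mz[j]),
                    abs(idf$rt[i] - fdf$rt[j]))]
    if (params$keep_all_matches) ordd else ordd[1L]
  }
  rows <- lapply(seq_len(nrow(idf)), function(i) {
    j <- link_one(i)
    base <- idf[i, , drop = FALSE]
    if (length(j) == 0L) {
      base$feature_id <- NA_character_; base$feature_mz <- NA_real_
      base$feature_rt <- NA_real_; base$feature_charge <- NA_integer_
      base$mz_diff <- NA_real_; base$rt_diff <- NA_real_
      base$mean_control <- NA_real_; base$mean_treatment <- NA_real_
      base$ratio <- NA_real_; base$p_value <- NA_real_
      base$linked <- FALSE
      return(base)
    }
    do.call(rbind, lapply(j, function(jj) {
      r <- base
      r$feature_id <- as.character(fdf$feature_id[jj])
      r$feature_mz <- fdf$mz[jj]; r$feature_rt <- fdf$rt[jj]
      r$feature_charge <- fdf$charge[jj]
      r$mz_diff <- idf$mz[i] - fdf$mz[jj]
      r$rt_diff <- idf$rt[i] - fdf$rt[jj]
      ctrl <- as.numeric(fdf[jj, ctrl_cols])
      trt <- as.numeric(fdf[jj, trt_cols])
      r$mean_control <- mean(ctrl, na.rm = TRUE)
      r$mean_treatment <- mean(trt, na.rm = TRUE)
      r$ratio <- if (isTRUE(r$mean_treatment == 0)) Inf else
        r$mean_control / r$mean_treatment
      r$p_value <- group_anova_p(ctrl, trt)
      r$linked <- TRUE
      r
    }))
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    o <- idf
    for (cc in c("feature_id", "feature_mz", "feature_rt", "feature_charge",
                 "mz_diff", "rt_diff", "mean_control", "mean_treatment",
                 "ratio", "p_value")) o[[cc]] <- numeric(0)
    o$linked <- logical(0)
    o
  }
  rownames(out) <- NULL
  structure(out, control = control, treatment = treatment,
            class = c("linked_records", "data.frame"))
}

# One-way ANOVA p-value across two condition groups; NA when either group
# has fewer than 2 non-missing values or all values are identical.
group_anova_p <- function(ctrl, trt) {
  ctrl <- ctrl[!is.na(ctrl)]; trt <- trt[!is.na(trt)]
  if (length(ctrl) < 2 || length(trt) < 2) return(NA_real_)
  vals <- c(ctrl, trt)
  if (stats::var(vals) == 0) return(1)
  grp <- factor(rep(c("control", "treatment"), c(length(ctrl), length(trt))))
  fit <- stats::aov(vals ~ grp)
  unname(summary(fit)[[1]][["Pr(>F)"]][1])
}

#' Mascot delta score for phosphosite localization
#'
#' The difference between the top two search-engine ion scores among the
#' alternative phosphorylation-site placements of the same peptide sequence;
#' larger values indicate a more confident localization. With a single
#' candidate placement the convention is to return its score unchanged.
#'
#' @param scores Numeric vector of ion scores of the alternative site
#'   placements for one peptide/spectrum.
#' @return Non-negative delta score.
#' @export
md_score <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L)
    stop("md_score requires at least one score", call. = FALSE)
  s <- sort(scores, decreasing = TRUE)
  if (length(s) == 1L) return(s[1])
  s[1] - s[2]
}

#' Mascot delta scores for a whole identification table
#'
#' Groups identification rows by peptide sequence (alternative phosphosite
#' placements of the same sequence) and computes [md_score()] per group.
#'
#' @param ids A `peptide_ids` table (needs `sequence` and `score`).
#' @return Data frame with `sequence`, `n_placements`, `top_score`,
#'   `md_score`.
#' @export
md_score_table <- function(ids) {
  df <- as.data.frame(ids)
  groups <- split(df$score, df$sequence)
  out <- data.frame(sequence = names(groups),
                    n_placements = vapply(groups, length, integer(1)),
                    top_score = vapply(groups, max, numeric(1)),
                    md_score = vapply(groups, md_score, numeric(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize linked records into a differential-expression table
#'
#' Builds the reporting table: accession, sequence with phosphosite markup,
#' m/z, control/treatment ratio, and ANOVA p-value, sorted by ratio
#' descending (infinite ratios first). Rows with `p_value < alpha` are
#' flagged differential; rows without a p-value (insufficient replicates)
#' are retained unflagged.
#'
#' @param linked A `linked_records` table.
#' @param alpha Significance level, default 0.05.
#' @return A data frame of class `differential_table` with columns
#'   `accession`, `sequence`, `phospho_sites`, `mz`, `ratio`, `p_value`,
#'   `differential`.
#' @export
summarize_linked <- function(linked, alpha = 0.05) {
  df <- as.data.frame(linked)
  if (nrow(df) > 0) df <- df[df$linked, , drop = FALSE]
  out <- data.frame(accession = df$accession, sequence = df$sequence,
                    phospho_sites = df$phospho_sites, mz = df$mz,
                    ratio = df$ratio, p_value = df$p_value,
                    stringsAsFactors = FALSE)
  out$differential <- !is.na(out$p_value) & out$p_value < alpha
  out <- out[order(-out$ratio), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, alpha = alpha,
            class = c("differential_table", "data.frame"))
}

#' @export
print.linked_records <- function(x, ...) {
  cat(sprintf("<linked_records> %d identification(s): %d linked, %d unlinked\n",
              nrow(x), sum(x$linked), sum(!x$linked)))
  if (nrow(x) > 0)
    print(utils::head(as.data.frame(x)[, c("sequence", "phospho_sites", "mz",
                                           "feature_id", "ratio",
                                           "p_value", "linked")], 6), ...)
  invisible(x)
}

#' @export
print.differential_table <- function(x, ...) {
  cat(sprintf("<differential_table> %d peptide(s), %d differential at alpha = %g\n",
              nrow(x), sum(x$differential), attr(x, "alpha")))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 10), ...)
  invisible(x)
}
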