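# Canonical data model for LC-MS peaks and readers for the delimited
# peak-list dialects the pipeline consumes (msInspect-style TSV, generic
# CSV/TSV with user-supplied header mapping).

#' Compute the neutral monoisotopic mass of an ion
#'
#' Converts an observed mass-to-charge ratio and charge state to the neutral
#' peptide mass by removing the charging protons:
#' \deqn{M = z \cdot (m/z) - z \cdot m_p}
#' with \eqn{m_p = 1.00728} Da.
#'
#' @param mz Observed m/z in Thomson. Must be positive.
#' @param charge Positive integer charge state.
#' @return Neutral monoisotopic mass in daltons.
#' @examples
#' compute_neutral_mass(812.858, 2) # 1623.701 Da
#' @export
compute_neutral_mass <- function(mz, charge) {
  if (any(charge < 1, na.rm = TRUE))
    stop("charge must be >= 1", call. = FALSE)
  if (any(mz <= 0, na.rm = TRUE))
    stop("mz must be positive", call. = FALSE)
  charge * mz - charge * PROTON_MASS
}

#' Convert a neutral mass back to m/z at a given charge
#'
#' Inverse of [compute_neutral_mass()].
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param charge Positive integer charge state.
#' @return m/z in Thomson.
#' @export
mz_from_mass <- function(mass, charge) {
  if (any(charge < 1, na.rm = TRUE))
    stop("charge must be >= 1", call. = FALSE)
  (mass + charge * PROTON_MASS) / charge
}

#' Describe the columns of a delimited peak-list file
#'
#' Maps canonical peak fields to the column headers of a source file. The
#' default targets the msInspect peptide-feature export
#' (`scan, time, mz, mass, intensity, charge`, tab-delimited, retention time
#' in seconds). Either `mz` or `mass` must be mapped; `rt` and `intensity`
#' are mandatory.
#'
#' @param mz,mass,rt,intensity,charge,scan Column header names in the source
#'   file, or `NA` for fields the file does not carry.
#' @param rt_units `"minutes"` or `"seconds"`; seconds are converted to the
#'   canonical unit (minutes) on read.
#' @param delimiter Field delimiter, default tab.
#' @return An object of class `column_mapping`.
#' @export
column_mapping <- function(mz = "mz", mass = "mass", rt = "time",
                           intensity = "intensity", charge = "charge",
                           scan = "scan", rt_units = c("seconds", "minutes"),
                           delimiter = "\t") {
  rt_units <- match.arg(rt_units)
  m <- list(mz = mz, mass = mass, rt = rt, intensity = intensity,
            charge = charge, scan = scan,
            rt_units = rt_units, delimiter = delimiter)
  if (is.na(m$mz) && is.na(m$mass))
    stop("column_mapping: at least one of 'mz' or 'mass' must be mapped",
         call. = FALSE)
  if (is.na(m$rt) || is.na(m$intensity))
    stop("column_mapping: 'rt' and 'intensity' must be mapped", call. = FALSE)
  structure(m, class = "column_mapping")
}

#' Default mapping for a plain csv dialect (mz, charge, rt in minutes)
#' @rdname column_mapping
#' @export
csv_mapping <- function(mz = "mz", mass = NA, rt = "rt",
                        intensity = "intensity", charge = "charge",
                        scan = NA, rt_units = "minutes", delimiter = ",") {
  column_mapping(mz = mz, mass = mass, rt = rt, intensity = intensity,
                 charge = charge, scan = scan, rt_units = rt_units,
                 delimiter = delimiter)
}

#' Read a column mapping from a YAML config file
#'
#' The file holds keys `mz, mass, rt, intensity, charge, scan, rt_units,
#' delimiter`; omitted keys take the [column_mapping()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A `column_mapping`.
#' @export
read_column_mapping <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- formals(column_mapping)
  keep <- intersect(names(cfg),
                    c("mz", "mass", "rt", "intensity", "charge", "scan",
                      "rt_units", "delimiter"))
  do.call(column_mapping, cfg[keep])
}

new_peaklist <- function(peaks, run_id, condition, replicate, skipped = 0L) {
  structure(peaks,
            run_id = run_id, condition = condition,
            replicate = as.integer(replicate), skipped = as.integer(skipped),
            class = c("peaklist", "data.frame"))
}

peak_columns <- c("run_id", "mz", "charge", "mass", "rt", "intensity", "scan")

empty_peaks <- function() {
  data.frame(run_id = character(), mz = numeric(), charge = integer(),
             mass = numeric(), rt = numeric(), intensity = numeric(),
             scan = integer(), stringsAsFactors = FALSE)
}

#' Construct a peak list from vectors
#'
#' Low-level constructor used by the readers and the synthetic generator.
#' Computes the neutral mass from `mz` and `charge` where `mass` is missing,
#' and validates the peak invariants (positive m/z, non-negative retention
#' time and intensity, charge >= 1 where present, mass consistent with
#' m/z and charge to 0.01 Da).
#'
#' @param mz,rt,intensity Numeric vectors of equal length.
#' @param charge Integer charge states (`NA` allowed).
#' @param mass Neutral masses; computed from `mz`/`charge` where `NA`.
#' @param scan Optional integer scan indices.
#' @param run_id Label of the source LC-MS run.
#' @param condition `"untreated"` or `"ap_treated"`.
#' @param replicate Replicate index 1..6.
#' @return A `peaklist` (data frame with attributes `run_id`, `condition`,
#'   `replicate`, `skipped`).
#' @export
peaklist <- function(mz, rt, intensity, charge = NA_integer_,
                     mass = NA_real_, scan = NA_integer_,
                     run_id = "run1",
                     condition = c("untreated", "ap_treated"),
                     replicate = 1L) {
  condition <- match.arg(condition)
  if (!replicate %in% 1:6)
    stop("replicate index must be within 1..6", call. = FALSE)
  n <- length(mz)
  df <- data.frame(run_id = rep_len(run_id, n),
                   mz = as.numeric(mz),
                   charge = as.integer(rep_len(charge, n)),
                   mass = as.numeric(rep_len(mass, n)),
                   rt = as.numeric(rt),
                   intensity = as.numeric(intensity),
                   scan = as.integer(rep_len(scan, n)),
                   stringsAsFactors = FALSE)
  need_mass <- is.na(df$mass) & !is.na(df$mz) & !is.na(df$charge)
  df$mass[need_mass] <- compute_neutral_mass(df$mz[need_mass],
                                             df$charge[need_mass])
  validate_peaks(df)
  new_peaklist(df, run_id, condition, replicate)
}

validate_peaks <- function(df) {
  ok_charge <- is.na(df$charge) | df$charge >= 1L
  if (!all(ok_charge)) stop("charge must be >= 1 when present", call. = FALSE)
  if (any(df$mz <= 0, na.rm = TRUE)) stop("mz must be positive", call. = FALSE)
  if (any(df$rt < 0, na.rm = TRUE))
    stop("retention time must be non-negative", call. = FALSE)
  if (any(df$intensity < 0, na.rm = TRUE))
    stop("intensity must be non-negative", call. = FALSE)
  both <- !is.na(df$mass) & !is.na(df$mz) & !is.na(df$charge)
  if (any(both)) {
    implied <- compute_neutral_mass(df$mz[both], df$charge[both])
    if (any(abs(df$mass[both] - implied) > 0.01))
      stop("mass inconsistent with mz and charge (> 0.01 Da)", call. = FALSE)
  }
  invisible(df)
}

#' Read a delimited LC-MS peak list
#'
#' Parses one header-plus-rows delimited file into a [peaklist()]. Retention
#' times are converted to minutes when the mapping declares seconds; neutral
#' mass is computed from m/z and charge when only m/z is mapped. Rows whose
#' mandatory fields (m/z or mass, rt, intensity) fail to parse are skipped
#' and counted in the `skipped` attribute.
#'
#' @param path Path to the file.
#' @param mapping A [column_mapping()]; default is the msInspect dialect.
#' @param condition `"untreated"` or `"ap_treated"`.
#' @param replicate Replicate index 1..6.
#' @param run_id Run label; defaults to the file name without extension.
#' @return A `peaklist`.
#' @export
read_peaklist <- function(path, mapping = column_mapping(),
                          condition = c("untreated", "ap_treated"),
                          replicate = 1L, run_id = NULL) {
  condition <- match.arg(condition)
  if (!file.exists(path)) stop("peak-list file not found: ", path,
                               call. = FALSE)
  if (is.null(run_id))
    run_id <- tools::file_path_sans_ext(basename(path))
  raw <- utils::read.table(path, header = TRUE, sep = mapping$delimiter,
                           quote = "\"", comment.char = "",
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           fill = TRUE, blank.lines.skip = TRUE)
  for (fld in c("mz", "mass", "rt", "intensity", "charge", "scan")) {
    col <- mapping[[fld]]
    if (!is.na(col) && !col %in% names(raw))
      stop("mapped column '", col, "' (field '", fld,
           "') missing from header of ", path, call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    warning("empty peak list: ", path, call. = FALSE)
    return(new_peaklist(empty_peaks(), run_id, condition, replicate))
  }
  get_num <- function(fld) {
    col <- mapping[[fld]]
    if (is.na(col)) return(rep(NA_real_, nrow(raw)))
    suppressWarnings(as.numeric(raw[[col]]))
  }
  mz <- get_num("mz"); mass <- get_num("mass"); rt <- get_num("rt")
  intensity <- get_num("intensity"); charge <- get_num("charge")
  scan <- get_num("scan")
  if (mapping$rt_units == "seconds") rt <- rt / 60
  mandatory_ok <- !is.na(rt) & !is.na(intensity) &
    (!is.na(mz) | !is.na(mass))
  skipped <- sum(!mandatory_ok)
  if (skipped > 0L)
    message(skipped, " malformed row(s) skipped in ", basename(path))
  keep <- which(mandatory_ok)
  df <- data.frame(run_id = rep(run_id, length(keep)),
                   mz = mz[keep], charge = as.integer(charge[keep]),
                   mass = mass[keep], rt = rt[keep],
                   intensity = intensity[keep],
                   scan = as.integer(scan[keep]),
                   stringsAsFactors = FALSE)
  need_mass <- is.na(df$mass) & !is.na(df$charge)
  df$mass[need_mass] <- compute_neutral_mass(df$mz[need_mass],
                                             df$charge[need_mass])
  need_mz <- is.na(df$mz) & !is.na(df$charge)
  df$mz[need_mz] <- mz_from_mass(df$mass[need_mz], df$charge[need_mz])
  validate_peaks(df)
  new_peaklist(df, run_id, condition, replicate, skipped)
}

#' Write a peak list in the plain csv dialect
#'
#' @param x A `peaklist`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("mz", "charge", "mass", "rt",
                                        "intensity", "scan")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Batch-load a directory of peak-list files
#'
#' Directory-walking loader honouring the batch contract of a peak-extraction
#' front end: every file matching `pattern` is read with `mapping`, and
#' condition/replicate are inferred from the file name via `name_pattern`, a
#' regular expression with two capture groups — (1) the condition token and
#' (2) the replicate number. Files whose condition token matches
#' `treated_token` are labelled `ap_treated`, all others `untreated`.
#'
#' @param dir Directory to scan.
#' @param pattern Filename glob converted with [utils::glob2rx()],
#'   default `"*.tsv"`.
#' @param mapping A [column_mapping()].
#' @param name_pattern Regex with capture groups for condition and replicate,
#'   default `"^(ctrl|ap)_rep(\\d+)"`.
#' @param treated_token Condition token marking AP-treated runs.
#' @return A list of `peaklist` objects, one per file.
#' @export
read_peaklist_dir <- function(dir, pattern = "*.tsv",
                              mapping = column_mapping(),
                              name_pattern = "^(ctrl|ap)_rep(\\d+)",
                              treated_token = "ap") {
  files <- list.files(dir, pattern = utils::glob2rx(pattern),
                      full.names = TRUE)
  if (length(files) == 0L)
    stop("no peak-list files matching '", pattern, "' in ", dir,
         call. = FALSE)
  lapply(files, function(f) {
    base <- basename(f)
    m <- regmatches(base, regexec(name_pattern, base))[[1]]
    if (length(m) < 3L)
      stop("cannot infer condition/replicate from file name: ", base,
           call. = FALSE)
    cond <- if (identical(m[2], treated_token)) "ap_treated" else "untreated"
    read_peaklist(f, mapping, condition = cond,
                  replicate = as.integer(m[3]))
  })
}

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("<peaklist> run '%s' (%s, replicate %d): %d peaks",
              attr(x, "run_id"), attr(x, "condition"),
              attr(x, "replicate"), nrow(x)))
  if (attr(x, "skipped") > 0)
    cat(sprintf(" [%d rows skipped]", attr(x, "skipped")))
  cat("\n")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 6), ...)
  invisible(x)
}

#' @export
summary.peaklist <- function(object, ...) {
  cat(sprintf("Peak list '%s' (%s, replicate %d)\n", attr(object, "run_id"),
              attr(object, "condition"), attr(object, "replicate")))
  cat(sprintf("  %d peaks; m/z %.4f-%.4f; rt %.2f-%.2f min\n",
              nrow(object), suppressWarnings(min(object$mz)),
              suppressWarnings(max(object$mz)),
              suppressWarnings(min(object$rt)),
              suppressWarnings(max(object$rt))))
  ch <- table(object$charge, useNA = "ifany")
  cat("  charge states: ",
      paste(names(ch), ch, sep = "=", collapse = ", "), "\n")
  invisible(object)
}
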