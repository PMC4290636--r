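# Independent brute-force oracles: plain double/triple loops over every
# (untreated, treated, n) triple and every (id, feature) pair, written
# without reference to the package's search structures.

oracle_mine <- function(u, t_, params) {
  u <- as.data.frame(u); t_ <- as.data.frame(t_)
  rows <- list()
  for (i in seq_len(nrow(u))) {
    for (n in seq_len(params$max_mods)) {
      merr <- (u$mass[i] - t_$mass) - n * params$delta_mass
      rdiff <- u$rt[i] - t_$rt
      ok <- !is.na(merr) & abs(merr) <= params$mass_tol &
        abs(rdiff) <= params$rt_tol
      if (isTRUE(params$same_charge))
        ok <- ok & !is.na(u$charge[i]) & !is.na(t_$charge) &
          u$charge[i] == t_$charge
      j <- which(ok)
      if (length(j) == 0L) next
      best <- j[order(abs(merr[j]), abs(rdiff[j]))[1L]]
      rows[[length(rows) + 1L]] <- data.frame(
        u_idx = i, t_idx = best, n_mods = n,
        mass_error = merr[best], rt_diff = rdiff[best])
    }
  }
  if (length(rows) == 0L)
    return(data.frame(u_idx = integer(), t_idx = integer(),
                      n_mods = integer(), mass_error = numeric(),
                      rt_diff = numeric()))
  do.call(rbind, rows)
}

oracle_link_assignment <- function(ids, feats, params) {
  ids <- as.data.frame(ids); feats <- as.data.frame(feats)
  vapply(seq_len(nrow(ids)), function(i) {
    best <- NA_integer_; best_mz <- Inf; best_rt <- Inf
    for (j in seq_len(nrow(feats))) {
      dmz <- abs(ids$mz[i] - feats$mz[j])
      drt <- abs(ids$rt[i] - feats$rt[j])
      if (dmz > params$mz_tol || drt > params$rt_tol) next
      if (params$require_charge_match &&
          (is.na(ids$charge[i]) || is.na(feats$charge[j]) ||
           ids$charge[i] != feats$charge[j])) next
      if (dmz < best_mz || (dmz == best_mz && drt < best_rt)) {
        best <- j; best_mz <- dmz; best_rt <- drt
      }
    }
    best
  }, integer(1))
}

# Random peak list on a mass grid dense enough that shift matches occur.
random_peaklist <- function(n, condition = "untreated", replicate = 1L) {
  mass <- runif(n, 900, 1100) +
    sample(0:5, n, replace = TRUE) * PHOSPHO_MASS +
    rnorm(n, 0, 0.03)
  charge <- sample(2:3, n, replace = TRUE)
  peaklist(mz = mz_from_mass(mass, charge),
           rt = runif(n, 10, 30), intensity = rlnorm(n, 12, 1),
           charge = charge, mass = mass,
           run_id = sprintf("%s_rep%d", condition, replicate),
           condition = condition, replicate = replicate)
}

random_ids <- function(n) {
  aas <- strsplit("ACDEFGHIKLMNPQRVW", "")[[1]] # no S/T/Y background
  seqs <- character(n); mods <- character(n)
  for (i in seq_len(n)) {
    len <- sample(8:14, 1)
    chars <- sample(aas, len, replace = TRUE)
    pos <- sample(len, 1)
    res <- sample(c("S", "T", "Y"), 1)
    chars[pos] <- res
    seqs[i] <- paste(chars, collapse = "")
    mods[i] <- paste0("p", res, pos)
  }
  annotate_peptide_ids(data.frame(
    sequence = seqs, mod_string = mods,
    mz = runif(n, 400, 1200), charge = sample(2:3, n, replace = TRUE),
    rt = runif(n, 10, 60), score = runif(n, 10, 60),
    accession = sprintf("ACC%04d", seq_len(n)),
    stringsAsFactors = FALSE))
}

random_features <- function(n, run_groups = c(c1 = "control", c2 = "control",
                                              t1 = "treatment",
                                              t2 = "treatment")) {
  df <- data.frame(feature_id = sprintf("F%04d", seq_len(n)),
                   mz = runif(n, 400, 1200),
                   charge = sample(2:3, n, replace = TRUE),
                   rt = runif(n, 10, 60), stringsAsFactors = FALSE)
  for (rc in names(run_groups)) df[[rc]] <- rlnorm(n, 10, 0.5)
  quant_features(df, run_groups)
}
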