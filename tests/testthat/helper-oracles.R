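# Independent oracles: deliberately naive implementations used only to
# check the package's estimators. They share no code with R/.

# One-way single-measure ICC by explicit double loops over a balanced
# participants x replicates matrix (rows = participants).
brute_force_icc1 <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  grand <- mean(mat)
  ssb <- 0
  for (i in seq_len(n)) {
    ssb <- ssb + k * (mean(mat[i, ]) - grand)^2
  }
  msbs <- ssb / (n - 1)
  ssw <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      ssw <- ssw + (mat[i, j] - mean(mat[i, ]))^2
    }
  }
  msws <- ssw / (n * (k - 1))
  (msbs - msws) / (msbs + (k - 1) * msws)
}

brute_force_msq <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  ssb <- 0
  for (i in seq_len(n)) ssb <- ssb + k * (mean(mat[i, ]) - grand)^2
  ssw <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    ssw <- ssw + (mat[i, j] - mean(mat[i, ]))^2
  }
  list(msbs = ssb / (n - 1), msws = ssw / (n * (k - 1)))
}

# Third-party ICC(1) oracle: pingouin's intraclass_corr, batched through a
# single python call. `tables` is a list of numeric matrices
# (participants x replicates). Returns the ICC1 value per table.
pingouin_icc1 <- function(tables) {
  long <- do.call(rbind, lapply(seq_along(tables), function(ti) {
    m <- tables[[ti]]
    data.frame(
      table = ti,
      target = rep(seq_len(nrow(m)), times = ncol(m)),
      rater = rep(seq_len(ncol(m)), each = nrow(m)),
      rating = as.vector(m))
  }))
  infile <- tempfile(fileext = ".csv")
  outfile <- tempfile(fileext = ".csv")
  utils::write.csv(long, infile, row.names = FALSE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, pandas as pd, pingouin as pg",
    "df = pd.read_csv(sys.argv[1])",
    "rows = []",
    "for ti, g in df.groupby('table'):",
    "    res = pg.intraclass_corr(data=g, targets='target', raters='rater', ratings='rating')",
    "    icc1 = res.loc[res['Type'].isin(['ICC1', 'ICC(1,1)']), 'ICC'].iloc[0]",
    "    rows.append({'table': ti, 'icc1': icc1})",
    "pd.DataFrame(rows).to_csv(sys.argv[2], index=False)"
  ), script)
  status <- system2("python", c(script, infile, outfile),
    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("pingouin oracle call failed")
  out <- utils::read.csv(outfile)
  out$icc1[order(out$table)]
}

# Brute-force sleep-run scanner: O(n^2)-style explicit loop over sorted
# timestamps; returns the chosen interval per study day.
brute_force_sleep_runs <- function(ts, max_gap = 15 * 60,
                                   min_duration = 2 * 3600, tz = "UTC") {
  ts <- sort(unique(ts))
  runs <- list()
  start <- 1
  for (i in seq_along(ts)) {
    if (i == length(ts) ||
        as.numeric(difftime(ts[i + 1], ts[i], units = "secs")) > max_gap) {
      runs[[length(runs) + 1]] <- list(start = ts[start], end = ts[i],
        n = i - start + 1)
      start <- i + 1
    }
  }
  qual <- Filter(function(r) {
    as.numeric(difftime(r$end, r$start, units = "secs")) >= min_duration
  }, runs)
  if (length(qual) == 0) {
    return(data.frame(study_day = as.Date(character()),
      start = as.POSIXct(character(), tz = "UTC"),
      end = as.POSIXct(character(), tz = "UTC"), n_samples = integer()))
  }
  df <- do.call(rbind, lapply(qual, function(r) {
    data.frame(
      study_day = as.Date(lubridate::with_tz(r$start, tz) -
        lubridate::dhours(12), tz = tz),
      start = r$start, end = r$end, n_samples = r$n,
      span = as.numeric(difftime(r$end, r$start, units = "secs")))
  }))
  best <- do.call(rbind, lapply(split(df, df$study_day), function(d) {
    d <- d[order(-d$span, d$start), ]
    d[1, ]
  }))
  best <- best[order(best$study_day), ]
  rownames(best) <- NULL
  best[c("study_day", "start", "end", "n_samples")]
}
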