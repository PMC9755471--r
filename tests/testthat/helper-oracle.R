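# Independent brute-force oracle: materialises the full boolean
# cross-recurrence matrix and enumerates runs and blocks directly. Used to
# verify the production implementations, which never build the matrix.

naive_recurrence_matrix <- function(p_sym, a_sym) {
  outer(p_sym, a_sym, `==`)   # M[i, j] <=> participant i matches assistant j
}

# Recurrence rate along diagonal k: cells (j + k, j).
naive_lag_profile <- function(p_sym, a_sym, max_lag_frames) {
  M <- naive_recurrence_matrix(p_sym, a_sym)
  n <- length(p_sym)
  ks <- (-max_lag_frames):max_lag_frames
  rr <- sapply(ks, function(k) {
    js <- which(seq_len(n) + k >= 1 & seq_len(n) + k <= n)
    mean(M[cbind(js + k, js)])
  })
  list(lags_frames = ks, rr = rr)
}

true_run_lengths <- function(v) {
  r <- rle(v)
  r$lengths[r$values]
}

naive_crqa_measures <- function(p_sym, a_sym, lmin = 2, include_main = TRUE,
                                min_area = 1) {
  M <- naive_recurrence_matrix(p_sym, a_sym)
  n <- length(p_sym)
  diag_lens <- unlist(lapply((-(n - 1)):(n - 1), function(k) {
    if (!include_main && k == 0) return(NULL)
    js <- which(seq_len(n) + k >= 1 & seq_len(n) + k <= n)
    true_run_lengths(M[cbind(js + k, js)])
  }))
  vert_lens <- unlist(lapply(seq_len(n), function(j) true_run_lengths(M[, j])))
  horiz_lens <- unlist(lapply(seq_len(n), function(i) true_run_lengths(M[i, ])))
  keep <- function(x) x[x >= lmin]
  avg0 <- function(x) if (length(x)) mean(x) else 0

  rp <- rle(p_sym); ra <- rle(a_sym)
  areas <- c()
  for (i in seq_along(rp$values)) {
    for (j in seq_along(ra$values)) {
      if (rp$values[i] == ra$values[j]) {
        areas <- c(areas, rp$lengths[i] * ra$lengths[j])
      }
    }
  }
  areas <- areas[areas >= min_area]
  ent <- if (length(areas) == 0) 0 else {
    q <- as.numeric(table(areas)) / length(areas)
    -sum(q * log(q))
  }
  list(rr = sum(M) / n^2,
       mean_line = avg0(keep(diag_lens)),
       tt_v = avg0(keep(vert_lens)),
       tt_h = avg0(keep(horiz_lens)),
       cat_ent = ent)
}

rand_series <- function(n, fps = 30, person_id = "p") {
  categorical_series(sample(c("LEFT", "RIGHT", "NONE"), n, replace = TRUE),
                     fps = fps, person_id = person_id)
}

series_of <- function(sym, fps = 30) categorical_series(sym, fps = fps)

# Compact constructor for single-bodypart tracks in tests.
track_of <- function(x, y = rep(0, length(x)), bodypart = "nose", fps = 30,
                     person_id = "p") {
  pose_track(matrix(x, ncol = 1), matrix(y, ncol = 1), bodyparts = bodypart,
             fps = fps, person_id = person_id)
}
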