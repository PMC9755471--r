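#' @keywords internal
"_PACKAGE"

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Integer-encode the symbols of two series, checking they are comparable.
encode_pair <- function(p, a) {
  stopifnot(inherits(p, "categorical_series"), inherits(a, "categorical_series"))
  if (length(p$symbols) != length(a$symbols)) {
    stop("series length mismatch: ", length(p$symbols), " vs ", length(a$symbols))
  }
  if (p$fps != a$fps) stop("series fps mismatch")
  list(p = as.integer(p$symbols), a = as.integer(a$symbols),
       n = length(p$symbols), fps = p$fps)
}

#' Diagonal lag profile of a categorical cross-recurrence plot
#'
#' Computes the recurrence rate along each diagonal of the cross-recurrence
#' plot between two equal-length categorical series, for signed lags from
#' `-max_lag` to `+max_lag` seconds at frame resolution. With the
#' participant's series as `p` and the (already mirrored) assistant's series
#' as `a`, the rate at lag `k` frames is the fraction of valid frames `t`
#' with `p[t + k] == a[t]`, normalised by the `n - |k|` comparisons actually
#' available on that diagonal. Consequently, if the assistant copies the
#' participant `d` frames later, the profile peaks at lag `-d`: mass at
#' negative lags means the participant leads, mass at positive lags means
#' the assistant leads.
#'
#' @param p participant [categorical_series()].
#' @param a assistant [categorical_series()], mirrored upstream when the
#'   camera geometry requires it (see [mirror_series()]).
#' @param max_lag half-width of the lag window in seconds (default 3).
#' @return An object of class `lag_profile` with fields `lags_s` (seconds),
#'   `lags_frames`, `rr` (raw rates in `[0, 1]`), `fps`, `normalized`.
#' @export
lag_profile <- function(p, a, max_lag = 3) {
  e <- encode_pair(p, a)
  L <- as.integer(round(max_lag * e$fps))
  if (L < 0L) stop("`max_lag` must be non-negative")
  if (L >= e$n) {
    stop("`max_lag` of ", max_lag, " s (", L, " frames) must be below the series length (",
         e$n, " frames)")
  }
  ks <- (-L):L
  rr <- vapply(ks, function(k) {
    if (k >= 0) mean(e$p[(1L + k):e$n] == e$a[1L:(e$n - k)])
    else mean(e$p[1L:(e$n + k)] == e$a[(1L - k):e$n])
  }, numeric(1))
  structure(list(lags_frames = ks, lags_s = ks / e$fps, rr = rr,
                 fps = e$fps, n = e$n, normalized = FALSE),
            class = "lag_profile")
}

#' @export
print.lag_profile <- function(x, ...) {
  i <- which.max(x$rr)
  cat("<lag_profile> lags ", min(x$lags_s), "..", max(x$lags_s), " s (",
      length(x$rr), " bins), max rr ", signif(x$rr[i], 4), " at ",
      x$lags_s[i], " s", if (x$normalized) " [min-max normalized]", "\n",
      sep = "")
  invisible(x)
}

#' Min-max normalise a lag profile for display
#'
#' Rescales the rates to `[0, 1]`. Intended only for plotting profiles on a
#' common scale; all statistics in this package operate on raw rates, since
#' min-max scaling would distort between-group rate comparisons.
#'
#' @param profile a [lag_profile()].
#' @return The profile with `rr` rescaled and `normalized = TRUE`.
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "lag_profile"))
  rng <- range(profile$rr)
  profile$rr <- if (diff(rng) == 0) rep(0, length(profile$rr)) else
    (profile$rr - rng[1]) / diff(rng)
  profile$normalized <- TRUE
  profile
}

#' Shuffled-surrogate baseline for a lag profile
#'
#' Estimates the chance level of the diagonal lag profile by recomputing it
#' against random permutations of the assistant's symbol series. Permutation
#' destroys temporal coupling while preserving the symbol frequencies, so a
#' genuine coordination peak in the original profile should exceed the
#' surrogate band.
#'
#' @inheritParams lag_profile
#' @param n_shuffles number of independent permutations (default 100).
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return An object of class `surrogate_profile` with per-lag `mean_rr` and
#'   `sd_rr` over the shuffles.
#' @export
shuffle_baseline <- function(p, a, max_lag = 3, n_shuffles = 100, seed = NULL) {
  e <- encode_pair(p, a)
  n_shuffles <- as.integer(n_shuffles)
  if (is.na(n_shuffles) || n_shuffles < 1L) stop("`n_shuffles` must be at least 1")
  with_seed(seed, {
    rrs <- vapply(seq_len(n_shuffles), function(i) {
      a_perm <- a
      a_perm$symbols <- a$symbols[sample.int(e$n)]
      lag_profile(p, a_perm, max_lag = max_lag)$rr
    }, numeric(2L * as.integer(round(max_lag * e$fps)) + 1L))
  })
  ks <- (-as.integer(round(max_lag * e$fps))):(as.integer(round(max_lag * e$fps)))
  structure(list(lags_frames = ks, lags_s = ks / e$fps,
                 mean_rr = rowMeans(rrs),
                 sd_rr = if (n_shuffles > 1L) apply(rrs, 1L, stats::sd)
                         else rep(0, nrow(rrs)),
                 n_shuffles = n_shuffles, seed = seed, fps = e$fps, n = e$n),
            class = "surrogate_profile")
}

#' @export
print.surrogate_profile <- function(x, ...) {
  cat("<surrogate_profile> ", x$n_shuffles, " shuffles, mean rr ",
      signif(mean(x$mean_rr), 4), "\n", sep = "")
  invisible(x)
}

# Run-length encode an integer symbol vector.
sym_rle <- function(v) {
  r <- rle(v)
  list(values = r$values, lengths = r$lengths)
}

#' Cross-recurrence measures for a categorical dyad
#'
#' Quantifies the structure of the cross-recurrence plot between two
#' equal-length categorical series (a cell `(i, j)` is recurrent when
#' `p[i] == a[j]`):
#'
#' * `rr` — recurrence rate, recurrent cells / n^2: overall coupling.
#' * `mean_line` — mean length (frames) of maximal diagonal recurrent runs of
#'   length at least `lmin`, over all diagonals (line of synchrony included
#'   by default): the mean duration of matched movement episodes.
#' * `tt_v`, `tt_h` — trapping times: mean length of maximal vertical
#'   (respectively horizontal) recurrent runs of length at least `lmin`: how
#'   long one partner dwells in a state the other also expresses.
#' * `cat_ent` — categorical entropy, see [cat_entropy()].
#'
#' When a line set is empty the corresponding measure is reported as 0 with
#' `lines_defined = FALSE`, so batch pipelines do not abort on degenerate
#' dyads.
#'
#' @inheritParams lag_profile
#' @param lmin minimum run length counted as a line (default 2).
#' @param include_main include the main diagonal in the diagonal-line
#'   statistics (default `TRUE`; cross recurrence between distinct systems
#'   has no trivial self-matching diagonal).
#' @param min_area minimum block area counted by [cat_entropy()].
#' @return An object of class `crqa_measures`.
#' @export
crqa_measures <- function(p, a, lmin = 2L, include_main = TRUE, min_area = 1L) {
  e <- encode_pair(p, a)
  lmin <- as.integer(lmin)
  if (is.na(lmin) || lmin < 1L) stop("`lmin` must be a positive integer")
  n <- e$n
  counts_p <- tabulate(e$p, nbins = 3L)
  counts_a <- tabulate(e$a, nbins = 3L)
  rr <- sum(as.numeric(counts_p) * counts_a) / as.numeric(n)^2

  # Diagonal lines: scan every diagonal of the implicit recurrence matrix.
  d_sum <- 0; d_cnt <- 0L
  for (k in (-(n - 1L)):(n - 1L)) {
    if (!include_main && k == 0L) next
    m <- if (k >= 0) e$p[(1L + k):n] == e$a[1L:(n - k)] else
      e$p[1L:(n + k)] == e$a[(1L - k):n]
    r <- rle(m)
    len <- r$lengths[r$values & r$lengths >= lmin]
    d_sum <- d_sum + sum(len)
    d_cnt <- d_cnt + length(len)
  }

  # Vertical lines: in the column where the assistant shows symbol c, the
  # vertical recurrent runs are exactly the maximal runs of c in p; so each
  # run of c in p is counted once per occurrence of c in a. Horizontal lines
  # are the transpose.
  tt_of <- function(runs_src, counts_other) {
    s <- 0; cnt <- 0
    for (c in 1:3) {
      len <- runs_src$lengths[runs_src$values == c & runs_src$lengths >= lmin]
      s <- s + counts_other[c] * sum(len)
      cnt <- cnt + counts_other[c] * length(len)
    }
    list(sum = s, count = cnt)
  }
  rp <- sym_rle(e$p); ra <- sym_rle(e$a)
  v <- tt_of(rp, counts_a)   # vertical runs live in p, one per matching column
  h <- tt_of(ra, counts_p)

  structure(list(
    rr = rr,
    mean_line = if (d_cnt > 0L) d_sum / d_cnt else 0,
    tt_v = if (v$count > 0) v$sum / v$count else 0,
    tt_h = if (h$count > 0) h$sum / h$count else 0,
    cat_ent = cat_entropy(p, a, min_area = min_area),
    lines_defined = list(mean_line = d_cnt > 0L, tt_v = v$count > 0,
                         tt_h = h$count > 0),
    lmin = lmin, include_main = include_main, n = n
  ), class = "crqa_measures")
}

#' @export
print.crqa_measures <- function(x, ...) {
  cat("<crqa_measures> rr=", signif(x$rr, 4),
      " mean_line=", signif(x$mean_line, 4),
      " tt_v=", signif(x$tt_v, 4), " tt_h=", signif(x$tt_h, 4),
      " cat_ent=", signif(x$cat_ent, 4),
      if (!all(unlist(x$lines_defined))) " [some line measures undefined]",
      "\n", sep = "")
  invisible(x)
}

#' Categorical entropy of recurrence-block areas
#'
#' In a categorical cross-recurrence plot the recurrent cells form
#' rectangular blocks: each maximal run of a symbol in one series crossed
#' with each maximal run of the same symbol in the other. The block area is
#' the product of the two run lengths. `cat_entropy()` returns the Shannon
#' entropy (natural log) of the relative-frequency distribution of those
#' areas. Higher values indicate more variable durations of the coordinated
#' episodes; low values indicate repetitive, rigid coordination.
#'
#' @inheritParams lag_profile
#' @param min_area smallest block area included (default 1, i.e. all blocks;
#'   raise to focus on extended coordination patterns).
#' @return Entropy in nats (0 when at most one distinct area occurs).
#' @export
cat_entropy <- function(p, a, min_area = 1L) {
  e <- encode_pair(p, a)
  rp <- sym_rle(e$p); ra <- sym_rle(e$a)
  areas <- NULL
  for (c in 1:3) {
    lp <- rp$lengths[rp$values == c]
    la <- ra$lengths[ra$values == c]
    if (length(lp) && length(la)) {
      areas <- c(areas, as.vector(outer(lp, la)))
    }
  }
  areas <- areas[areas >= min_area]
  if (length(areas) == 0L) return(0)
  q <- tabulate(areas)
  q <- q[q > 0] / length(areas)
  -sum(q * log(q))
}
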