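#' Default rule weights
#'
#' Importance weights for the five rules, constrained to sum to 100. The
#' shipped defaults (30, 25, 15, 15, 15) order the rules by their role in
#' the detection model — the conductance rise and the delayed temperature
#' decrease are the primary indications — and are artifact defaults: study-
#' specific weights should come from [calibrate_weights()] against
#' ground-truthed sessions.
#'
#' @return named numeric vector `c(r1, r2, r3, r4, r5)` summing to 100.
#' @export
default_rule_weights <- function() {
  c(r1 = 30, r2 = 25, r3 = 15, r4 = 15, r5 = 15)
}

#' Validate a rule-weight vector
#'
#' @param weights numeric vector of five non-negative weights that must sum
#'   to exactly 100.
#' @return the weights, invisibly, named `r1..r5`.
#' @export
validate_weights <- function(weights) {
  if (length(weights) != 5)
    stop("configuration error: exactly five rule weights are required",
         call. = FALSE)
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("configuration error: weights must be finite and non-negative",
         call. = FALSE)
  if (abs(sum(weights) - 100) > 1e-9)
    stop("configuration error: rule weights must sum to 100 (got ",
         format(sum(weights)), ")", call. = FALSE)
  names(weights) <- paste0("r", 1:5)
  invisible(weights)
}

#' Find candidate skin-conductance rises in a 1 Hz series
#'
#' A candidate is a maximal run of strictly positive first differences:
#' its onset is the local minimum at the run start, its peak the local
#' maximum at the run end, and `rise_run` the run length in seconds.
#'
#' @param g numeric 1 Hz conductance series (normally the phasic component).
#' @return data frame with columns `onset_idx`, `peak_idx` (1-based
#'   positions), `onset_t`, `peak_t` (seconds from series start),
#'   `rise_run`, `g_onset`, `g_peak`. Empty on monotone non-increasing
#'   input.
#' @examples
#' find_candidates(c(1, 2, 3, 4, 3))
#' @export
find_candidates <- function(g) {
  g <- as.numeric(g)
  empty <- data.frame(onset_idx = integer(0), peak_idx = integer(0),
                      onset_t = numeric(0), peak_t = numeric(0),
                      rise_run = integer(0), g_onset = numeric(0),
                      g_peak = numeric(0))
  if (length(g) < 3) return(empty)
  pos <- diff(g) > 0
  if (!any(pos)) return(empty)
  runs <- rle(pos)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  onset <- starts[keep]           # index into diff() = index of run start sample
  peak <- ends[keep] + 1L
  data.frame(onset_idx = onset, peak_idx = peak,
             onset_t = onset - 1, peak_t = peak - 1,
             rise_run = peak - onset,
             g_onset = g[onset], g_peak = g[peak])
}

#' Rule 1 — GSR amplitude increase
#'
#' Full score for a conductance rise of 2 to 5 consecutive seconds, the
#' typical span of a stimulus-driven response; half score for a slower rise
#' of up to 8 s (a longer rise indicates a less intense stimulus); zero
#' otherwise.
#'
#' @param rise_run length of the positive-derivative run in seconds.
#' @return 0, 0.5 or 1.
#' @export
score_r1 <- function(rise_run) {
  ifelse(rise_run >= 2 & rise_run <= 5, 1,
         ifelse(rise_run > 5 & rise_run <= 8, 0.5, 0))
}

#' Rule 2 — skin-temperature decrease
#'
#' Full score when the temperature derivative is negative for at least
#' three consecutive seconds starting exactly 3 s after the conductance
#' rise onset; half score when such a decrease starts anywhere from 2 to
#' 6 s after the onset; zero otherwise. Insufficient temperature coverage
#' scores 0 with a warning.
#'
#' @param st numeric 1 Hz temperature series (normally band-passed).
#' @param onset_idx 1-based index of the candidate onset second in `st`.
#' @param min_run minimum decrease duration in seconds (default 3).
#' @return 0, 0.5 or 1.
#' @export
score_r2 <- function(st, onset_idx, min_run = 3) {
  d <- diff(as.numeric(st))
  neg_run_from <- function(o) {
    ix <- onset_idx + o + seq_len(min_run) - 1L
    if (max(ix) > length(d)) return(NA)
    all(d[ix] < 0)
  }
  full <- neg_run_from(3L)
  if (is.na(full)) {
    warning("insufficient ST coverage after candidate onset; rule 2 scores 0",
            call. = FALSE)
    return(0)
  }
  if (full) return(1)
  for (o in c(2L, 4L, 5L, 6L)) {
    r <- neg_run_from(o)
    if (isTRUE(r)) return(0.5)
  }
  0
}

#' Rule 3 — rising time
#'
#' Full score when the onset-to-peak time is within the 1--5 s range typical
#' of stimulus-driven responses; half score up to 15 s; zero beyond.
#'
#' @param rise_time `peak_t - onset_t` in seconds.
#' @return 0, 0.5 or 1.
#' @export
score_r3 <- function(rise_time) {
  ifelse(rise_time >= 1 & rise_time <= 5, 1,
         ifelse(rise_time > 5 & rise_time <= 15, 0.5, 0))
}

#' Rule 4 — response slope
#'
#' The slope is `atan(delta_g / delta_t)` expressed in degrees, with
#' conductance in microsiemens and time in seconds (the threshold is
#' unit-dependent: it reads the slope off axes scaled in uS and s).
#' Steeper responses indicate more intense events: full score at >= 10
#' degrees, half score from 8 degrees, zero below.
#'
#' @param delta_g conductance rise `g_peak - g_onset`, microsiemens.
#' @param delta_t rise duration in seconds, > 0.
#' @return 0, 0.5 or 1.
#' @export
score_r4 <- function(delta_g, delta_t) {
  slope_deg <- atan(delta_g / delta_t) * 180 / pi
  ifelse(slope_deg >= 10, 1, ifelse(slope_deg >= 8, 0.5, 0))
}

#' Rule 5 — refractory duration
#'
#' A stress event spans roughly 10 s (mean latency + rise + half-recovery),
#' so a new moment of stress cannot follow an accepted one within 10 s:
#' score 1 when the candidate is more than 10 s after the last accepted
#' event (or there is none), 0 otherwise. This rule has no partial score.
#'
#' @param t candidate time in seconds.
#' @param previous_mos numeric vector of already accepted event times.
#' @return 0 or 1.
#' @export
score_r5 <- function(t, previous_mos) {
  if (length(previous_mos) == 0) return(1)
  if (t - max(previous_mos) > 10) 1 else 0
}

#' Weighted total score
#'
#' Each ternary rule score is multiplied by its importance weight and the
#' products are summed; with weights constrained to total 100 the score
#' ranges over \[0, 100\] and reaches 100 only when every rule is fully
#' satisfied.
#'
#' @param scores numeric vector of five rule scores, each in {0, 0.5, 1}.
#' @param weights five non-negative weights summing to 100.
#' @return total score in \[0, 100\].
#' @examples
#' total_score(c(1, 1, 1, 0.5, 1), c(30, 25, 15, 15, 15))
#' @export
total_score <- function(scores, weights = default_rule_weights()) {
  weights <- validate_weights(weights)
  if (length(scores) != 5 || !all(scores %in% c(0, 0.5, 1)))
    stop("scores must be five values in {0, 0.5, 1}", call. = FALSE)
  sum(scores * weights)
}

#' Detect moments of stress in a bio-geodatabase
#'
#' Scans conductance-rise candidates in time order; for each, rules 1--4 are
#' computed from the signals and rule 5 from the already accepted events,
#' the weighted total score is formed, and the candidate is accepted as a
#' moment of stress when the total reaches the critical score. The duration
#' rule is both scored and a feasibility constraint: a stress event spans
#' about 10 s, so a candidate inside the 10 s refractory window of the last
#' accepted event is never emitted, whatever its total score. Emitted event
#' sequences therefore always have consecutive gaps above 10 s. The event is
#' stamped at the candidate onset second and inherits that row's location.
#'
#' @param table a `biogeo_table` from [preprocess_session()] /
#'   [build_biogeo()].
#' @param weights five rule weights summing to 100.
#' @param cs critical score in \[0, 100\] (default 75).
#' @param gsr_source `"phasic"` (default) or `"filtered"`: which conductance
#'   component the rise rules scan.
#' @param st_source which temperature channel feeds the decrease rule:
#'   `"smooth"` (default, noise-filtered low-pass), `"band"` (band-passed)
#'   or `"raw"` (window-mean of the raw trace).
#' @return a `mos_events` data frame with columns `t`, `ts` (total score),
#'   `sc1`..`sc5`, `lat`, `lon`.
#' @export
detect_mos <- function(table, weights = default_rule_weights(), cs = 75,
                       gsr_source = c("phasic", "filtered"),
                       st_source = c("smooth", "band", "raw")) {
  weights <- validate_weights(weights)
  if (!is.numeric(cs) || cs < 0 || cs > 100)
    stop("configuration error: 'cs' must lie in [0, 100]", call. = FALSE)
  gsr_source <- match.arg(gsr_source)
  st_source <- match.arg(st_source)
  empty <- structure(
    data.frame(t = numeric(0), ts = numeric(0), sc1 = numeric(0),
               sc2 = numeric(0), sc3 = numeric(0), sc4 = numeric(0),
               sc5 = numeric(0), lat = numeric(0), lon = numeric(0)),
    class = c("mos_events", "data.frame"))
  if (is.null(table) || nrow(table) == 0) return(empty)
  g <- if (gsr_source == "phasic") table$phasic else table$g
  stv <- switch(st_source,
                smooth = if (!is.null(table$st_smooth)) table$st_smooth else table$st,
                band = table$st_band,
                raw = table$st)
  cands <- find_candidates(g)
  if (nrow(cands) == 0) return(empty)
  accepted <- numeric(0)
  rows <- vector("list", nrow(cands))
  for (i in seq_len(nrow(cands))) {
    cd <- cands[i, ]
    t_abs <- table$t[cd$onset_idx]
    sc <- c(score_r1(cd$rise_run),
            score_r2(stv, cd$onset_idx),
            score_r3(cd$peak_t - cd$onset_t),
            score_r4(cd$g_peak - cd$g_onset, cd$peak_t - cd$onset_t),
            score_r5(t_abs, accepted))
    ts <- sum(sc * weights)
    if (ts >= cs && sc[5] == 1) {
      accepted <- c(accepted, t_abs)
      rows[[i]] <- data.frame(t = t_abs, ts = ts, sc1 = sc[1], sc2 = sc[2],
                              sc3 = sc[3], sc4 = sc[4], sc5 = sc[5],
                              lat = table$lat[cd$onset_idx],
                              lon = table$lon[cd$onset_idx])
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  structure(do.call(rbind, rows), class = c("mos_events", "data.frame"))
}

#' Match detections against ground truth
#'
#' Greedy one-to-one matching of detected events to injected stimuli: events
#' are visited in time order and matched to the nearest unmatched truth time
#' within `match_window` seconds. Accuracy is `TP / (TP + FP + FN)`.
#'
#' @param events a `mos_events` data frame (or numeric event times).
#' @param truth ground-truth data frame with an `onset` column (as returned
#'   by [generate_session()]) or a numeric vector of expected event times.
#' @param match_window matching tolerance in seconds (default 10).
#' @return list with `tp`, `fp`, `fn`, `accuracy`, `recall`, `precision`.
#' @export
evaluate_detections <- function(events, truth, match_window = 10) {
  et <- if (is.data.frame(events)) events$t else as.numeric(events)
  tt <- if (is.data.frame(truth)) truth$onset else as.numeric(truth)
  et <- sort(et)
  matched <- rep(FALSE, length(tt))
  tp <- 0L
  for (e in et) {
    if (!length(tt)) break
    d <- abs(tt - e)
    d[matched] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= match_window) {
      matched[j] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- length(et) - tp
  fn <- sum(!matched)
  denom <- tp + fp + fn
  list(tp = tp, fp = fp, fn = fn,
       accuracy = if (denom == 0) 1 else tp / denom,
       recall = if (length(tt) == 0) 1 else tp / length(tt),
       precision = if (length(et) == 0) 1 else tp / length(et))
}

#' Calibrate rule weights and the critical score
#'
#' Random search over the weight simplex (five non-negative weights summing
#' to 100, always including the shipped defaults) crossed with a grid of
#' critical scores, maximising `TP - lambda * FP` against the ground truth
#' of one or more sessions. Deterministic given `seed`; ties resolve to the
#' first setting examined.
#'
#' @param sessions list of lists, each with elements `table` (a
#'   `biogeo_table`) and `truth` (see [evaluate_detections()]).
#' @param n_draws number of random weight vectors to try.
#' @param cs_grid critical scores to try.
#' @param lambda false-positive penalty (larger values favour precision).
#' @param match_window passed to [evaluate_detections()].
#' @param seed integer seed for the weight draws.
#' @return list with `weights`, `cs`, and `report`, a data frame of every
#'   setting with its total TP, FP and objective.
#' @export
calibrate_weights <- function(sessions, n_draws = 50,
                              cs_grid = seq(50, 90, by = 5), lambda = 1,
                              match_window = 10, seed = 1) {
  if (!length(sessions))
    stop("configuration error: at least one ground-truthed session is required",
         call. = FALSE)
  if (!length(cs_grid))
    stop("configuration error: empty critical-score grid", call. = FALSE)
  with_session_seed(seed, {
    draws <- c(list(unname(default_rule_weights())),
               lapply(seq_len(n_draws), function(i) {
                 w <- stats::rexp(5)
                 w / sum(w) * 100
               }))
    report <- vector("list", length(draws) * length(cs_grid))
    k <- 0L
    best <- NULL
    for (w in draws) {
      for (cs in cs_grid) {
        tp <- 0L; fp <- 0L
        for (s in sessions) {
          ev <- detect_mos(s$table, weights = w, cs = cs)
          m <- evaluate_detections(ev, s$truth, match_window)
          tp <- tp + m$tp; fp <- fp + m$fp
        }
        obj <- tp - lambda * fp
        k <- k + 1L
        report[[k]] <- data.frame(w1 = w[1], w2 = w[2], w3 = w[3], w4 = w[4],
                                  w5 = w[5], cs = cs, tp = tp, fp = fp,
                                  objective = obj)
        if (is.null(best) || obj > best$objective)
          best <- list(weights = w, cs = cs, objective = obj)
      }
    }
    list(weights = stats::setNames(best$weights, paste0("r", 1:5)),
         cs = best$cs, report = do.call(rbind, report))
  })
}
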