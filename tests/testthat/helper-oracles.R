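# Independent brute-force oracle for the two-sided 100 uV turn rule:
# a naive per-sample state machine that tracks the running maximum and
# minimum since the last reversal and registers a turn at the running
# extreme once the signal has moved at least `thr` away from it, provided
# the extreme also lies at least `thr` from the previous reversal point
# (or from the signal's starting value for the first turn). Deliberately
# written differently from detect_turns(), which walks an extrema list.
oracle_turns <- function(x, thr = 100) {
  stopifnot(length(x) >= 3)
  ti <- integer(0); tv <- numeric(0)
  anchor <- x[1]
  dirn <- 0L
  mx <- x[1]; mx_i <- 1L
  mn <- x[1]; mn_i <- 1L
  for (i in 2:length(x)) {
    v <- x[i]
    if (dirn >= 0L && v > mx) { mx <- v; mx_i <- i }
    if (dirn <= 0L && v < mn) { mn <- v; mn_i <- i }
    if (dirn >= 0L && mx - v >= thr) {
      if (abs(mx - anchor) >= thr) { ti <- c(ti, mx_i); tv <- c(tv, mx) }
      anchor <- mx
      dirn <- -1L
      mn <- v; mn_i <- i
    } else if (dirn <= 0L && v - mn >= thr) {
      if (abs(mn - anchor) >= thr) { ti <- c(ti, mn_i); tv <- c(tv, mn) }
      anchor <- mn
      dirn <- 1L
      mx <- v; mx_i <- i
    }
  }
  ord <- order(ti)
  data.frame(index = ti[ord], amplitude = tv[ord])
}

# piecewise-linear signal through the given extremum amplitudes, with
# boundary values first/last; each segment gets `per` interior samples
toy_signal <- function(amps, per = 10) {
  out <- numeric(0)
  for (k in seq_len(length(amps) - 1)) {
    out <- c(out, seq(amps[k], amps[k + 1], length.out = per + 1)[-(per + 1)])
  }
  c(out, amps[length(amps)])
}

# symmetric triangle wave built by exact linear interpolation through its
# extrema, which land exactly on the sample grid (fs must be a multiple of
# 4 * freq); includes the endpoint sample so the final quarter-cycle closes
# at zero and every boundary flank is exactly `amp`
make_triangle <- function(freq, fs, duration, amp = 100) {
  stopifnot(fs %% (4 * freq) == 0)
  n_ext <- round(2 * freq * duration)
  knots_t <- c(0, (2 * seq_len(n_ext) - 1) / (4 * freq), duration)
  knots_v <- c(0, amp * rep_len(c(1, -1), n_ext), 0)
  t <- (0:round(duration * fs)) / fs
  stats::approx(knots_t, knots_v, xout = t)$y
}

# random piecewise-linear EMG-like signal for oracle-equivalence testing
random_emg_signal <- function(n_knots = 20, per = 8, amp_max = 300) {
  amps <- stats::runif(n_knots, -amp_max, amp_max)
  toy_signal(amps, per)
}

# analyze a synthetic voice recording end to end with given parameters
analyze_voice <- function(rec, ...) {
  en <- compute_energy_track(rec)
  bd <- detect_voice_bounds(en)
  estimate_f0_track(rec, bd, ...)
}
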