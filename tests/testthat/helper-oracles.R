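# Independent oracles and fixture builders used across the suite.
# Each oracle is deliberately naive (enumeration / fine time stepping) and
# coded without reference to the package internals it checks.

# interleave-order oracle: enumerate the wrap-around rule directly
oracle_slice_order <- function(n_slices) {
  step <- 1 + floor(sqrt(n_slices))
  out <- integer(0)
  for (start in seq_len(min(step, n_slices)))
    out <- c(out, seq(start, n_slices, by = step))
  out
}

# fine-time-step Bloch integrator: no event-driven shortcuts, fixed small dt.
# Uses the same packet-grid geometry as the simulator so slab means are
# comparable, but advances the state by uniform dt steps.
oracle_bloch_schedule <- function(protocol, tissue, v_mm_s, n_cycles = 6,
                                  dz = 0.1, dt = 0.25, margin_slices = 2) {
  n <- protocol$n_slices
  d <- protocol$slice_thickness_mm
  tr <- protocol$tr_ms
  t1 <- tissue$t1_ms
  m0 <- tissue$m0
  v <- v_mm_s / 1000
  t_total <- n_cycles * tr
  lo <- -margin_slices * d - max(v, 0) * t_total
  hi <- n * d + margin_slices * d - min(v, 0) * t_total
  z0 <- seq(lo + dz / 2, hi, by = dz)
  mz <- rep(m0, length(z0))
  ord <- slice_order(protocol)
  slot_ms <- tr / n
  ev_t <- rep((seq_len(n) - 1) * slot_ms, n_cycles) +
    rep((seq_len(n_cycles) - 1) * tr, each = n)
  ev_s <- rep(ord, n_cycles)
  sig <- numeric(n)
  decay <- exp(-dt / t1)
  ei <- 1
  fire <- function(t_now) {
    while (ei <= length(ev_t) && ev_t[ei] <= t_now + 1e-9) {
      s <- ev_s[ei]
      z <- z0 + v * ev_t[ei]
      in_slab <- z >= (s - 1) * d & z < s * d
      sig[s] <<- mean(mz[in_slab])
      mz[in_slab] <<- 0
      ei <<- ei + 1
    }
  }
  fire(0)
  for (k in seq_len(round(t_total / dt))) {
    mz <- m0 + (mz - m0) * decay
    fire(k * dt)
  }
  sig
}

# two-sided Fisher p by brute-force enumeration of all tables with the
# observed margins (hypergeometric weights)
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  a_min <- max(0, c1 - r2)
  a_max <- min(r1, c1)
  probs <- vapply(a_min:a_max, function(a)
    dhyper(a, r1, r2, c1), numeric(1))
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small standard fixtures -----------------------------------------------------

small_protocol <- function(n_measurements = 40, n_slices = 31)
  acq_protocol(n_measurements = n_measurements, n_slices = n_slices)

# compact phantom used throughout: 24 x 24 in-plane, study slice count/timing
small_phantom_spec <- function(protocol = small_protocol(), ...) {
  defaults <- list(protocol = protocol, nx = 24, ny = 24,
                   waveform = velocity_waveform("constant", v0 = 4),
                   noise_sd = 0, seed = 1)
  args <- utils::modifyList(defaults, list(...))
  do.call(phantom_spec, args)
}

expect_csf_error <- function(expr, class) {
  expect_error(expr, class = class)
}
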