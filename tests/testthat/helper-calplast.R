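# shared fixtures and independent oracles

fast_cfg <- function(...) solver_config(store_field = FALSE,
                                        store_every = 100000, ...)

# closed-form weight trajectory for a piecewise-constant calcium trace:
# segments is a data.frame with columns C (uM) and dur (s)
piecewise_weight_oracle <- function(w0, segments, params) {
  w <- w0
  for (i in seq_len(nrow(segments))) {
    C <- segments$C[i]; tt <- segments$dur[i]
    if (C > params$theta_p) {
      wstar <- params$gamma_p / (params$gamma_p + params$gamma_d)
      w <- wstar + (w - wstar) * exp(-(params$gamma_p + params$gamma_d) * tt)
    } else if (C > params$theta_d) {
      w <- w * exp(-params$gamma_d * tt)
    }
  }
  w
}

# explicit-Euler integration of the same trace through update_weights()
piecewise_weight_euler <- function(w0, segments, params, dt) {
  w <- w0
  for (i in seq_len(nrow(segments))) {
    n <- round(segments$dur[i] / dt)
    for (k in seq_len(n))
      w <- update_weights(w, segments$C[i], dt, params)
  }
  w
}

# brute-force classification oracle: walk the curve point by point,
# compress consecutive identical signs, then drop the no-change runs
classify_oracle <- function(dw, epsilon) {
  letters_ <- character(0)
  prev <- ""
  for (x in dw) {
    s <- if (x > epsilon) "P" else if (x < -epsilon) "D" else "0"
    if (s != prev) { letters_ <- c(letters_, s); prev <- s }
  }
  letters_ <- letters_[letters_ != "0"]
  if (length(letters_) == 0) "none" else paste(letters_, collapse = "")
}
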