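# shared internal helpers

PHASES <- c("expansion", "vibration", "contraction")

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, lower, upper))
  }
  invisible(x)
}

match_kind <- function(kind) match.arg(kind, c("join", "leave"))

match_phase <- function(phase) match.arg(phase, c("expansion", "contraction"))

# trapezoidal area under y(x); x strictly increasing
area_under <- function(x, y) pracma::trapz(x, y)
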