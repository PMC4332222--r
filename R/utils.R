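#' @keywords internal
"_PACKAGE"

# Hierarchical child seeds: all randomness in a run derives from one master
# seed. Kept below 2^31 - 1 so set.seed() always accepts the value.
child_seed <- function(master, i) {
  as.integer((as.numeric(master) + 1000003 * as.numeric(i)) %% 2147483629)
}

# Inverse-CDF truncated normal: deterministic given the RNG stream.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd >= 0, lower < upper)
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

abort_lungfot <- function(msg, class) {
  stop(structure(class = c(class, "lungfot_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
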