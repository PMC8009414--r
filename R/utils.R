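# internal helpers shared across modules

# round half away from zero; base round() is banker's rounding, which would
# systematically under-allocate gap targets ending in .5
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_config <- function(msg) rlang::abort(msg, class = "arraybias_config_error")
abort_state <- function(msg) rlang::abort(msg, class = "arraybias_state_error")
abort_stat <- function(msg) rlang::abort(msg, class = "arraybias_stat_error")
abort_format <- function(msg) rlang::abort(msg, class = "arraybias_format_error")

stopifnot_panel <- function(panel) {
  if (!inherits(panel, "snp_panel")) {
    abort_config("`panel` must be a <snp_panel> object")
  }
  invisible(panel)
}

n_loci <- function(panel) nrow(panel$loci)
n_pops <- function(panel) nrow(panel$pop_meta)

# Balding-Nichols draw: Beta with mean p and variance F * p * (1 - p).
# Fixed input frequencies (p in {0,1}) stay fixed; F ~ 0 degenerates to p.
rbeta_bn <- function(p, f) {
  out <- p
  idx <- which(p > 0 & p < 1)
  if (length(idx) == 0L) return(out)
  if (f < 1e-12) return(out)
  scale <- (1 - f) / f
  out[idx] <- rbeta(length(idx), p[idx] * scale, (1 - p[idx]) * scale)
  out
}

# normal truncated at zero by redrawing (no atom at 0)
rnorm_pos <- function(n, mean, sd) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < 0)
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0]
  }
  out
}
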