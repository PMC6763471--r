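# Piecewise-constant external-osmolarity shock protocols.

#' Osmotic shock protocol
#'
#' A right-continuous piecewise-constant external osmolarity `c_e(t)`:
#' at each step time the medium osmolarity jumps to the paired value and
#' holds until the next step. A protocol starting at `t = 0` defines the
#' baseline medium; [simulate_scgm()] prepends the parameter set's `c_e`
#' as baseline when the first step is later than the simulation start.
#'
#' @param t_s step times in seconds (strictly increasing).
#' @param c_e_mM external osmolarities in mM (non-negative), same length.
#' @return an object of class `shock_protocol`.
#' @examples
#' # hyperosmotic shock to 500 mM at 70 min, back down to 325 mM at 100 min
#' shock_protocol(t_s = c(70, 100) * 60, c_e_mM = c(500, 325))
#' @export
shock_protocol <- function(t_s = numeric(0), c_e_mM = numeric(0)) {
  stopifnot(length(t_s) == length(c_e_mM))
  if (length(t_s) > 1 && any(diff(t_s) <= 0))
    stop("protocol step times must be strictly increasing")
  if (any(c_e_mM < 0)) stop("protocol osmolarities must be non-negative")
  structure(list(t_s = as.numeric(t_s), c_e_mM = as.numeric(c_e_mM)),
            class = "shock_protocol")
}

#' @export
print.shock_protocol <- function(x, ...) {
  if (!length(x$t_s)) {
    cat("Shock protocol: none (constant external osmolarity)\n")
  } else {
    cat("Shock protocol:\n")
    for (i in seq_along(x$t_s))
      cat(sprintf("  t = %6.1f min -> c_e = %g mM\n",
                  x$t_s[i] / 60, x$c_e_mM[i]))
  }
  invisible(x)
}

#' External osmolarity at a given time
#'
#' @param protocol a [shock_protocol()].
#' @param t time(s) in seconds.
#' @param baseline_mM osmolarity before the first step (mM).
#' @return osmolarity in mM (right-continuous in `t`).
#' @export
protocol_value <- function(protocol, t, baseline_mM) {
  stopifnot(inherits(protocol, "shock_protocol"))
  vapply(t, function(ti) {
    i <- which(protocol$t_s <= ti)
    if (length(i)) protocol$c_e_mM[max(i)] else baseline_mM
  }, numeric(1))
}

#' Read a shock protocol from YAML
#'
#' The file is a YAML list of `{t_min, c_e_mM}` entries, times in minutes.
#'
#' @param path YAML file path.
#' @return a [shock_protocol()].
#' @export
read_protocol <- function(path) {
  entries <- yaml::read_yaml(path)
  if (!length(entries)) return(shock_protocol())
  t_min <- vapply(entries, function(e) as.numeric(e$t_min), numeric(1))
  c_e <- vapply(entries, function(e) as.numeric(e$c_e_mM), numeric(1))
  shock_protocol(t_s = min_to_s(t_min), c_e_mM = c_e)
}

# Segment boundaries of a protocol clipped to [t0, t_end]
protocol_segments <- function(protocol, t0, t_end, baseline_mM) {
  steps <- protocol$t_s[protocol$t_s > t0 & protocol$t_s < t_end]
  starts <- c(t0, steps)
  ends <- c(steps, t_end)
  c_e <- protocol_value(protocol, starts, baseline_mM)
  data.frame(start = starts, end = ends, c_e_mM = c_e)
}
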