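# Internal helpers shared across modules.

# Classed conditions so callers can distinguish failure modes programmatically.
# All spatroi errors carry class c(<subclass>, "spatroi_error", "error").
sr_stop <- function(subclass, msg, ...) {
  stop(structure(
    class = c(subclass, "spatroi_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

sr_warn <- function(subclass, msg, ...) {
  warning(structure(
    class = c(subclass, "spatroi_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Map a channel name to the slice index of a (row, col, 3) pixel array.
channel_index <- function(channel) {
  idx <- match(toupper(channel), c("R", "G", "B"))
  if (is.na(idx)) {
    sr_stop("spatroi_parameter_error",
            "unknown channel '%s'; expected one of R, G, B", channel)
  }
  idx
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Logical disc mask in (row, col) orientation; cx, cy are 0-based pixel coords.
disc_mask <- function(nrow, ncol, cx, cy, radius) {
  x <- matrix(rep(seq_len(ncol) - 1, each = nrow), nrow = nrow)
  y <- matrix(rep(seq_len(nrow) - 1, times = ncol), nrow = nrow)
  (x - cx)^2 + (y - cy)^2 <= radius^2
}

# Trapezoid-rule integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# row/col <-> EBImage (x, y) transposition at the EBImage boundary.
as_eb <- function(m) t(m)
from_eb <- function(m) t(m)
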