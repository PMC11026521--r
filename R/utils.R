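# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.vnorm <- function(v) sqrt(sum(v * v))

.unitize <- function(v, what = "vector") {
  n <- .vnorm(v)
  if (!is.finite(n) || n < 1e-12) {
    stop_aaa("aaa_precondition_error", sprintf("cannot normalize zero-length %s", what))
  }
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Classed conditions so callers can distinguish failure modes without
# parsing messages.
stop_aaa <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "aaa_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

.as_point_matrix <- function(x, what = "points") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.numeric(x) && is.null(dim(x)) && length(x) %% 3 == 0) {
    x <- matrix(x, ncol = 3, byrow = TRUE)
  }
  if (!is.matrix(x) || ncol(x) != 3 || !is.numeric(x)) {
    stop_aaa("aaa_precondition_error", "%s must be an n x 3 numeric matrix", what)
  }
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}
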