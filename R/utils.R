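`%||%` <- function(x, y) if (is.null(x)) y else x

stop_input <- function(...) stop(..., call. = FALSE)

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

## Named numeric vector aligned to a circuit's neuron order.
align_state <- function(x, names) {
  if (is.null(names(x))) {
    if (length(x) != length(names)) {
      stop_input("state vector length ", length(x),
                 " does not match circuit size ", length(names))
    }
    return(stats::setNames(as.numeric(x), names))
  }
  missing <- setdiff(names, names(x))
  if (length(missing) > 0) {
    stop_input("state vector is missing neurons: ",
               paste(missing, collapse = ", "))
  }
  stats::setNames(as.numeric(x[names]), names)
}
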