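#' @useDynLib panseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif setNames
#' @importFrom utils read.csv write.csv
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# He-style initialization for an array of weights with a given fan-in.
init_array <- function(dim, fan_in) {
  array(stats::rnorm(prod(dim), sd = sqrt(2 / fan_in)), dim = dim)
}

zeros <- function(...) array(0, dim = c(...))

mark_frozen <- function(p, frozen = TRUE) {
  rapply(p, function(a) { attr(a, "frozen") <- frozen; a },
         classes = "ANY", how = "replace")
}

is_frozen <- function(a) isTRUE(attr(a, "frozen"))

# Flatten a nested list of arrays to a single-level named list ("a.b.c").
flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(p[[nm]])) out <- c(out, flatten_params(p[[nm]], key))
    else out[[key]] <- p[[nm]]
  }
  out
}

# Write a flat named list of arrays back into the nested structure.
unflatten_into <- function(p, flat) {
  for (key in names(flat)) {
    path <- strsplit(key, ".", fixed = TRUE)[[1]]
    p[[path]] <- flat[[key]]
  }
  p
}

n_params <- function(p) sum(vapply(flatten_params(p), length, 0L))

# Elementwise-add two parallel nested lists of arrays (gradient accumulation).
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (nm in names(b)) a[[nm]] <- add_grads(a[[nm]], b[[nm]])
    return(a)
  }
  a + b
}

# Per-channel sums of an (H,W,C,N) array -> length-C vector.
channel_sums <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  rowSums(matrix(colSums(m), d[3], d[4]))
}

# Broadcast a length-C vector over an (H,W,C,N) array.
bcast_c <- function(v, d) {
  array(rep(rep(v, each = d[1] * d[2]), d[4]), dim = d)
}

stopifnot_binary <- function(m, what) {
  if (!all(m %in% c(0, 1)))
    stop(what, " must be binary (values in {0,1})", call. = FALSE)
}
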