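# Internal helpers shared across modules.

#' @noRd
el_log <- function(...) {
  if (isTRUE(getOption("endolight.verbose", TRUE))) {
    message("[endolight] ", ...)
  }
  invisible(NULL)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-region seed derived from a global seed and the region
# centre's linear index. Kept below 2^31 - 1; arithmetic stays well inside
# the exactly-representable double range.
#' @noRd
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) * 31 + as.double(index) * 7919
  as.integer(s %% 2147483629)
}

# linear index <-> (i, j, k) conversions for a 3D grid (1-based, column-major)
#' @noRd
coord_to_linear <- function(coords, shape) {
  coords <- matrix(as.integer(coords), ncol = 3)
  as.integer(coords[, 1] +
    (coords[, 2] - 1L) * shape[1] +
    (coords[, 3] - 1L) * shape[1] * shape[2])
}

#' @noRd
linear_to_coord <- function(idx, shape) {
  idx0 <- as.integer(idx) - 1L
  i <- idx0 %% shape[1]
  j <- (idx0 %/% shape[1]) %% shape[2]
  k <- idx0 %/% (shape[1] * shape[2])
  cbind(i = i + 1L, j = j + 1L, k = k + 1L)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
group_levels <- function() c("control", "case", "sibling")
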