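# Internal helpers shared across modules.

# All user-visible files are 1-based inclusive (GFF convention). Internal
# interval arithmetic uses 0-based half-open [start0, end0). These two
# converters are the only place the +1/-1 appears.
to0 <- function(start1, end1) list(start0 = start1 - 1L, end0 = end1)
to1 <- function(start0, end0) list(start1 = start0 + 1L, end1 = end0)

# 0-based window index of a 1-based coordinate.
window_index <- function(coord1, window_size) {
  as.integer(floor((coord1 - 1) / window_size))
}

# Half-open span of a window, returned 1-based inclusive.
window_span <- function(index, window_size) {
  list(start = index * window_size + 1L, end = (index + 1L) * window_size)
}

# C-locale (radix) ordering so output files do not depend on the session
# locale.
c_order <- function(...) order(..., method = "radix")

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so package functions never perturb user simulations.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Read a text file tolerating CRLF line endings and trailing blank lines.
read_lines_clean <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sub("\r$", "", lines)
}

is_wholenumber <- function(x) {
  !is.na(suppressWarnings(as.numeric(x))) &
    grepl("^[0-9]+$", trimws(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
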