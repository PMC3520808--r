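# Internal helpers shared across the package.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.  `seed = NULL` leaves the RNG stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Atomic file write: write to a sibling temp file, then rename into place, so
# a crash never leaves a half-written artifact and reruns are all-or-nothing.
atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(pattern = paste0(".", basename(path), "."), tmpdir = dir)
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    # rename across filesystems can fail; fall back to copy + remove
    if (!file.copy(tmp, path, overwrite = TRUE))
      stop("could not write ", path)
    unlink(tmp)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) {
  stop(structure(class = c("cfcentile_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# check that `x` is one of `choices`, returning the match
match_code <- function(x, choices, what) {
  if (length(x) != 1L || !x %in% choices)
    stop_domain(what, " must be one of ", paste(choices, collapse = ", "),
                " (got '", paste(x, collapse = ","), "')")
  x
}

# packageVersion() reads DESCRIPTION from disk; cache it (hot in bootstraps)
.pkg_cache <- new.env(parent = emptyenv())
pkg_version <- function() {
  v <- .pkg_cache$version
  if (is.null(v)) {
    v <- tryCatch(as.character(utils::packageVersion("cfcentile")),
                  error = function(e) "unknown")
    .pkg_cache$version <- v
  }
  v
}
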